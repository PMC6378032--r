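# The four shipped presets must reproduce the published parameter table
# cell-for-cell.
published_table <- local({
  cols <- c("early_onset", "late_amyloid_first", "late_tau_first",
            "late_amyloid_first_rx")
  rows <- list(
    a_beta0 = c(0.05, 0.01, 0.01, 0.01),
    tau_p0 = c(0, 0, 0, 0),
    tau_o0 = c(0, 0.05, 0.05, 0.05),
    n_deg0 = c(0, 0, 0, 0),
    cog0 = c(0, 0, 0, 0),
    k_ab = c(1, 1, 1, 1),
    k_tp = c(1, 1, 1, 1),
    k_c = c(1, 1, 1, 1),
    k_n = c(1, 1, 1, 1),
    lam_ab = c(0.08, 0.12, 0.1, 0.12),
    lam_ab_ao = c(0, 0, 0, 0),
    delta_ab = c(0, 0, 0, 0.04),
    lam_tp_ab = c(0.025, 0.025, 0.025, 0.025),
    lam_tp = c(0.05, 0.05, 0.05, 0.05),
    lam_to_as = c(0.002, 0.002, 0.002, 0.002),
    lam_c = c(0.05, 0.05, 0.05, 0.05),
    lam_cn = c(0.001, 0.001, 0.001, 0.001),
    lam_c_as = c(0, 0, 0, 0),
    lam_c_eps = c(0.001, 0.001, 0.001, 0.001),
    lam_n = c(0.05, 0.05, 0.05, 0.05),
    lam_n_tp = c(0.025, 0.025, 0.025, 0.025),
    lam_n_to = c(0.0075, 0.0075, 0.0075, 0.0075),
    lam_n_as = c(0, 0, 0, 0),
    a_o = c(0, 0, 0, 0),
    as_level = c(0, 1, 2, 1),
    eps = c(0, 0, 0, 0),
    reserve_low = c(1, 1, 1, 1),
    reserve_high = c(25, 25, 25, 25)
  )
  list(cols = cols, rows = rows)
})

test_that("presets reproduce every published parameter value", {
  for (j in seq_along(published_table$cols)) {
    cfg <- ad_preset(published_table$cols[j])
    for (p in names(published_table$rows)) {
      expect_identical(unname(get_params(cfg, p)),
                       published_table$rows[[p]][j],
                       label = sprintf("%s / %s", cfg$name, p))
    }
  }
  # therapy schedule: only the treatment column is active, onset at 65
  expect_false(ad_preset("early_onset")$therapy$active)
  expect_false(ad_preset("late_amyloid_first")$therapy$active)
  expect_false(ad_preset("late_tau_first")$therapy$active)
  rx <- ad_preset("late_amyloid_first_rx")
  expect_true(rx$therapy$active)
  expect_identical(rx$therapy$onset_age, 65)
  # the amyloid cascade is seeded in every preset
  for (nm in published_table$cols) {
    expect_gt(ad_preset(nm)$initial[["a_beta"]], 0)
  }
})

test_that("preset lookup is case-insensitive and names valid scenarios on error", {
  expect_identical(ad_preset("Early_Onset")$name, "early_onset")
  expect_error(ad_preset("nope"), "late_tau_first")
  expect_error(ad_preset(c("a", "b")), "single string")
})

test_that("config files round-trip losslessly", {
  for (nm in c("early_onset", "late_amyloid_first", "late_tau_first",
               "late_amyloid_first_rx")) {
    path <- withr::local_tempfile(fileext = ".yaml")
    cfg <- ad_preset(nm)
    write_config(cfg, path)
    expect_identical(read_config(path), cfg)
  }
  set.seed(7)
  for (i in 1:10) {
    path <- withr::local_tempfile(fileext = ".yaml")
    cfg <- random_config()
    write_config(cfg, path)
    expect_identical(read_config(path), cfg)
  }
})

test_that("config reading applies defaults and rejects bad files", {
  # omitted keys fall back to defaults, notably the 0-100 x 0.1 grid
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("schema_version: 1", "name: minimal"), path)
  cfg <- read_config(path)
  expect_identical(cfg$grid, list(start = 0, end = 100, step = 0.1))
  expect_identical(cfg$degradation_form, "literal")

  # unknown top-level and nested keys are rejected by name
  writeLines(c("name: x", "frobnicate: 1"), path)
  expect_error(read_config(path), "frobnicate")
  writeLines(c("name: x", "rates:", "  lam_zz: 0.1"), path)
  expect_error(read_config(path), "lam_zz")

  # invariant violations are reported with the offending field
  writeLines(c("name: x", "rates:", "  lam_ab: -0.08"), path)
  expect_error(read_config(path), "lam_ab")
  expect_error(read_config(withr::local_tempfile()), "not found")
})

test_that("validation returns violations as data", {
  for (nm in c("early_onset", "late_amyloid_first", "late_tau_first",
               "late_amyloid_first_rx")) {
    expect_identical(nrow(validate_config(ad_preset(nm))), 0L)
  }
  cfg <- ad_preset("early_onset")
  cfg$therapy$onset_age <- -5
  v <- validate_config(cfg)
  expect_identical(nrow(v), 1L)
  expect_identical(v$field, "therapy.onset_age")

  cfg2 <- ad_preset("early_onset")
  cfg2$caps[["k_ab"]] <- 0
  v2 <- validate_config(cfg2)
  expect_identical(nrow(v2), 1L)
  expect_identical(v2$field, "caps.k_ab")
  expect_match(v2$rule, "> 0")
})
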