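test_that("null dynamics stay identically zero", {
  cfg <- decoupled_config("a_beta", lam = 0, K = 1, x0 = 1)
  cfg$initial[["a_beta"]] <- 0
  traj <- simulate(cfg, grid = list(start = 0, end = 100, step = 1))
  expect_true(all(as.matrix(traj[-1]) == 0))
})

test_that("each decoupled logistic cascade matches the closed form", {
  grid <- list(start = 0, end = 100, step = 0.5)
  cases <- list(
    list(state = "a_beta", lam = 0.08, K = 1, x0 = 0.05),
    list(state = "tau_p", lam = 0.05, K = 1, x0 = 0.02),
    list(state = "n_deg", lam = 0.05, K = 0.8, x0 = 0.01),
    list(state = "cog", lam = 0.05, K = 1.2, x0 = 0.03)
  )
  for (cs in cases) {
    cfg <- decoupled_config(cs$state, lam = cs$lam, K = cs$K, x0 = cs$x0)
    traj <- simulate(cfg, grid = grid)
    expected <- logistic_closed_form(traj$age, cs$lam, cs$K, cs$x0)
    expect_lt(max(abs(traj[[cs$state]] - expected)), 1e-6)
  }
})

test_that("halving the solver tolerance leaves trajectories unchanged to 1e-6", {
  cfg <- ad_preset("late_amyloid_first_rx")
  grid <- list(start = 0, end = 100, step = 1)
  a <- simulate_risk_pair(cfg, grid = grid, rtol = 1e-8, atol = 1e-10)
  b <- simulate_risk_pair(cfg, grid = grid, rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(as.matrix(a[-1]) - as.matrix(b[-1]))), 1e-6)
})

test_that("therapy leaves the pre-onset interval untouched", {
  rx <- ad_preset("late_amyloid_first_rx")
  nat <- natural_history_twin(rx)
  expect_identical(nat$rates[["delta_ab"]], 0)
  a <- simulate_risk_pair(rx)
  b <- simulate_risk_pair(nat)
  pre <- a$age < rx$therapy$onset_age
  expect_lt(max(abs(as.matrix(a[pre, -1]) - as.matrix(b[pre, -1]))), 1e-8)
  # ... and therapy does change the post-onset amyloid course
  expect_lt(a$a_beta[a$age == 100], b$a_beta[b$age == 100])
})

test_that("all levels stay nonnegative, including under the therapy sink", {
  rx <- ad_preset("late_amyloid_first_rx")
  rx$rates[["delta_ab"]] <- 0.4 # strong clearance: would drive amyloid negative
  traj <- simulate_risk_pair(rx)
  expect_true(all(as.matrix(traj[-1]) >= 0))
  # amyloid is actually exhausted under this dose, so the floor is active
  expect_identical(traj$a_beta[traj$age == 100], 0)
})

test_that("cognition feeds back into no other equation", {
  cfg <- ad_preset("early_onset")
  base <- simulate(cfg, grid = list(start = 0, end = 100, step = 1))
  cfg2 <- cfg
  cfg2$initial[["cog"]] <- 0.5
  pert <- simulate(cfg2, grid = list(start = 0, end = 100, step = 1))
  shared <- c("a_beta", "tau_p", "tau_o", "n_deg")
  expect_lt(max(abs(as.matrix(base[shared]) - as.matrix(pert[shared]))), 1e-8)
  expect_gt(max(abs(base$cog - pert$cog)), 0.1)
})

test_that("risk pair shares the non-cognitive states and splits on reserve", {
  cfg <- ad_preset("early_onset")
  pair <- simulate_risk_pair(cfg, grid = list(start = 0, end = 100, step = 0.5))
  high <- simulate(cfg, grid = list(start = 0, end = 100, step = 0.5),
                   reserve = "high")
  low <- simulate(cfg, grid = list(start = 0, end = 100, step = 0.5),
                  reserve = "low")
  shared <- c("a_beta", "tau_p", "tau_o", "n_deg")
  expect_lt(max(abs(as.matrix(pair[shared]) - as.matrix(high[shared]))), 1e-7)
  expect_lt(max(abs(pair$cog_high - high$cog)), 1e-7)
  expect_lt(max(abs(pair$cog_low - low$cog)), 1e-7)

  # equal reserve constants give identical cognition curves
  cfg_eq <- cfg
  cfg_eq$host[["reserve_high"]] <- cfg_eq$host[["reserve_low"]]
  pair_eq <- simulate_risk_pair(cfg_eq, grid = list(start = 0, end = 100,
                                                    step = 1))
  expect_identical(pair_eq$cog_low, pair_eq$cog_high)

  # high reserve constant brings cognitive onset earlier
  on <- detect_onset(pair)$onsets
  expect_lt(on[["cog_high"]], on[["cog_low"]])
})

test_that("trajectory CSV export round-trips with the documented header", {
  path <- withr::local_tempfile(fileext = ".csv")
  traj <- simulate_risk_pair(ad_preset("early_onset"),
                             grid = list(start = 0, end = 100, step = 10))
  write_trajectory(traj, path)
  expect_identical(readLines(path, n = 1),
                   "age,a_beta,tau_p,tau_o,tau_total,n_deg,cog_low,cog_high")
  back <- read_trajectory(path)
  expect_equal(as.data.frame(back), as.data.frame(traj), ignore_attr = TRUE,
               tolerance = 1e-12)

  single <- simulate(ad_preset("early_onset"),
                     grid = list(start = 0, end = 100, step = 10))
  write_trajectory(single, path)
  expect_identical(readLines(path, n = 1),
                   "age,a_beta,tau_p,tau_o,tau_total,n_deg,cog")
})

test_that("invalid configs and grids are rejected", {
  cfg <- ad_preset("early_onset")
  cfg$rates[["lam_ab"]] <- -1
  expect_error(simulate(cfg), "lam_ab")
  expect_error(simulate(ad_preset("early_onset"), times = c(10, 5)),
               "increasing")
})
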