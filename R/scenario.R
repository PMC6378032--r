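# Scenario configurations: constructor, published presets, validation, and
# YAML config file input/output.

.CONFIG_SCHEMA_VERSION <- 1L

.PRESET_NAMES <- c("early_onset", "late_amyloid_first", "late_tau_first",
                   "late_amyloid_first_rx")

#' Build a cascade scenario configuration
#'
#' Assembles initial state, rate constants, carrying capacities, host
#' factors, therapy schedule, and output age grid into a validated scenario
#' object. The defaults are the published early-onset parameterization, so
#' `scenario_config()` with no arguments equals `ad_preset("early_onset")`
#' apart from the name; individual fields can be overridden via named
#' vectors or lists supplying a subset of the components.
#'
#' @param name Scenario identifier.
#' @param initial Named numeric: initial levels `a_beta`, `tau_p`, `tau_o`,
#'   `n_deg`, `cog` at age `grid$start`. The amyloid level is positive in
#'   every shipped preset so that the amyloid cascade starts at some point
#'   during the lifespan even without an external amyloidopathy driver.
#' @param rates Named numeric rate constants (per year); see
#'   [cascade_rhs()] for the coupling structure. Missing names default to
#'   the early-onset values.
#' @param caps Named numeric logistic carrying capacities `k_ab`, `k_tp`,
#'   `k_n`, `k_c` (dimensionless levels). The SNAP-tau component grows
#'   linearly and has no capacity.
#' @param host Named numeric host factors: amyloidopathy `a_o`, aging/SNAP
#'   burden `as_level`, ApoE genetic risk `eps`, and the two
#'   cognitive-reserve constants `reserve_low`, `reserve_high`.
#' @param therapy List with `active` flag and `onset_age` (years) for the
#'   anti-amyloid therapy step input.
#' @param grid List with `start`, `end`, `step` (years) defining the output
#'   age grid; defaults to ages 0 to 100 sampled every 0.1 years.
#' @param degradation_form How the therapy withdrawal term acts on amyloid:
#'   `"literal"` (constant sink `delta_ab * A_Rx(t)`, the default) or
#'   `"proportional"` (`delta_ab * a_beta * A_Rx(t)`).
#' @return An object of class `ad_scenario`.
#' @export
scenario_config <- function(name = "custom",
                            initial = NULL, rates = NULL, caps = NULL,
                            host = NULL, therapy = NULL, grid = NULL,
                            degradation_form = c("literal", "proportional")) {
  degradation_form <- match.arg(degradation_form)
  def_initial <- c(a_beta = 0.05, tau_p = 0, tau_o = 0, n_deg = 0, cog = 0)
  def_rates <- c(lam_ab = 0.08, lam_ab_ao = 0, delta_ab = 0,
                 lam_tp_ab = 0.025, lam_tp = 0.05, lam_to_as = 0.002,
                 lam_n = 0.05, lam_n_tp = 0.025, lam_n_to = 0.0075,
                 lam_n_as = 0, lam_c = 0.05, lam_cn = 0.001,
                 lam_c_as = 0, lam_c_eps = 0.001)
  def_caps <- c(k_ab = 1, k_tp = 1, k_n = 1, k_c = 1)
  def_host <- c(a_o = 0, as_level = 0, eps = 0, reserve_low = 1,
                reserve_high = 25)
  def_therapy <- list(active = FALSE, onset_age = 0)
  def_grid <- list(start = 0, end = 100, step = 0.1)

  therapy <- .merge_list(def_therapy, therapy, "therapy")
  therapy$active <- isTRUE(therapy$active)
  therapy$onset_age <- as.numeric(therapy$onset_age)
  grid <- lapply(.merge_list(def_grid, grid, "grid"), as.numeric)
  cfg <- structure(list(
    name = as.character(name)[1],
    initial = .merge_named(def_initial, initial, "initial"),
    rates = .merge_named(def_rates, rates, "rates"),
    caps = .merge_named(def_caps, caps, "caps"),
    host = .merge_named(def_host, host, "host"),
    therapy = therapy,
    grid = grid,
    degradation_form = degradation_form
  ), class = "ad_scenario")
  .assert_valid(cfg)
  cfg
}

.merge_named <- function(defaults, supplied, what) {
  if (is.null(supplied)) return(defaults)
  supplied <- unlist(supplied)
  bad <- setdiff(names(supplied), names(defaults))
  if (length(bad) || is.null(names(supplied))) {
    stop(sprintf("unknown %s key(s): %s", what,
                 paste(if (length(bad)) bad else "<unnamed>", collapse = ", ")),
         call. = FALSE)
  }
  defaults[names(supplied)] <- as.numeric(supplied)
  defaults
}

.merge_list <- function(defaults, supplied, what) {
  if (is.null(supplied)) return(defaults)
  bad <- setdiff(names(supplied), names(defaults))
  if (length(bad) || is.null(names(supplied))) {
    stop(sprintf("unknown %s key(s): %s", what,
                 paste(if (length(bad)) bad else "<unnamed>", collapse = ", ")),
         call. = FALSE)
  }
  defaults[names(supplied)] <- supplied
  defaults
}

#' Published scenario presets
#'
#' Returns one of the four published parameter sets: early-onset autosomal
#' dominant AD, late-onset amyloid-first AD, late-onset tau-first (SNAP)
#' AD, or anti-amyloid therapy applied to the late-onset amyloid-first
#' scenario (therapy started at age 65 and maintained for life). Names are
#' matched case-insensitively.
#'
#' @param name One of `"early_onset"`, `"late_amyloid_first"`,
#'   `"late_tau_first"`, `"late_amyloid_first_rx"`.
#' @return An `ad_scenario` configuration.
#' @examples
#' ad_preset("early_onset")$initial[["a_beta"]] # 0.05
#' @export
ad_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L) {
    stop("ad_preset: 'name' must be a single string", call. = FALSE)
  }
  key <- match(tolower(name), .PRESET_NAMES)
  if (is.na(key)) {
    stop(sprintf("unknown scenario '%s'; valid names: %s", name,
                 paste(.PRESET_NAMES, collapse = ", ")), call. = FALSE)
  }
  switch(.PRESET_NAMES[key],
    early_onset = scenario_config(name = "early_onset"),
    late_amyloid_first = scenario_config(
      name = "late_amyloid_first",
      initial = c(a_beta = 0.01, tau_o = 0.05),
      rates = c(lam_ab = 0.12),
      host = c(as_level = 1)),
    late_tau_first = scenario_config(
      name = "late_tau_first",
      initial = c(a_beta = 0.01, tau_o = 0.05),
      rates = c(lam_ab = 0.1),
      host = c(as_level = 2)),
    late_amyloid_first_rx = scenario_config(
      name = "late_amyloid_first_rx",
      initial = c(a_beta = 0.01, tau_o = 0.05),
      rates = c(lam_ab = 0.12, delta_ab = 0.04),
      host = c(as_level = 1),
      therapy = list(active = TRUE, onset_age = 65))
  )
}

#' Validate a scenario configuration
#'
#' Checks all type invariants (non-negative levels and rates, positive
#' capacities, positive initial amyloid, sane therapy schedule and age
#' grid) and returns the violations as data rather than raising.
#'
#' @param config An `ad_scenario` (or a bare list with the same shape).
#' @return A data frame with columns `field`, `value`, `rule`; zero rows
#'   when the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- list()
  flag <- function(field, value, rule) {
    v[[length(v) + 1L]] <<- data.frame(field = field,
                                       value = as.character(value)[1],
                                       rule = rule)
  }
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(config$initial) || any(config$initial < 0)) {
    bad <- names(config$initial)[!is.finite(config$initial) | config$initial < 0]
    for (b in bad) flag(paste0("initial.", b), config$initial[[b]],
                        "initial levels must be finite and >= 0")
  }
  for (r in names(config$rates)) {
    x <- config$rates[[r]]
    if (!is.finite(x) || x < 0) flag(paste0("rates.", r), x,
                                     "rates must be finite and >= 0")
  }
  for (k in names(config$caps)) {
    x <- config$caps[[k]]
    if (!is.finite(x) || x <= 0) flag(paste0("caps.", k), x,
                                      "carrying capacities must be > 0")
  }
  for (h in names(config$host)) {
    x <- config$host[[h]]
    if (!is.finite(x) || x < 0) flag(paste0("host.", h), x,
                                     "host factors must be finite and >= 0")
  }
  if (!is.logical(config$therapy$active)) {
    flag("therapy.active", config$therapy$active, "must be a flag")
  }
  if (!is.finite(config$therapy$onset_age) || config$therapy$onset_age < 0) {
    flag("therapy.onset_age", config$therapy$onset_age,
         "therapy onset age must be >= 0")
  }
  g <- config$grid
  if (!is.finite(g$start) || !is.finite(g$end) || g$start >= g$end) {
    flag("grid", sprintf("[%s, %s]", g$start, g$end), "grid start must precede end")
  }
  if (!is.finite(g$step) || g$step <= 0) {
    flag("grid.step", g$step, "grid step must be > 0")
  }
  if (!config$degradation_form %in% c("literal", "proportional")) {
    flag("degradation_form", config$degradation_form,
         "must be 'literal' or 'proportional'")
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(field = character(), value = character(), rule = character())
}

.assert_valid <- function(config) {
  v <- validate_config(config)
  if (nrow(v)) {
    stop("invalid scenario config: ",
         paste(sprintf("%s (%s)", v$field, v$rule), collapse = "; "),
         call. = FALSE)
  }
  invisible(config)
}

#' Read and write scenario configuration files
#'
#' Configurations are stored as YAML with a `schema_version` key. Unknown
#' keys are rejected by name; omitted optional keys fall back to the
#' constructor defaults (notably the age grid, 0--100 years in steps of
#' 0.1). `read_config(write_config(cfg, path))` reproduces `cfg`
#' field-for-field.
#'
#' @param path File path.
#' @param config An `ad_scenario`.
#' @return `read_config` returns an `ad_scenario`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file is not a YAML mapping: ", path, call. = FALSE)
  allowed <- c("schema_version", "name", "initial", "rates", "caps", "host",
               "therapy", "grid", "degradation_form")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$schema_version) && raw$schema_version != .CONFIG_SCHEMA_VERSION) {
    stop("unsupported config schema_version: ", raw$schema_version, call. = FALSE)
  }
  scenario_config(
    name = if (is.null(raw$name)) "custom" else raw$name,
    initial = raw$initial, rates = raw$rates, caps = raw$caps,
    host = raw$host, therapy = raw$therapy, grid = raw$grid,
    degradation_form = if (is.null(raw$degradation_form)) "literal"
                       else raw$degradation_form
  )
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ad_scenario"))
  out <- list(
    schema_version = .CONFIG_SCHEMA_VERSION,
    name = config$name,
    initial = as.list(config$initial),
    rates = as.list(config$rates),
    caps = as.list(config$caps),
    host = as.list(config$host),
    therapy = config$therapy,
    grid = config$grid,
    degradation_form = config$degradation_form
  )
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @export
print.ad_scenario <- function(x, ...) {
  cat(sprintf("<ad_scenario> %s\n", x$name))
  cat(sprintf("  initial: %s\n",
              paste(sprintf("%s=%g", names(x$initial), x$initial), collapse = " ")))
  nz <- x$rates[x$rates != 0]
  cat(sprintf("  rates (nonzero): %s\n",
              paste(sprintf("%s=%g", names(nz), nz), collapse = " ")))
  cat(sprintf("  caps: %s\n",
              paste(sprintf("%s=%g", names(x$caps), x$caps), collapse = " ")))
  cat(sprintf("  host: %s\n",
              paste(sprintf("%s=%g", names(x$host), x$host), collapse = " ")))
  cat(sprintf("  therapy: %s\n",
              if (isTRUE(x$therapy$active))
                sprintf("anti-amyloid from age %g", x$therapy$onset_age)
              else "none"))
  cat(sprintf("  grid: %g to %g years, step %g; degradation: %s\n",
              x$grid$start, x$grid$end, x$grid$step, x$degradation_form))
  invisible(x)
}
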