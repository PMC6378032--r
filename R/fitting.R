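# Synthetic longitudinal observations and parameter recovery by bounded
# nonlinear least squares. This is the forward/backward pair: the forward
# model generates noisy samples of its own trajectories; the backward step
# recovers free parameters from such samples.

# flat parameter names -> (component, key) used by fit_parameters
.PARAM_GROUP <- local({
  g <- c(stats::setNames(rep("rates", length(.RATE_NAMES)), .RATE_NAMES),
         stats::setNames(rep("caps", length(.CAP_NAMES)), .CAP_NAMES),
         stats::setNames(rep("host", length(.HOST_NAMES)), .HOST_NAMES),
         a_beta0 = "initial", tau_p0 = "initial", tau_o0 = "initial",
         n_deg0 = "initial", cog0 = "initial")
  g
})
.PARAM_KEY <- local({
  k <- c(stats::setNames(.RATE_NAMES, .RATE_NAMES),
         stats::setNames(.CAP_NAMES, .CAP_NAMES),
         stats::setNames(.HOST_NAMES, .HOST_NAMES),
         a_beta0 = "a_beta", tau_p0 = "tau_p", tau_o0 = "tau_o",
         n_deg0 = "n_deg", cog0 = "cog")
  k
})

#' Get or set scenario parameters by flat name
#'
#' Rates, capacities, host factors, and initial values are addressable by a
#' flat name: rate and capacity names as in the configuration (`lam_ab`,
#' `k_tp`, ...), host factors by name (`as_level`, `reserve_high`, ...),
#' and initial values with a `0` suffix (`a_beta0`, `tau_o0`, ...).
#'
#' @param config An `ad_scenario`.
#' @param params Named numeric vector of parameter values (`set_params`) or
#'   character vector of parameter names (`get_params`).
#' @return `set_params` returns the modified configuration; `get_params` a
#'   named numeric vector.
#' @export
set_params <- function(config, params) {
  stopifnot(inherits(config, "ad_scenario"))
  bad <- setdiff(names(params), names(.PARAM_GROUP))
  if (length(bad) || is.null(names(params))) {
    stop("unknown parameter name(s): ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
         call. = FALSE)
  }
  for (p in names(params)) {
    config[[.PARAM_GROUP[[p]]]][[.PARAM_KEY[[p]]]] <- as.numeric(params[[p]])
  }
  config
}

#' @rdname set_params
#' @export
get_params <- function(config, params) {
  stopifnot(inherits(config, "ad_scenario"))
  bad <- setdiff(params, names(.PARAM_GROUP))
  if (length(bad)) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  vapply(params, function(p) config[[.PARAM_GROUP[[p]]]][[.PARAM_KEY[[p]]]],
         numeric(1))
}

# run `code` under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

# simulate levels of the requested biomarkers at the given ages
.model_values <- function(config, ages, biomarkers, rtol = 1e-8,
                          atol = 1e-10) {
  t0 <- config$grid$start
  times <- sort(unique(c(t0, ages)))
  tr <- simulate_risk_pair(config, times = times, rtol = rtol, atol = atol)
  tr$cog <- tr$cog_high
  out <- lapply(biomarkers, function(m) {
    if (!m %in% names(tr)) {
      stop("unknown biomarker: ", m, call. = FALSE)
    }
    data.frame(age = ages, biomarker = m,
               value = tr[[m]][match(ages, tr$age)])
  })
  do.call(rbind, out)
}

#' Generate synthetic noisy observations
#'
#' Samples the model's own trajectory at the stated ages and adds
#' independent Gaussian noise (standard deviation `noise_sd` in level
#' units), truncated at zero because levels are non-negative. Reproducible
#' given `seed`; the caller's random-number stream is left untouched.
#'
#' @param config Generating `ad_scenario`.
#' @param ages Sampling ages (years), strictly increasing, within the
#'   configured age grid.
#' @param biomarkers Observed biomarkers; any of `a_beta`, `tau_p`,
#'   `tau_o`, `tau_total`, `n_deg`, `cog` (high-risk), `cog_low`,
#'   `cog_high`.
#' @param noise_sd Noise standard deviation (level units, >= 0).
#' @param seed Integer seed (optional).
#' @return An `ad_observations` data frame with columns `age`, `biomarker`,
#'   `value` and attributes `noise_sd`, `seed`, `truth_ref` (the
#'   generating configuration).
#' @examples
#' obs <- generate_observations(ad_preset("early_onset"),
#'                              ages = seq(0, 100, 10), noise_sd = 0.02,
#'                              seed = 7)
#' @export
generate_observations <- function(config, ages, biomarkers = "a_beta",
                                  noise_sd = 0, seed = NULL) {
  .assert_valid(config)
  if (is.unsorted(ages, strictly = TRUE)) {
    stop("ages must be strictly increasing", call. = FALSE)
  }
  if (min(ages) < config$grid$start || max(ages) > config$grid$end) {
    stop("ages fall outside the configured age grid [",
         config$grid$start, ", ", config$grid$end, "]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  obs <- .model_values(config, ages, biomarkers)
  obs$value <- .with_seed(seed, {
    pmax(0, obs$value + stats::rnorm(nrow(obs), 0, noise_sd))
  })
  structure(obs, class = c("ad_observations", "data.frame"),
            noise_sd = noise_sd, seed = seed, truth_ref = config)
}

#' Recover parameters from observations
#'
#' Fits the named free parameters of the cascade to an observation table by
#' bounded nonlinear least squares (Levenberg-Marquardt), minimizing the
#' sum of squared differences between simulated and observed levels at the
#' observation ages. Small identifiable subsets observed through their own
#' cascade (for example `lam_ab` and `a_beta0` from amyloid data alone)
#' recover well; freeing many rates at once from a single biomarker is
#' usually unidentifiable and will return a boundary or flat solution.
#'
#' @param obs Observations with columns `age`, `biomarker`, `value`.
#' @param base_config `ad_scenario` supplying every fixed parameter.
#' @param free Character vector of flat parameter names to fit (see
#'   [set_params()]).
#' @param bounds Optional named list of `c(lower, upper)` per free
#'   parameter; defaults: rates `[0, 1]`, capacities `[0.1, 10]`, initial
#'   values `[0, 1]` (amyloid `[1e-6, 1]`), host factors `[0, 50]`.
#' @param init Optional named numeric starting values (default: the
#'   base configuration's values, nudged inside the bounds).
#' @return A `fit_result`: list with `fitted_params`, `residual_ss`,
#'   `converged`, `n_evals`, `bounds`, and `config` (the base configuration
#'   with fitted values installed).
#' @export
fit_parameters <- function(obs, base_config, free, bounds = NULL,
                           init = NULL) {
  stopifnot(is.data.frame(obs))
  if (!all(c("age", "biomarker", "value") %in% names(obs))) {
    stop("observations need columns age, biomarker, value", call. = FALSE)
  }
  if (nrow(obs) == 0L) stop("no observations to fit", call. = FALSE)
  .assert_valid(base_config)
  bad <- setdiff(free, names(.PARAM_GROUP))
  if (length(bad)) {
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  ages <- sort(unique(obs$age))
  markers <- unique(obs$biomarker)
  residuals_for <- function(cfg) {
    sim <- .model_values(cfg, ages, markers)
    key <- paste(sim$biomarker, sim$age)
    sim$value[match(paste(obs$biomarker, obs$age), key)] - obs$value
  }

  if (length(free) == 0L) {
    r <- residuals_for(base_config)
    return(structure(list(fitted_params = stats::setNames(numeric(0), character(0)),
                          residual_ss = sum(r^2), converged = TRUE,
                          n_evals = 1L, bounds = list(),
                          config = base_config),
                     class = "fit_result"))
  }

  default_bound <- function(p) {
    switch(.PARAM_GROUP[[p]],
           rates = c(0, 1),
           caps = c(0.1, 10),
           host = c(0, 50),
           initial = if (p == "a_beta0") c(1e-6, 1) else c(0, 1))
  }
  bnd <- lapply(stats::setNames(free, free), function(p) {
    if (!is.null(bounds[[p]])) bounds[[p]] else default_bound(p)
  })
  lower <- vapply(bnd, `[`, numeric(1), 1L)
  upper <- vapply(bnd, `[`, numeric(1), 2L)
  start <- get_params(base_config, free)
  if (!is.null(init)) start[names(init)] <- unlist(init)
  if (any(start < lower | start > upper)) {
    stop("starting values fall outside the bounds", call. = FALSE)
  }
  start <- pmin(pmax(start, lower), upper)

  n_evals <- 0L
  fn <- function(p) {
    n_evals <<- n_evals + 1L
    names(p) <- free
    residuals_for(set_params(base_config, p))
  }
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-10, ptol = 1e-10, maxiter = 200))
  par <- fit$par
  names(par) <- free
  structure(list(fitted_params = par,
                 residual_ss = fit$deviance,
                 converged = fit$info %in% 1:4,
                 n_evals = n_evals,
                 bounds = bnd,
                 config = set_params(base_config, par)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(format_fit(x), sep = "\n")
  invisible(x)
}

#' Format a fit report
#'
#' @param x A `fit_result`.
#' @return Character vector of key-value lines.
#' @export
format_fit <- function(x) {
  stopifnot(inherits(x, "fit_result"))
  c(sprintf("%s: %.6g", names(x$fitted_params), x$fitted_params),
    sprintf("residual_ss: %.6e", x$residual_ss),
    sprintf("converged: %s", x$converged),
    sprintf("n_evals: %d", x$n_evals))
}

#' Read and write observation CSV files
#'
#' Observations are exchanged as CSV with columns `age`, `biomarker`,
#' `value`.
#'
#' @param obs An observation data frame.
#' @param path File path.
#' @return `write_observations` returns `path` invisibly;
#'   `read_observations` an `ad_observations` data frame.
#' @export
write_observations <- function(obs, path) {
  stopifnot(is.data.frame(obs))
  utils::write.csv(as.data.frame(obs)[c("age", "biomarker", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observation file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("age", "biomarker", "value") %in% names(df))) {
    stop("observation file needs columns age, biomarker, value", call. = FALSE)
  }
  structure(df, class = c("ad_observations", "data.frame"))
}
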