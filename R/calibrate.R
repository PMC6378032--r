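# Least-squares calibration of the logistic carrying capacities so that the
# capacity-bearing biomarkers reach the maximal level at the target age.

#' Calibrate carrying capacities
#'
#' Adjusts the four carrying capacities (`k_ab`, `k_tp`, `k_n`, `k_c`) by
#' bounded least squares so that amyloid, total tau, neurodegeneration, and
#' cognition all reach the maximal level (1 by default) at the target age
#' (100 years by default). This shapes all biomarker curves into sigmoids
#' that saturate together at the end of the lifespan. The SNAP-tau
#' component grows linearly and has no capacity of its own; it is captured
#' through total tau. The cognition target uses the high-risk reserve
#' curve, the one that saturates within the modeled horizon. Calibration is
#' always performed under the natural-history condition (`delta_ab = 0`);
#' for a therapy scenario the fitted capacities are frozen before the
#' degradation term is switched back on, so pre-therapy biomarker evolution
#' is untouched by the later intervention.
#'
#' @param config An `ad_scenario`.
#' @param target_age Age (years) at which the targets are evaluated; must
#'   lie within the configured age grid.
#' @param target_level Level every targeted biomarker should reach at
#'   `target_age`.
#' @param reserve Cognition curve used for the cognition target (default
#'   `"high"`).
#' @param lower,upper Per-capacity bounds for the optimizer.
#' @param rtol,atol Solver tolerances used inside the objective.
#' @return A `calibration_result`: list with `fitted_caps`, `residual_ss`,
#'   `converged`, `n_evals`, the achieved `levels` at `target_age`, and
#'   `config`, the input configuration with the fitted capacities installed
#'   (and its original `delta_ab` restored).
#' @examples
#' \donttest{
#' cal <- calibrate_capacities(ad_preset("early_onset"))
#' cal$fitted_caps
#' }
#' @export
calibrate_capacities <- function(config, target_age = 100, target_level = 1,
                                 reserve = "high",
                                 lower = rep(0.1, 4), upper = rep(10, 4),
                                 rtol = 1e-8, atol = 1e-10) {
  .assert_valid(config)
  if (all(config$rates == 0)) {
    stop("infeasible calibration: all growth rates are zero", call. = FALSE)
  }
  if (target_age <= config$grid$start || target_age > config$grid$end) {
    stop("target_age must lie within the configured age grid", call. = FALSE)
  }
  if (target_level <= 0) stop("target_level must be > 0", call. = FALSE)

  natural <- config
  natural$rates[["delta_ab"]] <- 0
  times <- c(config$grid$start, target_age)
  n_evals <- 0L

  levels_at_target <- function(kvec) {
    cfg <- natural
    cfg$caps[] <- kvec
    tr <- simulate(cfg, times = times, reserve = reserve,
                   rtol = rtol, atol = atol)
    last <- tr[nrow(tr), ]
    cogcol <- "cog"
    c(a_beta = last$a_beta, tau_total = last$tau_total,
      n_deg = last$n_deg, cog = last[[cogcol]])
  }
  objective <- function(kvec) {
    n_evals <<- n_evals + 1L
    levels_at_target(kvec) - target_level
  }

  fit <- minpack.lm::nls.lm(par = config$caps, lower = lower, upper = upper,
                            fn = objective,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-12, ptol = 1e-10, maxiter = 100))
  caps <- fit$par
  names(caps) <- names(config$caps)
  out_config <- config
  out_config$caps <- caps
  structure(list(
    fitted_caps = caps,
    residual_ss = fit$deviance,
    converged = fit$info %in% 1:4,
    n_evals = n_evals,
    target_age = target_age,
    target_level = target_level,
    levels = levels_at_target(caps),
    config = out_config
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(format_calibration(x), sep = "\n")
  invisible(x)
}

#' Format a calibration report
#'
#' Key-value text block with the fitted capacities, the achieved levels at
#' the target age, the residual sum of squares, and the convergence flag.
#'
#' @param x A `calibration_result`.
#' @return Character vector of report lines.
#' @export
format_calibration <- function(x) {
  stopifnot(inherits(x, "calibration_result"))
  c(sprintf("scenario: %s", x$config$name),
    sprintf("target: level %g at age %g", x$target_level, x$target_age),
    sprintf("%s: %.6f", names(x$fitted_caps), x$fitted_caps),
    sprintf("level_%s_at_target: %.6f", names(x$levels), x$levels),
    sprintf("residual_ss: %.3e", x$residual_ss),
    sprintf("converged: %s", x$converged),
    sprintf("n_evals: %d", x$n_evals))
}
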