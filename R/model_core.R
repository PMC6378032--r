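# Right-hand side of the biomarker cascade ODE system and its inputs.
#
# State vector (all levels dimensionless, nominally in [0, 1]):
#   a_beta  amyloid pathology
#   tau_p   amyloid-related phospho-tau pathology
#   tau_o   aging/SNAP-related tau pathology
#   n_deg   neuronal dysfunction/loss
#   cog     cognitive impairment
# Total tau is derived as tau_p + tau_o and never integrated separately.

.STATE_NAMES <- c("a_beta", "tau_p", "tau_o", "n_deg", "cog")

#' Heaviside step function (half-maximum convention)
#'
#' Returns 0 for negative arguments, 1 for positive arguments, and 1/2 at
#' zero. Used to switch the anti-amyloid therapy input on at a fixed age.
#'
#' @param n Numeric vector; must be finite.
#' @return Numeric vector of the same length with values in \{0, 1/2, 1\}.
#' @examples
#' heaviside(c(-5, 0, 3)) # 0, 0.5, 1
#' @export
heaviside <- function(n) {
  if (!is.numeric(n) || length(n) == 0L || any(!is.finite(n))) {
    stop("heaviside: 'n' must be finite numeric", call. = FALSE)
  }
  0.5 * (sign(n) + 1)
}

#' Anti-amyloid therapy input
#'
#' Evaluates the therapy forcing A_Rx(t): identically zero for an inactive
#' schedule, otherwise a Heaviside step switched on at the therapy onset age
#' and maintained thereafter.
#'
#' @param t Age in years (numeric vector, non-negative).
#' @param schedule Therapy schedule: a list with elements `active` (flag) and
#'   `onset_age` (years), as stored in a [scenario_config()].
#' @return Therapy level in \{0, 1/2, 1\} per age.
#' @export
therapy_input <- function(t, schedule) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("therapy_input: 't' must be finite numeric", call. = FALSE)
  }
  if (!isTRUE(schedule$active)) {
    return(rep(0, length(t)))
  }
  heaviside(t - schedule$onset_age)
}

#' Total tau level
#'
#' Total tau pathology is the sum of the amyloid-related (p-tau) and the
#' aging/SNAP-related components; it is a derived quantity, not an
#' integrated state.
#'
#' @param state Named numeric vector (or list) with elements `tau_p` and
#'   `tau_o`.
#' @return Total tau level.
#' @export
total_tau <- function(state) {
  state[["tau_p"]] + state[["tau_o"]]
}

#' Evaluate the cascade right-hand side
#'
#' Time derivative of the five-state biomarker cascade. Each cascade grows
#' logistically towards its carrying capacity; cross terms couple amyloid
#' into p-tau, both tau components into neurodegeneration, and
#' neurodegeneration (scaled by cognitive reserve) into cognition. Constant
#' host factors (amyloidopathy, aging/SNAP, ApoE risk) add linearly.
#' Anti-amyloid therapy withdraws amyloid at rate `delta_ab` while the step
#' input is on; with `degradation_form = "proportional"` the withdrawal is
#' scaled by the current amyloid level instead of being a constant sink.
#'
#' @param t Age in years.
#' @param state Named numeric vector with elements `a_beta`, `tau_p`,
#'   `tau_o`, `n_deg`, `cog`.
#' @param config A [scenario_config()].
#' @param reserve Which cognitive-reserve constant feeds the cognition
#'   equation: `"high"` (default) or `"low"`.
#' @param rx_level Optional override of the therapy input; if `NULL` it is
#'   computed from the config's schedule via [therapy_input()].
#' @return Named numeric vector of derivatives (level per year).
#' @examples
#' cfg <- ad_preset("early_onset")
#' cascade_rhs(0, c(a_beta = 0.05, tau_p = 0, tau_o = 0, n_deg = 0, cog = 0), cfg)
#' @export
cascade_rhs <- function(t, state, config, reserve = c("high", "low"),
                        rx_level = NULL) {
  reserve <- match.arg(reserve)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t)) {
    stop("cascade_rhs: 't' must be a finite scalar", call. = FALSE)
  }
  state <- unlist(state)[.STATE_NAMES]
  if (any(is.na(state)) || any(!is.finite(state))) {
    stop("cascade_rhs: state must supply finite ", paste(.STATE_NAMES, collapse = ", "),
         call. = FALSE)
  }
  r <- config$rates
  k <- config$caps
  h <- config$host
  if (any(!is.finite(c(r, k, unlist(h[c("a_o", "as_level", "eps", "reserve_low", "reserve_high")]))))) {
    stop("cascade_rhs: parameters must be finite", call. = FALSE)
  }
  R <- if (reserve == "high") h[["reserve_high"]] else h[["reserve_low"]]
  a_rx <- if (is.null(rx_level)) therapy_input(t, config$therapy) else rx_level
  ab <- state[["a_beta"]]; tp <- state[["tau_p"]]; to <- state[["tau_o"]]
  nd <- state[["n_deg"]]; cg <- state[["cog"]]
  withdrawal <- if (identical(config$degradation_form, "proportional")) {
    r[["delta_ab"]] * ab * a_rx
  } else {
    r[["delta_ab"]] * a_rx
  }
  tau <- tp + to
  d <- c(
    a_beta = r[["lam_ab"]] * ab * (k[["k_ab"]] - ab) +
      r[["lam_ab_ao"]] * h[["a_o"]] - withdrawal,
    tau_p = r[["lam_tp_ab"]] * ab + r[["lam_tp"]] * tp * (k[["k_tp"]] - tp),
    tau_o = r[["lam_to_as"]] * h[["as_level"]],
    n_deg = r[["lam_n_to"]] * (tau - tp) + r[["lam_n_tp"]] * tp +
      r[["lam_n"]] * nd * (k[["k_n"]] - nd) + r[["lam_n_as"]] * h[["as_level"]],
    cog = r[["lam_cn"]] * nd * R + r[["lam_c"]] * cg * (k[["k_c"]] - cg) +
      r[["lam_c_as"]] * h[["as_level"]] + r[["lam_c_eps"]] * h[["eps"]]
  )
  d
}
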