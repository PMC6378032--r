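# Numerical integration of the cascade over the age span.
#
# The therapy step input is handled by splitting the integration interval at
# the onset age, so the adaptive stepper never sees a discontinuous
# right-hand side. Levels are kept physical by a nonnegativity floor: the
# right-hand side is evaluated on the floored state and a component sitting
# at (or below) zero with an inward-pointing derivative is frozen, which is
# how a constant-sink withdrawal term behaves once amyloid is exhausted.
# Output levels are additionally clamped at zero.

.make_rhs <- function(config, reserves, rx) {
  r <- config$rates; k <- config$caps; h <- config$host
  proportional <- identical(config$degradation_form, "proportional")
  force(reserves); force(rx)
  function(t, y, parms) {
    ye <- pmax(y, 0)
    ab <- ye[1L]; tp <- ye[2L]; to <- ye[3L]; nd <- ye[4L]; cg <- ye[-(1:4)]
    tau <- tp + to
    withdrawal <- if (proportional) r[["delta_ab"]] * ab * rx
                  else r[["delta_ab"]] * rx
    d <- c(
      r[["lam_ab"]] * ab * (k[["k_ab"]] - ab) +
        r[["lam_ab_ao"]] * h[["a_o"]] - withdrawal,
      r[["lam_tp_ab"]] * ab + r[["lam_tp"]] * tp * (k[["k_tp"]] - tp),
      r[["lam_to_as"]] * h[["as_level"]],
      r[["lam_n_to"]] * (tau - tp) + r[["lam_n_tp"]] * tp +
        r[["lam_n"]] * nd * (k[["k_n"]] - nd) +
        r[["lam_n_as"]] * h[["as_level"]],
      r[["lam_cn"]] * nd * reserves + r[["lam_c"]] * cg * (k[["k_c"]] - cg) +
        r[["lam_c_as"]] * h[["as_level"]] + r[["lam_c_eps"]] * h[["eps"]]
    )
    d[y <= 0 & d < 0] <- 0
    list(d)
  }
}

.grid_times <- function(grid) {
  ages <- seq(grid$start, grid$end, by = grid$step)
  if (ages[length(ages)] < grid$end - 1e-9) ages <- c(ages, grid$end)
  ages
}

# Integrate the cascade for one or more cognitive-reserve values, splitting
# at the therapy onset age. `reserves` is a named vector; its names become
# the cognition column names.
.integrate_cascade <- function(config, times, reserves, rtol, atol) {
  y0 <- c(config$initial[c("a_beta", "tau_p", "tau_o", "n_deg")],
          rep(config$initial[["cog"]], length(reserves)))
  names(y0) <- c("a_beta", "tau_p", "tau_o", "n_deg", names(reserves))
  t0 <- times[1L]; tend <- times[length(times)]

  onset <- config$therapy$onset_age
  split <- isTRUE(config$therapy$active) && onset > t0 && onset < tend
  segments <- if (split) {
    list(list(from = t0, to = onset, rx = 0),
         list(from = onset, to = tend, rx = 1))
  } else {
    rx_whole <- if (isTRUE(config$therapy$active) && onset <= t0) 1 else 0
    list(list(from = t0, to = tend, rx = rx_whole))
  }

  rows <- vector("list", length(segments))
  y <- y0
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    # requested output times in this segment; the split point itself is
    # reported from the pre-therapy side
    keep <- times[times >= seg$from & times <= seg$to &
                    (i == length(segments) | times < seg$to)]
    tt <- sort(unique(c(seg$from, keep, seg$to)))
    sol <- deSolve::ode(y = y, times = tt,
                        func = .make_rhs(config, reserves, seg$rx),
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (anyNA(sol)) {
      stop(sprintf("integration failed on [%g, %g] (scenario '%s')",
                   seg$from, seg$to, config$name), call. = FALSE)
    }
    y <- sol[nrow(sol), -1L]
    rows[[i]] <- sol[sol[, "time"] %in% keep, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  state <- pmax(out[, -1L, drop = FALSE], 0)
  df <- data.frame(age = out[, "time"], state, check.names = FALSE)
  df$tau_total <- df$tau_p + df$tau_o
  df <- df[, c("age", "a_beta", "tau_p", "tau_o", "tau_total", "n_deg",
               names(reserves))]
  rownames(df) <- NULL
  df
}

#' Simulate a biomarker cascade scenario
#'
#' Integrates the five-state cascade from the configured initial state over
#' the scenario's age grid with an adaptive solver (relative tolerance
#' `1e-8`, absolute `1e-10` by default). If the therapy schedule is active,
#' integration is split exactly at the onset age. The result is
#' deterministic given the configuration and grid.
#'
#' @param object An `ad_scenario` configuration.
#' @param nsim,seed Unused (the model is deterministic); present for
#'   compatibility with the [stats::simulate()] generic.
#' @param grid Age grid (list with `start`, `end`, `step`); defaults to the
#'   configuration's grid.
#' @param reserve Which cognitive-reserve constant to use for the cognition
#'   equation: `"high"` (default) or `"low"`.
#' @param times Optional explicit output ages (overrides `grid`); must lie
#'   within the grid span and include its start.
#' @param rtol,atol Solver tolerances.
#' @param ... Ignored.
#' @return An `ad_trajectory`: a data frame with columns `age`, `a_beta`,
#'   `tau_p`, `tau_o`, `tau_total`, `n_deg`, `cog`, one row per output age,
#'   all levels floored at zero, with the generating configuration attached
#'   as attribute `config`.
#' @examples
#' traj <- simulate(ad_preset("early_onset"))
#' traj[traj$age == 100, ]
#' @export
simulate.ad_scenario <- function(object, nsim = 1, seed = NULL,
                                 grid = NULL, reserve = c("high", "low"),
                                 times = NULL, rtol = 1e-8, atol = 1e-10,
                                 ...) {
  reserve <- match.arg(reserve)
  .assert_valid(object)
  if (is.null(times)) {
    g <- if (is.null(grid)) object$grid else grid
    times <- .grid_times(g)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("output ages must be strictly increasing", call. = FALSE)
  }
  R <- object$host[[if (reserve == "high") "reserve_high" else "reserve_low"]]
  df <- .integrate_cascade(object, times, stats::setNames(R, "cog"),
                           rtol, atol)
  structure(df, class = c("ad_trajectory", "data.frame"),
            config = object, reserve = reserve)
}

#' Simulate the low- and high-risk cognition pair
#'
#' Runs the cascade once with both cognitive-reserve constants. Because
#' cognition feeds back into no other equation, the amyloid, tau, and
#' neurodegeneration trajectories are shared exactly between the two risk
#' groups; the two cognition curves are integrated side by side in a single
#' solver run.
#'
#' @inheritParams simulate.ad_scenario
#' @param config An `ad_scenario` carrying both `reserve_low` and
#'   `reserve_high`.
#' @return An `ad_trajectory` data frame with columns `age`, `a_beta`,
#'   `tau_p`, `tau_o`, `tau_total`, `n_deg`, `cog_low`, `cog_high`.
#' @examples
#' pair <- simulate_risk_pair(ad_preset("early_onset"))
#' @export
simulate_risk_pair <- function(config, grid = NULL, times = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  .assert_valid(config)
  if (is.null(times)) {
    g <- if (is.null(grid)) config$grid else grid
    times <- .grid_times(g)
  }
  reserves <- c(cog_low = config$host[["reserve_low"]],
                cog_high = config$host[["reserve_high"]])
  df <- .integrate_cascade(config, times, reserves, rtol, atol)
  structure(df, class = c("ad_trajectory", "data.frame"),
            config = config, reserve = "both")
}

#' Natural-history twin of a therapy scenario
#'
#' Returns the same configuration with the amyloid degradation rate set to
#' zero, i.e. the no-therapy natural history against which a treated run is
#' compared. The therapy schedule itself is kept, so treated and untreated
#' runs are integrated over identical segments and agree exactly before the
#' onset age.
#'
#' @param config An `ad_scenario`.
#' @return An `ad_scenario` with `delta_ab = 0`.
#' @export
natural_history_twin <- function(config) {
  stopifnot(inherits(config, "ad_scenario"))
  config$rates[["delta_ab"]] <- 0
  config$name <- paste0(config$name, "_natural")
  config
}

#' Read and write trajectory CSV files
#'
#' Trajectories are exchanged as plain CSV with an `age` column followed by
#' the biomarker level columns (`a_beta`, `tau_p`, `tau_o`, `tau_total`,
#' `n_deg`, and `cog` or `cog_low`/`cog_high`), one row per grid point.
#'
#' @param traj An `ad_trajectory`.
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns an `ad_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(is.data.frame(traj), "age" %in% names(traj))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!"age" %in% names(df)) {
    stop("trajectory file lacks an 'age' column: ", path, call. = FALSE)
  }
  structure(df, class = c("ad_trajectory", "data.frame"))
}

#' Plot a cascade trajectory
#'
#' Draws the biomarker curves in the conventional coloring (amyloid red,
#' total tau blue, neurodegeneration orange, cognition green; the low-risk
#' cognition curve is dashed). Curves are rendered with a display floor
#' (default 0.05) so that onset delays of the sigmoidal curves are visible
#' on a common baseline; the floor is cosmetic and never enters the
#' dynamics.
#'
#' @param x An `ad_trajectory`.
#' @param floor Display floor applied as `pmax(level, floor)`; set to 0 to
#'   disable.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ad_trajectory <- function(x, floor = 0.05, ...) {
  spec <- list(a_beta = c("amyloid", "red", 1),
               tau_total = c("total tau", "blue", 1),
               n_deg = c("neurodegeneration", "darkorange", 1),
               cog = c("cognition", "darkgreen", 1),
               cog_high = c("cognition (high risk)", "darkgreen", 1),
               cog_low = c("cognition (low risk)", "darkgreen", 2))
  cols <- intersect(names(spec), names(x))
  y <- pmax(as.matrix(x[cols]), floor)
  graphics::matplot(x$age, y, type = "l",
                    col = vapply(spec[cols], `[`, "", 2),
                    lty = as.numeric(vapply(spec[cols], `[`, "", 3)),
                    lwd = 2, xlab = "age (years)",
                    ylab = "normalized biomarker level", ...)
  graphics::legend("topleft", legend = vapply(spec[cols], `[`, "", 1),
                   col = vapply(spec[cols], `[`, "", 2),
                   lty = as.numeric(vapply(spec[cols], `[`, "", 3)),
                   lwd = 2, bty = "n")
  invisible(x)
}
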