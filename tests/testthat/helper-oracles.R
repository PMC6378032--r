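# Closed-form logistic solution used as an independent oracle for the
# decoupled cascades: dx/dt = lam * x * (K - x), x(0) = x0.
logistic_closed_form <- function(t, lam, K, x0) {
  K / (1 + ((K - x0) / x0) * exp(-lam * K * t))
}

# A configuration in which only one logistic cascade is active (all cross
# terms and host factors zero), so its trajectory must match the closed
# form. `state` is one of a_beta, tau_p, n_deg, cog.
decoupled_config <- function(state, lam = 0.08, K = 1, x0 = 0.05,
                             reserve = 1) {
  rate_of <- c(a_beta = "lam_ab", tau_p = "lam_tp", n_deg = "lam_n",
               cog = "lam_c")
  cap_of <- c(a_beta = "k_ab", tau_p = "k_tp", n_deg = "k_n", cog = "k_c")
  rates <- stats::setNames(rep(0, 14),
                           c("lam_ab", "lam_ab_ao", "delta_ab", "lam_tp_ab",
                             "lam_tp", "lam_to_as", "lam_n", "lam_n_tp",
                             "lam_n_to", "lam_n_as", "lam_c", "lam_cn",
                             "lam_c_as", "lam_c_eps"))
  rates[[rate_of[[state]]]] <- lam
  initial <- c(a_beta = 0, tau_p = 0, tau_o = 0, n_deg = 0, cog = 0)
  initial[[state]] <- x0
  caps <- c(k_ab = 1, k_tp = 1, k_n = 1, k_c = 1)
  caps[[cap_of[[state]]]] <- K
  scenario_config(name = paste0("decoupled_", state),
                  initial = initial, rates = rates, caps = caps,
                  host = c(a_o = 0, as_level = 0, eps = 0,
                           reserve_low = reserve, reserve_high = reserve))
}

# Stationary toy configuration: every capacity-bearing state starts at its
# carrying capacity with all cross terms off, so levels stay at 1 forever
# and the calibration objective is already zero.
stationary_config <- function() {
  cfg <- decoupled_config("a_beta", lam = 0.05, K = 1, x0 = 1)
  cfg$rates[c("lam_tp", "lam_n", "lam_c")] <- 0.05
  cfg$initial[c("tau_p", "n_deg", "cog")] <- 1
  cfg$name <- "stationary"
  cfg
}

# random valid configuration for round-trip / property tests (values kept
# at <= 6 significant digits, the precision a user would type)
random_config <- function() {
  rnd <- function(n, lo, hi) signif(runif(n, lo, hi), 6)
  scenario_config(
    name = paste0("rand_", paste(sample(letters, 6), collapse = "")),
    initial = c(a_beta = rnd(1, 0.001, 0.1), tau_p = 0,
                tau_o = rnd(1, 0, 0.05), n_deg = 0, cog = 0),
    rates = stats::setNames(rnd(14, 0, 0.1),
                            c("lam_ab", "lam_ab_ao", "delta_ab", "lam_tp_ab",
                              "lam_tp", "lam_to_as", "lam_n", "lam_n_tp",
                              "lam_n_to", "lam_n_as", "lam_c", "lam_cn",
                              "lam_c_as", "lam_c_eps")),
    caps = stats::setNames(rnd(4, 0.5, 2), c("k_ab", "k_tp", "k_n", "k_c")),
    host = c(a_o = rnd(1, 0, 1), as_level = rnd(1, 0, 2),
             eps = rnd(1, 0, 1), reserve_low = 1, reserve_high = 25),
    therapy = list(active = sample(c(TRUE, FALSE), 1),
                   onset_age = sample(40:80, 1) * 1.0)
  )
}
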