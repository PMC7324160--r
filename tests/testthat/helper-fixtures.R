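# Shared fixtures: the published best-fit network and random stable networks.

eq_params <- function() v1_fit_params()
eq_taus <- function() v1_fit_taus()

# Random parameter draw with a valid interior fixed point at L = 0 and a
# positive equilibrium determinant (saddle-free). `isn = TRUE` forces
# W_EE > 1, `isn = FALSE` forces W_EE < 1, NULL leaves it free.
random_stable_params <- function(isn = NULL) {
  repeat {
    W_EE <- if (isTRUE(isn)) runif(1, 1.2, 4) else if (isFALSE(isn))
      runif(1, 0, 0.9) else runif(1, 0, 4)
    p <- tryCatch(two_pop_params(
      W_EE = W_EE,
      W_EI = runif(1, 0.5, 3),
      W_IE = runif(1, 1, 9),
      W_II = runif(1, 0.5, 8),
      I_EX = runif(1, 2, 10),
      I_IX = runif(1, 10, 40),
      lambda = runif(1, 1, 8),
      tf_E = transfer_function(threshold = runif(1, 0, 3)),
      tf_I = transfer_function(threshold = runif(1, 0, 9))),
      error = function(e) NULL)
    if (is.null(p)) next
    if (model_determinant(p) < 0.2) next
    fp <- fixed_point(p, 0)
    if (fp$branch == "interior" && fp$r_E > 0.1 && fp$r_I > 0.1) return(p)
  }
}

# One synthetic unit as isn_units rows: Poisson counts around given mean
# rates for one phase on a laser grid.
make_unit <- function(unit_id, phase, laser, rates, trials = 100,
                      window_s = 0.3, session = "s01", width_ms = 0.5) {
  mu <- rep(rates * window_s, each = trials)
  data.frame(session = session, unit_id = unit_id, phase = phase,
             laser_mW = rep(laser, each = trials),
             trial = rep(seq_len(trials), times = length(laser)),
             spike_count = rpois(length(mu), mu), window_s = window_s,
             depth_um = 200, width_ms = width_ms)
}

small_config <- function(units_per_session = 20, trials_per_level = 50,
                         laser_mW = c(0, 0.5, 1, 1.5, 2, 3, 5, 8), ...) {
  generator_config(n_sessions = 1, units_per_session = units_per_session,
                   trials_per_level = trials_per_level,
                   laser_mW = laser_mW, L0_range = c(1, 1), ...)
}
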