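#' Default generator truth: the fitted V1 network
#'
#' The best-fit two-population parameters inferred from the three-phase V1
#' dataset (gains 1, rectified-linear): `W_EE = 2.56, W_EI = 1.77,
#' W_IE = 8.54, W_II = 7.11, I_EX = 8.51, I_IX = 34.16, x0_E = 1.19,
#' x0_I = 8.65, lambda = 6.3`. This network is an ISN (`W_EE > 1`) with a
#' paradoxical inhibitory dose-response.
#'
#' @return An [two_pop_params()] object.
#' @export
v1_fit_params <- function() {
  two_pop_params(W_EE = 2.56, W_EI = 1.77, W_IE = 8.54, W_II = 7.11,
                 I_EX = 8.51, I_IX = 34.16, lambda = 6.3,
                 tf_E = transfer_function(threshold = 1.19),
                 tf_I = transfer_function(threshold = 8.65))
}

#' Default generator time constants
#'
#' `tau_E = 7.8` ms and `tau_I = 34.3` ms, the values recovered from the
#' population response dynamics (ratio 4.4, inside the stable band).
#'
#' @return A [time_constants()] object.
#' @export
v1_fit_taus <- function() time_constants(7.8, 34.3)

#' Configuration of the synthetic-experiment generator
#'
#' Describes a synthetic optogenetic blocker experiment: the ground-truth
#' network, sessions with their own blocker efficacies and light-coupling
#' scale (`L0`, mW per normalized intensity unit), a laser grid in mW, trial
#' structure, the E/I unit mixture with log-normal rate heterogeneity, and
#' the waveform-width mixture. Defaults follow the experimental design the
#' generator emulates: 0-10 mW pulses of 600 ms with a 300 ms steady-state
#' window and 100 repetitions per level, ~80% excitatory units, width modes
#' at 0.58 ms (E) and 0.46 ms (I).
#'
#' @param truth Ground-truth [two_pop_params()].
#' @param taus Ground-truth [time_constants()].
#' @param n_sessions Number of recording sessions.
#' @param units_per_session Units recorded per session.
#' @param frac_E Fraction of excitatory units, in `(0, 1)`.
#' @param laser_mW Laser grid (mW), including 0 for baseline.
#' @param L0_range True per-session `L0` drawn uniformly from this range (mW).
#' @param eps_range Per-session blocker efficacies drawn uniformly from this
#'   range (both `eps_E` and `eps_I`).
#' @param trials_per_level Repetitions per intensity level.
#' @param pulse_ms Pulse duration (ms).
#' @param steady_window_ms Steady-state counting window at the end of the
#'   pulse (ms).
#' @param rate_sigma Log-normal sigma of the per-unit rate multiplier.
#' @param width_mean_E,width_mean_I,width_sd Waveform-width mixture (ms).
#' @param depth_range_um Uniform range of recording depths (metadata only).
#' @param overdispersion Trial-count dispersion: 0 gives Poisson counts;
#'   `d > 0` gives negative-binomial counts with variance `mu * (1 + d * mu)`.
#' @return An object of class `isn_genconfig`.
#' @export
generator_config <- function(truth = v1_fit_params(),
                             taus = v1_fit_taus(),
                             n_sessions = 2,
                             units_per_session = 40,
                             frac_E = 0.8,
                             laser_mW = c(0, 0.3, 0.5, 1, 1.5, 2, 3, 5, 7, 10),
                             L0_range = c(0.8, 1.6),
                             eps_range = c(0.25, 0.45),
                             trials_per_level = 100,
                             pulse_ms = 600,
                             steady_window_ms = 300,
                             rate_sigma = 0.5,
                             width_mean_E = 0.58, width_mean_I = 0.46,
                             width_sd = 0.05,
                             depth_range_um = c(100, 400),
                             overdispersion = 0) {
  stopifnot(inherits(truth, "isn_params"), inherits(taus, "isn_taus"),
            n_sessions >= 1, units_per_session >= 1,
            frac_E > 0, frac_E < 1, trials_per_level >= 1,
            pulse_ms > 0, steady_window_ms > 0, rate_sigma >= 0,
            overdispersion >= 0)
  structure(as.list(environment()), class = "isn_genconfig")
}

sim_counts <- function(n, mu, overdispersion) {
  if (overdispersion > 0)
    stats::rnbinom(n, size = 1 / overdispersion, mu = mu)
  else stats::rpois(n, mu)
}

#' Generate a synthetic unit-trial dataset
#'
#' For each session and phase, population mean rates are computed from the
#' ground-truth model ([apply_blockers()] + [fixed_point()]) on the laser
#' grid (mW converted to normalized intensity by the session's true `L0`).
#' Each unit's expected rate is the population rate times its log-normal
#' multiplier; trial spike counts are Poisson (optionally over-dispersed)
#' with mean `rate * steady_window`. Waveform widths are drawn from the
#' two-component Gaussian mixture tied to the true population labels.
#' Everything is determined by `seed`.
#'
#' @param config An [generator_config()].
#' @param seed Integer seed.
#' @return A list: `units` (an [isn_units] table) and `truth`, a sidecar list
#'   recording every latent (unit labels and multipliers, per-session
#'   efficacies and `L0`, the generator parameters).
#' @export
generate_dataset <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "isn_genconfig"))
  set.seed(seed)
  window_s <- config$steady_window_ms / 1000
  sessions <- sprintf("s%02d", seq_len(config$n_sessions))
  L0 <- stats::setNames(stats::runif(config$n_sessions,
                                     config$L0_range[1], config$L0_range[2]),
                        sessions)
  eps <- stats::setNames(lapply(sessions, function(s)
    blocker_efficacy(stats::runif(1, config$eps_range[1], config$eps_range[2]),
                     stats::runif(1, config$eps_range[1], config$eps_range[2]))),
    sessions)
  n_E <- round(config$frac_E * config$units_per_session)
  rows <- vector("list", 0)
  unit_meta <- vector("list", 0)
  for (s in sessions) {
    labels <- c(rep("E", n_E), rep("I", config$units_per_session - n_E))
    mult <- stats::rlnorm(config$units_per_session, 0, config$rate_sigma)
    widths <- ifelse(labels == "E",
                     stats::rnorm(config$units_per_session,
                                  config$width_mean_E, config$width_sd),
                     stats::rnorm(config$units_per_session,
                                  config$width_mean_I, config$width_sd))
    widths <- pmax(widths, 0.05)
    depths <- stats::runif(config$units_per_session,
                           config$depth_range_um[1], config$depth_range_um[2])
    ids <- sprintf("%s_u%03d", s, seq_len(config$units_per_session))
    Lnorm <- config$laser_mW / L0[s]
    pop_rate <- list()
    for (ph in isn_phases) {
      p <- apply_blockers(config$truth, ph, eps[[s]])
      fp <- fixed_point(p, Lnorm)
      if (any(fp$r_E < 0 | fp$r_I < 0))
        stop("configuration implies negative rates")
      pop_rate[[ph]] <- fp
    }
    nT <- config$trials_per_level
    for (k in seq_along(ids)) {
      for (ph in isn_phases) {
        base <- if (labels[k] == "E") pop_rate[[ph]]$r_E else pop_rate[[ph]]$r_I
        mu <- base * mult[k] * window_s
        cnt <- sim_counts(nT * length(mu), rep(mu, each = nT),
                          config$overdispersion)
        rows[[length(rows) + 1L]] <- data.frame(
          session = s, unit_id = ids[k], phase = ph,
          laser_mW = rep(config$laser_mW, each = nT),
          trial = rep(seq_len(nT), times = length(mu)),
          spike_count = cnt, window_s = window_s,
          depth_um = depths[k], width_ms = widths[k])
      }
      unit_meta[[length(unit_meta) + 1L]] <- data.frame(
        session = s, unit_id = ids[k], label = labels[k],
        multiplier = mult[k], width_ms = widths[k], depth_um = depths[k])
    }
  }
  units <- validate_units(do.call(rbind, rows))
  truth <- list(params = config$truth, taus = config$taus,
                labels = do.call(rbind, unit_meta),
                eps = eps, L0_mW = L0, seed = seed, config = config)
  list(units = units, truth = truth)
}

#' Generate synthetic PSTHs around a pulse onset
#'
#' Simulates the population rate dynamics for a step pulse at a given
#' normalized intensity, then draws per-trial Poisson bin counts for a
#' population of units (log-normal rate heterogeneity as in
#' [generate_dataset()]). Optionally deletes all spikes in the onset bin to
#' emulate the stimulation artifact that analysis must drop.
#'
#' @param config An [generator_config()].
#' @param L_level Pulse intensity in normalized units (default 2.6, a
#'   high-intensity pulse well above the inhibitory minimum).
#' @param n_units_I,n_units_E Units contributing to the I and E PSTHs.
#' @param n_trials Repetitions.
#' @param pre_ms,pulse_ms Baseline and pulse durations (ms).
#' @param bin_ms PSTH bin width (ms); a warning is given if larger than
#'   `tau_E`.
#' @param onset_artifact If `TRUE`, counts in the `t = 0` bin are zeroed.
#' @param seed Integer seed.
#' @return A list with `psth` (data frame `population, time_ms, rate, count,
#'   n_sweeps`: `rate` is the trial-and-unit averaged rate, `count` the
#'   summed count) and `truth` (the noiseless rate traces and latents).
#' @export
generate_dynamics <- function(config = generator_config(), L_level = 2.6,
                              n_units_I = 50, n_units_E = 100, n_trials = 100,
                              pre_ms = 100, pulse_ms = 800, bin_ms = 1,
                              onset_artifact = FALSE, seed = 1) {
  stopifnot(inherits(config, "isn_genconfig"))
  if (bin_ms > config$taus$tau_E)
    warning("bin width exceeds tau_E; dynamics will be under-resolved")
  set.seed(seed)
  laser <- laser_step(L_level, t_on = pre_ms, t_off = pre_ms + pulse_ms)
  tr <- simulate_dynamics(config$truth, config$taus, laser,
                          T_ms = pre_ms + pulse_ms, dt = 0.1)
  edges <- seq(0, pre_ms + pulse_ms, by = bin_ms)
  mids <- utils::head(edges, -1) + bin_ms / 2
  bin_of <- findInterval(tr$time_ms, edges, rightmost.closed = TRUE)
  rE_bin <- tapply(tr$r_E, bin_of, mean)[as.character(seq_along(mids))]
  rI_bin <- tapply(tr$r_I, bin_of, mean)[as.character(seq_along(mids))]
  out <- list()
  for (pop in c("E", "I")) {
    n_units <- if (pop == "E") n_units_E else n_units_I
    base <- if (pop == "E") rE_bin else rI_bin
    mult <- stats::rlnorm(n_units, 0, config$rate_sigma)
    ## summed counts over units and trials per bin: Poisson with summed mean
    mu <- base * (bin_ms / 1000) * sum(mult) * n_trials
    cnt <- stats::rpois(length(mu), mu)
    if (onset_artifact) # first bin at/after pulse onset carries the artifact
      cnt[which(mids >= pre_ms)[1]] <- 0
    rate <- cnt / (n_units * n_trials * bin_ms / 1000)
    out[[pop]] <- data.frame(population = pop, time_ms = mids - pre_ms,
                             rate = rate, count = cnt,
                             n_sweeps = n_units * n_trials)
  }
  list(psth = rbind(out$E, out$I),
       truth = list(trace = tr, onset_ms = pre_ms, L_level = L_level,
                    params = config$truth, taus = config$taus, seed = seed))
}
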