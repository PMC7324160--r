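#' @title Unit-trial tables
#' @description
#' Unit-level recordings are carried as a long-format data frame (class
#' `isn_units`) with one row per (unit, phase, laser intensity, trial):
#' columns `session`, `unit_id`, `phase` (one of `intact`, `e_blocked`,
#' `ei_blocked`), `laser_mW`, `trial`, `spike_count`, `window_s` (duration of
#' the steady-state counting window, s), and optionally `depth_um` and
#' `width_ms`. Steady-state rate is always `spike_count / window_s`.
#' @name isn_units
NULL

unit_required_cols <- c("session", "unit_id", "phase", "laser_mW", "trial",
                        "spike_count", "window_s")

validate_units <- function(units) {
  miss <- setdiff(unit_required_cols, names(units))
  if (length(miss))
    stop("unit table missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!units$phase %in% isn_phases)
  if (length(bad))
    stop("unknown phase label at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(units$spike_count) | units$spike_count < 0)
  if (length(bad))
    stop("negative or non-finite spike_count at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(units$window_s) | units$window_s <= 0)
  if (length(bad))
    stop("non-positive window_s at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  if (!inherits(units, "isn_units")) class(units) <- c("isn_units", class(units))
  units
}

unit_rows <- function(units, unit_id) {
  units[units$unit_id == unit_id, , drop = FALSE]
}

## Per-trial steady-state rates of one unit at a given phase and intensity.
trial_rates <- function(unit, phase, laser_mW) {
  sel <- unit$phase == phase & unit$laser_mW == laser_mW
  unit$spike_count[sel] / unit$window_s[sel]
}

welch_classify <- function(unit, phase, alpha, method) {
  u <- unit[unit$phase == phase, , drop = FALSE]
  if (nrow(u) == 0)
    stop("unit has no '", phase, "' trials; classification method unavailable")
  Ls <- sort(unique(u$laser_mW))
  if (length(Ls) < 2 || min(Ls) > 0)
    stop("classification requires baseline (L = 0) and maximum-intensity trials")
  base <- trial_rates(u, phase, 0)
  top <- trial_rates(u, phase, max(Ls))
  effect <- mean(top) - mean(base)
  ## Welch's unequal-variance t-test; degenerate (constant) samples cannot be
  ## tested and count as no detectable increase.
  p <- if (stats::var(base) + stats::var(top) == 0) 1 else
    tryCatch(stats::t.test(top, base)$p.value, error = function(e) 1)
  label <- if (effect > 0 && p < alpha) "I" else "E"
  list(label = label, method = method, p_value = p, effect = effect)
}

#' Classify a unit as excitatory or inhibitory by pharmacology
#'
#' With both excitatory and inhibitory synapses blocked, only opsin-expressing
#' (inhibitory) cells respond to the laser. The unit's per-trial steady-state
#' rates at the maximum laser intensity are compared with its baseline
#' (`L = 0`) rates within the `ei_blocked` phase using Welch's
#' unequal-variance t-test; the unit is labeled inhibitory iff the mean
#' change is positive and `p < alpha`.
#'
#' @param unit Rows of an [isn_units] table belonging to one unit.
#' @param alpha Significance level (default 0.01).
#' @return List with `label` (`"E"`/`"I"`), `method`, `p_value`, `effect`
#'   (rate change, spk/s).
#' @export
classify_pharma <- function(unit, alpha = 0.01) {
  welch_classify(unit, "ei_blocked", alpha, "pharma")
}

#' Classify a unit by its response at high laser power
#'
#' In an ISN, sufficiently strong stimulation silences the excitatory
#' population and inhibitory rates rise above baseline; units with a
#' statistically significant positive rate change at maximum intensity in the
#' *intact* phase are labeled inhibitory. The same Welch test as
#' [classify_pharma()] is used. This criterion is deliberately stringent: an
#' inhibitory unit that stays below baseline at every tested intensity is
#' (knowingly) missed.
#'
#' @inheritParams classify_pharma
#' @return As [classify_pharma()], with `method = "high_power"`.
#' @export
classify_high_power <- function(unit, alpha = 0.01) {
  welch_classify(unit, "intact", alpha, "high_power")
}

#' Classify every unit in a table
#'
#' @param units An [isn_units] table.
#' @param method `"pharma"` or `"high_power"`.
#' @param alpha Significance level.
#' @return Data frame `unit_id, session, label, p_value, effect`.
#' @export
classify_units <- function(units, method = c("pharma", "high_power"), alpha = 0.01) {
  units <- validate_units(units)
  method <- match.arg(method)
  fn <- if (method == "pharma") classify_pharma else classify_high_power
  ids <- unique(units$unit_id)
  rows <- lapply(ids, function(id) {
    u <- unit_rows(units, id)
    r <- fn(u, alpha)
    data.frame(unit_id = id, session = u$session[1], label = r$label,
               p_value = r$p_value, effect = r$effect)
  })
  do.call(rbind, rows)
}

#' Classify units by waveform width
#'
#' Fits a kernel density to the distribution of spike waveform widths, finds
#' the local minimum between the two dominant modes (narrow fast-spiking
#' inhibitory cells vs. broad regular-spiking excitatory cells), and labels
#' units below the threshold inhibitory.
#'
#' @param units An [isn_units] table with a `width_ms` column (one width per
#'   unit); at least 20 units are required for a stable density fit.
#' @param bandwidth Optional kernel bandwidth (ms); default `stats::bw.nrd0`.
#' @return List with `result` (data frame `unit_id, width_ms, label`),
#'   `threshold_ms`, and the fitted `density`.
#' @export
classify_width <- function(units, bandwidth = NULL) {
  units <- validate_units(units)
  if (!"width_ms" %in% names(units)) stop("unit table has no width_ms column")
  w <- tapply(units$width_ms, units$unit_id, function(v) v[1])
  w <- w[order(names(w))]
  if (length(w) < 20) stop("at least 20 units are required for the density fit")
  d <- if (is.null(bandwidth)) stats::density(w) else stats::density(w, bw = bandwidth)
  y <- d$y
  ## interior local maxima / minima of the density curve
  dy <- diff(y)
  turn <- diff(sign(dy))
  maxima <- which(turn < 0) + 1L
  minima <- which(turn > 0) + 1L
  if (length(maxima) < 2)
    stop("waveform-width density is unimodal; width classification undefined")
  top2 <- maxima[order(y[maxima], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- minima[minima > lo & minima < hi]
  if (length(between) == 0)
    stop("no density minimum between the two dominant modes")
  thr_idx <- between[which.min(y[between])]
  threshold <- d$x[thr_idx]
  res <- data.frame(unit_id = names(w), width_ms = as.numeric(w),
                    label = ifelse(w < threshold, "I", "E"),
                    row.names = NULL)
  list(result = res, threshold_ms = threshold, density = d)
}

#' Per-session laser normalization from the inhibitory minimum
#'
#' Fits a continuous two-segment piecewise-linear function (free breakpoint)
#' to the average inhibitory dose-response curve by least squares (grid
#' search over interior breakpoints refined with [stats::optimize()]). The
#' breakpoint `L0` is the intensity at the inhibitory minimum and defines the
#' normalized intensity scale `L / L0`. If the best-fit first-segment slope
#' is non-negative the response carries no paradoxical suppression and `L0`
#' is undefined.
#'
#' @param mean_I_response Data frame with columns `laser_mW` and `rate`
#'   (average inhibitory rate, spk/s); at least 4 intensity levels.
#' @return An object of class `isn_norm`: `L0_mW`, `intercept`, `slope1`,
#'   `slope2`, `sse`, `paradoxical` (logical; `L0_mW` is `NA` when `FALSE`).
#' @export
find_L0 <- function(mean_I_response) {
  stopifnot(all(c("laser_mW", "rate") %in% names(mean_I_response)))
  x <- mean_I_response$laser_mW
  y <- mean_I_response$rate
  o <- order(x); x <- x[o]; y <- y[o]
  if (length(unique(x)) < 4) stop("at least 4 intensity levels are required")
  fit_at <- function(c0) {
    X <- cbind(1, x, pmax(x - c0, 0))
    f <- stats::lsfit(X, y, intercept = FALSE)
    sum(f$residuals^2)
  }
  grid <- seq(x[2], x[length(x) - 1], length.out = 50)
  sses <- vapply(grid, fit_at, 0)
  c0 <- grid[which.min(sses)]
  span <- diff(range(grid)) / 49
  opt <- stats::optimize(fit_at, c(max(min(grid), c0 - span), min(max(grid), c0 + span)))
  c0 <- opt$minimum
  X <- cbind(1, x, pmax(x - c0, 0))
  f <- stats::lsfit(X, y, intercept = FALSE)
  b <- f$coefficients
  paradoxical <- b[2] < 0
  structure(list(L0_mW = if (paradoxical) c0 else NA_real_,
                 intercept = unname(b[1]), slope1 = unname(b[2]),
                 slope2 = unname(b[2] + b[3]), sse = sum(f$residuals^2),
                 paradoxical = unname(paradoxical)),
            class = "isn_norm")
}

#' @export
print.isn_norm <- function(x, ...) {
  cat("<isn_norm>")
  if (x$paradoxical)
    cat(sprintf(" L0 = %.4g mW (slopes %.3g / %.3g)\n", x$L0_mW, x$slope1, x$slope2))
  else cat(" no paradoxical minimum (first-segment slope >= 0); L0 undefined\n")
  invisible(x)
}

#' Initial slope of a unit's dose-response
#'
#' Ordinary least-squares slope of the unit's mean steady-state rate against
#' normalized laser intensity, over the sub-minimum range `[0, 1]` (at least
#' two intensity levels). The normalized slope divides by
#' `baseline + 0.1 spk/s`; the small regularizer keeps near-silent units
#' finite and bounds normalized slopes below by -1 on the `[0, 1]` range.
#'
#' @param unit Rows of an [isn_units] table for one unit.
#' @param normalization An [find_L0()] result for the unit's session, or a
#'   positive number used directly as `L0` (mW).
#' @param phase Phase whose response is summarized (default `"intact"`).
#' @return List with `raw_slope` (spk/s per normalized intensity unit),
#'   `normalized_slope`, `baseline_rate` (spk/s).
#' @export
initial_slope <- function(unit, normalization, phase = "intact") {
  L0 <- if (inherits(normalization, "isn_norm")) normalization$L0_mW else normalization
  if (!is.finite(L0) || L0 <= 0) stop("normalization must provide a positive L0")
  u <- unit[unit$phase == phase, , drop = FALSE]
  if (nrow(u) == 0) stop("unit has no trials in phase '", phase, "'")
  rate <- tapply(u$spike_count / u$window_s, u$laser_mW, mean)
  Ln <- as.numeric(names(rate)) / L0
  keep <- Ln <= 1 + 1e-9
  if (sum(keep) < 2) stop("fewer than 2 intensity levels at or below L0")
  fit <- stats::lm(r ~ l, data = data.frame(r = as.numeric(rate[keep]), l = Ln[keep]))
  baseline <- if (any(Ln == 0)) as.numeric(rate[Ln == 0]) else as.numeric(rate[1])
  raw <- unname(stats::coef(fit)[2])
  list(raw_slope = raw,
       normalized_slope = raw / (baseline + 0.1),
       baseline_rate = baseline)
}

#' Population-average dose-response with summed-count SEM
#'
#' Averages unit mean rates per intensity for the requested population, and
#' computes the SEM on the *summed* counts: within each intensity, spike
#' counts are summed over units within each trial, converted to a per-unit
#' rate, and the SEM is taken across trials. This is the population-level
#' uncertainty appropriate for Poisson-like counts.
#'
#' @param units An [isn_units] table.
#' @param labels Data frame with `unit_id` and `label` columns (e.g. from
#'   [classify_units()]), or a named character vector.
#' @param population `"E"` or `"I"`.
#' @param phase Phase to summarize.
#' @return Data frame `laser_mW, mean_rate, sem, n_units`.
#' @export
population_average <- function(units, labels, population, phase = "intact") {
  units <- validate_units(units)
  if (is.data.frame(labels)) labels <- stats::setNames(labels$label, labels$unit_id)
  ids <- names(labels)[labels == population]
  u <- units[units$unit_id %in% ids & units$phase == phase, , drop = FALSE]
  if (nrow(u) == 0) stop("no trials for population '", population, "' in phase '", phase, "'")
  n_units <- length(unique(u$unit_id))
  out <- lapply(split(u, u$laser_mW), function(g) {
    mean_rate <- mean(tapply(g$spike_count / g$window_s, g$unit_id, mean))
    summed <- tapply(g$spike_count, g$trial, sum)
    trial_rate <- summed / (g$window_s[1] * n_units)
    data.frame(laser_mW = g$laser_mW[1], mean_rate = mean_rate,
               sem = stats::sd(trial_rate) / sqrt(length(trial_rate)),
               n_units = n_units)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$laser_mW), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect the brief inhibitory transient after stimulus onset
#'
#' ISN operation requires inhibitory cells to transiently increase firing
#' before the paradoxical steady-state suppression. Given a trial-averaged
#' population PSTH at 1 ms resolution, the onset bin (`t = 0`, which carries
#' a stimulation artifact) is dropped, and the binned rates in the 1-12 ms
#' post-onset window are compared with a matched-duration window immediately
#' before onset using a two-sample KS test. Peak amplitude, latency, FWHM
#' (linear interpolation at half-maximum on the smoothed PSTH) and the time
#' at which the rate crosses back below baseline are reported, together with
#' the baseline-normalized transient and steady-state rates.
#'
#' @param psth Data frame with columns `time_ms` (1 ms bins, including at
#'   least 12 ms before onset) and `rate` (spk/s).
#' @param onset_ms Pulse onset time (ms).
#' @param window Post-onset test window (ms after onset), default `c(1, 12)`.
#' @param alpha Significance level for the KS test.
#' @param smooth_ms Boxcar smoothing width (ms) for peak/FWHM measurement.
#' @param steady_ms Window (ms) at the end of the trace over which the
#'   steady-state rate is measured.
#' @return An object of class `isn_transient` with fields `significant`,
#'   `p_value`, `peak_amplitude` (spk/s above baseline), `latency_to_peak_ms`,
#'   `fwhm_ms`, `crossing_time_ms`, `normalized_transient`,
#'   `normalized_steady_state`, `baseline_rate`.
#' @export
detect_transient <- function(psth, onset_ms = 0, window = c(1, 12),
                             alpha = 0.01, smooth_ms = 3, steady_ms = 100) {
  stopifnot(all(c("time_ms", "rate") %in% names(psth)))
  t <- psth$time_ms - onset_ms
  r <- psth$rate
  win_len <- window[2] - window[1] + 1
  pre_sel <- t >= -win_len & t < 0
  if (sum(pre_sel) < win_len)
    stop("insufficient pre-pulse baseline: need at least ", win_len, " ms before onset")
  post_sel <- t >= window[1] & t <= window[2]
  pre <- r[pre_sel]
  post <- r[post_sel]
  ks <- suppressWarnings(stats::ks.test(post, pre))
  baseline <- mean(r[t < 0])
  ## smoothed trace for amplitude/shape measurements; onset bin excluded
  keep <- t < 0 | t >= 1
  ts <- t[keep]; rs <- r[keep]
  k <- max(1L, as.integer(smooth_ms))
  sm <- stats::filter(rs, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- rs[is.na(sm)]
  sm <- as.numeric(sm)
  post_idx <- which(ts >= window[1] & ts <= max(window[2] * 2, window[2]))
  pk <- post_idx[which.max(sm[post_idx])]
  peak_amp <- sm[pk] - baseline
  latency <- ts[pk]
  half <- baseline + peak_amp / 2
  cross_at <- function(i, j) {
    # linear interpolation of the time where sm crosses `half` between bins
    ts[i] + (half - sm[i]) / (sm[j] - sm[i]) * (ts[j] - ts[i])
  }
  left <- NA_real_; right <- NA_real_
  i <- pk
  while (i > 1 && sm[i] > half && ts[i] > 0) i <- i - 1
  if (sm[i] <= half) left <- cross_at(i, i + 1)
  j <- pk
  while (j < length(sm) && sm[j] > half) j <- j + 1
  if (j <= length(sm) && sm[j] <= half) right <- cross_at(j, j - 1)
  fwhm <- right - left
  ## first downward crossing of baseline after the peak
  after <- which(ts > ts[pk] & sm < baseline)
  crossing <- if (length(after)) {
    j <- after[1]
    ts[j - 1] + (baseline - sm[j - 1]) / (sm[j] - sm[j - 1]) * (ts[j] - ts[j - 1])
  } else NA_real_
  steady_sel <- ts >= max(ts) - steady_ms
  steady <- mean(rs[steady_sel])
  structure(list(significant = ks$p.value < alpha && mean(post) > mean(pre),
                 p_value = ks$p.value,
                 peak_amplitude = peak_amp,
                 latency_to_peak_ms = latency,
                 fwhm_ms = fwhm,
                 crossing_time_ms = crossing,
                 normalized_transient = peak_amp / baseline,
                 normalized_steady_state = (steady - baseline) / baseline,
                 baseline_rate = baseline),
            class = "isn_transient")
}

#' Model-predicted currents into excitatory cells
#'
#' Decomposes the net input current to the excitatory population at the
#' interior fixed point into its excitatory (`(W_EE r_E + I_EX) / x0_E`) and
#' inhibitory (`-W_EI r_I / x0_E`) parts, in units of the excitatory
#' threshold. At the fixed point (unit gain, `r_E > 0`) the identity
#' `net = (r_E + x0_E) / x0_E` holds.
#'
#' @param params An [two_pop_params()] object.
#' @param L Laser intensity (scalar or vector).
#' @return Data frame `L, E_current, I_current, net` (threshold units) or,
#'   when `x0_E = 0`, raw currents (spk/s-equivalent) with a warning.
#' @export
currents_into_E <- function(params, L) {
  fp <- fixed_point(params, L)
  x0E <- params$tf_E$threshold
  scale <- if (x0E == 0) {
    warning("x0_E = 0: reporting raw currents, not threshold units")
    1
  } else x0E
  E_cur <- (params$W_EE * fp$r_E + params$I_EX) / scale
  I_cur <- -params$W_EI * fp$r_I / scale
  data.frame(L = fp$L, E_current = E_cur, I_current = I_cur,
             net = E_cur + I_cur)
}
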