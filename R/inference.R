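#' Dose-response dataset for parameter inference
#'
#' Assembles per-(session, phase, population) dose-response curves into the
#' container consumed by [fit_global()]. Intact-phase data are typically
#' pooled across sessions (use `session = "pooled"`); blocker-phase curves
#' keep session identity because blocker efficacies vary by session.
#'
#' @param df Data frame with columns `session`, `phase` (one of
#'   `intact`, `e_blocked`, `ei_blocked`), `population` (`"E"`/`"I"`), `L`
#'   (normalized laser intensity), `rate` (mean rate, spk/s) and optionally
#'   `sem` and `n_units`.
#' @return An object of class `isn_dataset`.
#' @export
dose_response_dataset <- function(df) {
  need <- c("session", "phase", "population", "L", "rate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("dataset missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("empty dataset")
  if (!all(df$phase %in% isn_phases)) stop("unknown phase labels in dataset")
  if (!all(df$population %in% c("E", "I"))) stop("population must be 'E' or 'I'")
  if (any(!is.finite(df$rate) | df$rate < 0)) stop("rates must be finite and non-negative")
  key <- interaction(df$session, df$phase, df$population, drop = TRUE)
  for (g in split(df, key)) {
    if (anyDuplicated(g$L))
      stop("intensities must be strictly increasing within each curve")
  }
  if (!"sem" %in% names(df)) df$sem <- NA_real_
  df <- df[order(df$phase, df$session, df$population, df$L), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("isn_dataset", class(df))
  df
}

#' Model dose-response curves from known parameters
#'
#' Generates the (noiseless) mean population curves the equilibrium model
#' predicts at a set of intensities in the three pharmacological phases — the
#' forward map used both for fitting and for generate-then-recover tests.
#' The intact phase is pooled (one curve); blocker phases are produced per
#' session with that session's efficacies.
#'
#' @param params An [two_pop_params()] object (generator truth).
#' @param L Numeric vector of normalized intensities.
#' @param eps_by_session Named list of [blocker_efficacy()] objects, one per
#'   session.
#' @param phases Which phases to include.
#' @return An [dose_response_dataset()].
#' @export
model_dose_response <- function(params, L, eps_by_session,
                                phases = isn_phases) {
  rows <- list()
  if ("intact" %in% phases) {
    fp <- fixed_point(params, L)
    rows[[1]] <- data.frame(session = "pooled", phase = "intact",
                            population = rep(c("E", "I"), each = length(L)),
                            L = c(L, L), rate = c(fp$r_E, fp$r_I))
  }
  for (s in names(eps_by_session)) {
    for (ph in intersect(c("e_blocked", "ei_blocked"), phases)) {
      p2 <- apply_blockers(params, ph, eps_by_session[[s]])
      fp <- fixed_point(p2, L)
      rows[[length(rows) + 1L]] <- data.frame(
        session = s, phase = ph,
        population = rep(c("E", "I"), each = length(L)),
        L = c(L, L), rate = c(fp$r_E, fp$r_I))
    }
  }
  dose_response_dataset(do.call(rbind, rows))
}

## Internal: flatten an isn_dataset plus a parameter vector into residuals.
## theta layout: 9 structural parameters
##   (W_EE, W_EI, W_IE, W_II, I_EX, I_IX, x0_E, x0_I, lambda)
## followed by eps_E per session then eps_I per session.
structural_names <- c("W_EE", "W_EI", "W_IE", "W_II", "I_EX", "I_IX",
                      "x0_E", "x0_I", "lambda")

dataset_env <- function(dataset) {
  blocker_sessions <- sort(unique(dataset$session[dataset$phase != "intact"]))
  list(L = dataset$L,
       is_E = dataset$population == "E",
       eE_on = dataset$phase %in% c("e_blocked", "ei_blocked"),
       eI_on = dataset$phase == "ei_blocked",
       sess_idx = match(dataset$session, blocker_sessions),
       sessions = blocker_sessions,
       y = dataset$rate,
       w = if (all(is.finite(dataset$sem)) && all(dataset$sem > 0))
         1 / dataset$sem else rep(1, nrow(dataset)))
}

residual_vec <- function(theta, env, weighted = FALSE) {
  p <- theta[1:9]
  nS <- length(env$sessions)
  epsE <- if (nS) theta[10:(9 + nS)] else numeric(0)
  epsI <- if (nS) theta[(10 + nS):(9 + 2 * nS)] else numeric(0)
  eE <- ifelse(env$eE_on, epsE[env$sess_idx], 1)
  eI <- ifelse(env$eI_on, epsI[env$sess_idx], 1)
  eE[is.na(eE)] <- 1; eI[is.na(eI)] <- 1
  fp <- fixed_point_vec(W_EE = eE * p[1], W_EI = eI * p[2],
                        W_IE = eE * p[3], W_II = eI * p[4],
                        I_EX = eE * p[5], I_IX = eE * p[6],
                        x0_E = p[7], x0_I = p[8], lambda = p[9], L = env$L)
  pred <- ifelse(env$is_E, fp$r_E, fp$r_I)
  res <- pred - env$y
  if (weighted) res * env$w else res
}

#' Residual sum of squares of a parameter set on a dataset
#'
#' Sum over all curve points of the squared difference between observed mean
#' rates and the rates predicted by [apply_blockers()] + [fixed_point()].
#' Points where the effective model is singular contribute a large finite
#' penalty rather than an error, which keeps the loss usable inside
#' optimizers.
#'
#' @param params An [two_pop_params()] object.
#' @param eps_map Named list of [blocker_efficacy()] objects per session
#'   present in the blocker phases.
#' @param dataset An [dose_response_dataset()].
#' @param weight_sem If `TRUE` and the dataset carries positive SEMs,
#'   residuals are divided by the SEM before squaring.
#' @return Non-negative scalar.
#' @export
residual_loss <- function(params, eps_map, dataset, weight_sem = FALSE) {
  stopifnot(inherits(params, "isn_params"), inherits(dataset, "isn_dataset"))
  env <- dataset_env(dataset)
  g <- absorb_gains(params)
  theta <- c(g$W_EE, g$W_EI, g$W_IE, g$W_II, g$I_EX, g$I_IX,
             g$x0_E, g$x0_I, g$lambda,
             vapply(env$sessions, function(s) eps_map[[s]]$eps_E, 0),
             vapply(env$sessions, function(s) eps_map[[s]]$eps_I, 0))
  sum(residual_vec(theta, env, weighted = weight_sem)^2)
}

#' Global multi-restart least-squares fit of the two-population model
#'
#' Infers the 9 structural equilibrium parameters (4 weights, 2 external
#' inputs, 2 thresholds, opsin efficacy; gains pinned at 1) plus one
#' `(eps_E, eps_I)` blocker-efficacy pair per session from three-phase
#' dose-response curves. Each restart draws an i.i.d. uniform starting point
#' (structural parameters on `init_range`, efficacies on `[0, 1]`) and runs
#' bounded Levenberg-Marquardt least squares (all parameters constrained
#' non-negative, efficacies in `[0, 1]`); the restart with minimal residual
#' sum of squares wins. The result is deterministic given `seed`.
#'
#' With fewer than three phases only parameter ratios are identifiable (the
#' equilibrium is invariant under a two-parameter rescaling family), so a
#' warning is raised and the fit proceeds anyway.
#'
#' @param dataset An [dose_response_dataset()].
#' @param n_restarts Number of random restarts (default 1000; increase to
#'   10^4 for the most exhaustive search).
#' @param init_range Range of the uniform restart distribution for the
#'   structural parameters.
#' @param seed Integer seed making the restart sequence reproducible.
#' @param weight_sem Passed to the residual (see [residual_loss()]).
#' @return An object of class `isn_fit`: `params` (an [two_pop_params()]),
#'   `eps` (named list of [blocker_efficacy()] per session), `sse`,
#'   `n_restarts`, `best_restart` (index of the winning restart).
#' @export
fit_global <- function(dataset, n_restarts = 1000, init_range = c(0, 10),
                       seed = NULL, weight_sem = FALSE) {
  stopifnot(inherits(dataset, "isn_dataset"))
  if (nrow(dataset) == 0) stop("empty dataset")
  phases <- unique(dataset$phase)
  if (length(phases) < 3)
    warning("dataset covers ", length(phases),
            " phase(s): parameters are identifiable only up to the ",
            "equilibrium rescaling family")
  env <- dataset_env(dataset)
  nS <- length(env$sessions)
  npar <- 9 + 2 * nS
  lower <- rep(0, npar)
  upper <- c(rep(Inf, 9), rep(1, 2 * nS))
  if (!is.null(seed)) set.seed(seed)
  best <- NULL; best_sse <- Inf; best_i <- NA_integer_
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
  for (i in seq_len(n_restarts)) {
    start <- c(stats::runif(9, init_range[1], init_range[2]),
               stats::runif(2 * nS, 0, 1))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = residual_vec, env = env, weighted = weight_sem,
                         control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (sse < best_sse) { best_sse <- sse; best <- fit$par; best_i <- i }
  }
  if (is.null(best)) stop("all restarts failed")
  params <- two_pop_params(best[1], best[2], best[3], best[4], best[5], best[6],
                           lambda = best[9],
                           tf_E = transfer_function(threshold = best[7]),
                           tf_I = transfer_function(threshold = best[8]))
  eps <- stats::setNames(lapply(seq_len(nS), function(s)
    blocker_efficacy(best[9 + s], best[9 + nS + s])), env$sessions)
  structure(list(params = params, eps = eps, sse = best_sse,
                 n_restarts = n_restarts, best_restart = best_i),
            class = "isn_fit")
}

#' @export
print.isn_fit <- function(x, ...) {
  cat("<isn_fit> sse =", format(x$sse, digits = 6),
      "(", x$n_restarts, "restarts, best #", x$best_restart, ")\n")
  print(x$params)
  for (s in names(x$eps))
    cat(sprintf("  session %s: eps_E=%.4g eps_I=%.4g\n",
                s, x$eps[[s]]$eps_E, x$eps[[s]]$eps_I))
  invisible(x)
}

#' Stratified unit resampling
#'
#' Draws units with replacement within each (session, population) stratum,
#' preserving the shape of the dataset. Resampled copies of the same unit get
#' distinct ids.
#'
#' @param units An [isn_units] table.
#' @param labels Data frame `unit_id, label` or named vector of `"E"`/`"I"`.
#' @return A list with resampled `units` and matching `labels`.
#' @export
resample_units <- function(units, labels) {
  units <- validate_units(units)
  if (is.data.frame(labels)) labels <- stats::setNames(labels$label, labels$unit_id)
  info <- unique(units[, c("session", "unit_id")])
  info$label <- labels[info$unit_id]
  picked <- do.call(rbind, lapply(split(info, interaction(info$session, info$label,
                                                          drop = TRUE)),
                                  function(g) g[sample(nrow(g), replace = TRUE), ]))
  out <- vector("list", nrow(picked))
  new_labels <- character(nrow(picked))
  for (k in seq_len(nrow(picked))) {
    u <- unit_rows(units, picked$unit_id[k])
    u$unit_id <- paste0(picked$unit_id[k], "#", k)
    out[[k]] <- u
    new_labels[k] <- picked$label[k]
  }
  units2 <- do.call(rbind, out)
  rownames(units2) <- NULL
  list(units = validate_units(units2),
       labels = stats::setNames(new_labels, vapply(out, function(u) u$unit_id[1], "")))
}

#' Bootstrap uncertainty of the global fit
#'
#' Repeatedly resamples units with replacement (stratified by session and
#' population, see [resample_units()]), rebuilds the population dose-response
#' curves, reruns [fit_global()], and summarizes the resample distribution of
#' every parameter by median, mode (histogram peak) and percentile interval.
#'
#' @param units An [isn_units] table (laser in mW).
#' @param labels Unit population labels (`"E"`/`"I"`), data frame or named
#'   vector.
#' @param L0_by_session Named numeric vector: the normalization intensity per
#'   session used to place all curves on the normalized scale.
#' @param n_boot Number of bootstrap resamples (>= 2; the most exhaustive
#'   setting is 10^4).
#' @param n_restarts_per_boot Restarts per resample fit.
#' @param seed Integer seed.
#' @param resampler Resampling function `(units, labels) -> list(units,
#'   labels)`; the default is stratified unit resampling. Supplying the
#'   identity makes one bootstrap replicate reproduce the plain fit.
#' @param probs Percentiles reported in the summary.
#' @param summarize If `TRUE` (default) the resample distribution is
#'   summarized; summaries require `n_boot >= 2`.
#' @return An object of class `isn_boot`: `samples` (data frame, one row per
#'   resample, columns = parameter names + sse) and `summary` (median, mode,
#'   percentiles per parameter; `NULL` when `summarize = FALSE`).
#' @export
bootstrap_fit <- function(units, labels, L0_by_session, n_boot = 10000,
                          n_restarts_per_boot = 100, seed = NULL,
                          resampler = resample_units,
                          probs = c(0.025, 0.25, 0.75, 0.975),
                          summarize = TRUE) {
  if (summarize && n_boot < 2)
    stop("n_boot must be at least 2 for resample summaries")
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    rs <- resampler(units, labels)
    ds <- build_dose_response(rs$units, rs$labels, L0_by_session)
    fit <- fit_global(ds, n_restarts = n_restarts_per_boot)
    th <- c(fit$params$W_EE, fit$params$W_EI, fit$params$W_IE, fit$params$W_II,
            fit$params$I_EX, fit$params$I_IX, fit$params$tf_E$threshold,
            fit$params$tf_I$threshold, fit$params$lambda)
    rows[[b]] <- c(stats::setNames(th, structural_names), sse = fit$sse)
  }
  samples <- as.data.frame(do.call(rbind, rows))
  summ <- NULL
  if (summarize) {
    summ <- lapply(structural_names, function(nm) {
      v <- samples[[nm]]
      h <- graphics::hist(v, breaks = "FD", plot = FALSE)
      list(median = stats::median(v),
           mode = h$mids[which.max(h$counts)],
           percentiles = stats::quantile(v, probs))
    })
    names(summ) <- structural_names
  }
  structure(list(samples = samples, summary = summ), class = "isn_boot")
}

#' Build normalized dose-response curves from unit tables
#'
#' Converts unit-trial counts into the population curves [fit_global()]
#' consumes: intact-phase curves pooled across sessions, blocker-phase curves
#' per session, intensities normalized by each session's `L0`.
#'
#' @param units An [isn_units] table.
#' @param labels Unit labels (`"E"`/`"I"`).
#' @param L0_by_session Named numeric vector of per-session `L0` (mW).
#' @return An [dose_response_dataset()].
#' @export
build_dose_response <- function(units, labels, L0_by_session) {
  units <- validate_units(units)
  if (is.data.frame(labels)) labels <- stats::setNames(labels$label, labels$unit_id)
  units$Lnorm <- units$laser_mW / L0_by_session[units$session]
  units$rate <- units$spike_count / units$window_s
  units$pop <- labels[units$unit_id]
  rows <- list()
  for (ph in intersect(isn_phases, unique(units$phase))) {
    u <- units[units$phase == ph, , drop = FALSE]
    if (ph == "intact") {
      agg <- stats::aggregate(rate ~ pop + Lnorm,
                              data = u, FUN = mean)
      rows[[length(rows) + 1L]] <- data.frame(
        session = "pooled", phase = ph, population = agg$pop,
        L = agg$Lnorm, rate = agg$rate)
    } else {
      agg <- stats::aggregate(rate ~ pop + Lnorm + session, data = u, FUN = mean)
      rows[[length(rows) + 1L]] <- data.frame(
        session = agg$session, phase = ph, population = agg$pop,
        L = agg$Lnorm, rate = agg$rate)
    }
  }
  dose_response_dataset(do.call(rbind, rows))
}

#' Fit rate-dynamics time constants to step-response traces
#'
#' With the equilibrium connectivity held fixed, fits `(tau_E, tau_I)` by
#' least squares between [simulate_dynamics()] output and observed E and I
#' rate traces around a pulse onset. Optimization starts deterministically
#' from `tau_E = tau_I = 10` ms (Nelder-Mead on log time constants).
#'
#' @param params An [two_pop_params()] object (fixed).
#' @param traces Data frame with columns `time_ms`, `r_E`, `r_I`, `laser`
#'   (as produced by [simulate_dynamics()] or binned PSTHs on the same grid).
#' @param dt Euler step used for the model traces (ms).
#' @param init Starting values `(tau_E, tau_I)` in ms.
#' @return A [time_constants()] object with attributes `sse` and
#'   `identifiable` (`FALSE`, with a warning, when the traces carry no
#'   dynamics, e.g. start at the fixed point with constant laser).
#' @export
fit_time_constants <- function(params, traces, dt = 0.1, init = c(10, 10)) {
  stopifnot(all(c("time_ms", "r_E", "r_I", "laser") %in% names(traces)))
  t <- traces$time_ms
  L_fun <- stats::approxfun(t, traces$laser, method = "constant", rule = 2)
  T_ms <- max(t) - min(t)
  init_state <- c(r_E = traces$r_E[1], r_I = traces$r_I[1])
  degenerate <- stats::sd(traces$r_E) + stats::sd(traces$r_I) < 1e-8
  obj <- function(logtau) {
    tau <- exp(logtau)
    sim <- simulate_dynamics(params, time_constants(tau[1], tau[2]),
                             laser = function(x) L_fun(x + min(t)),
                             T_ms = T_ms, dt = min(dt, min(tau) / 10),
                             init = init_state)
    simE <- stats::approx(sim$time_ms + min(t), sim$r_E, xout = t)$y
    simI <- stats::approx(sim$time_ms + min(t), sim$r_I, xout = t)$y
    sum((simE - traces$r_E)^2 + (simI - traces$r_I)^2)
  }
  if (degenerate) {
    warning("traces carry no dynamics (constant at fixed point): ",
            "time constants are not identifiable")
    out <- time_constants(init[1], init[2])
    attr(out, "sse") <- obj(log(init))
    attr(out, "identifiable") <- FALSE
    return(out)
  }
  if (T_ms < 5 * max(init))
    warning("traces shorter than 5 candidate time constants; fit may be poor")
  opt <- stats::optim(log(init), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  tau <- exp(opt$par)
  out <- time_constants(tau[1], tau[2])
  attr(out, "sse") <- opt$value
  attr(out, "identifiable") <- TRUE
  out
}

#' Count the free parameters of a model configuration
#'
#' The full three-phase model has 15 parameters: 2 time constants, 2
#' thresholds, 2 gains, 4 connection weights, 2 external inputs, the opsin
#' efficacy, and 2 blocker efficacies per session. Equilibrium analysis drops
#' the time constants; pinning the gains (always possible because the
#' equilibrium determines parameters only up to one scale per population)
#' drops 2 more, leaving 11 free parameters in the canonical setup.
#'
#' @param equilibrium If `TRUE` the time constants are not free.
#' @param gains_pinned If `TRUE` the gains are fixed at 1.
#' @param n_sessions Number of sessions contributing blocker efficacies.
#' @return Integer count.
#' @export
count_free_parameters <- function(equilibrium = TRUE, gains_pinned = TRUE,
                                  n_sessions = 1) {
  stopifnot(n_sessions >= 0)
  9 +                       # 4 weights + 2 inputs + 2 thresholds + lambda
    2 * n_sessions +        # eps_E, eps_I per session
    (if (equilibrium) 0 else 2) +
    (if (gains_pinned) 0 else 2)
}
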