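#' Piecewise-constant laser trace
#'
#' Convenience constructor for a step stimulus: intensity `L_off` before
#' `t_on` (ms), `L_on` from `t_on` to `t_off`, then `L_off` again.
#'
#' @param L_on Intensity during the pulse.
#' @param t_on Pulse onset (ms).
#' @param t_off Pulse offset (ms); `Inf` for a step that stays on.
#' @param L_off Intensity outside the pulse.
#' @return A function of time (ms) returning intensity, usable as the
#'   `laser` argument of [simulate_dynamics()].
#' @export
laser_step <- function(L_on, t_on = 0, t_off = Inf, L_off = 0) {
  force(L_on); force(t_on); force(t_off); force(L_off)
  function(t) ifelse(t >= t_on & t < t_off, L_on, L_off)
}

#' Simulate the two-population rate dynamics
#'
#' Integrates the coupled rate equations with fixed-step explicit Euler.
#' Rates can never become negative: the transfer function is non-negative and
#' the leak term is proportional to `-r`. For a constant stimulus and a
#' stable network the trajectory converges to the corresponding
#' [fixed_point()]. In the ISN regime (`a_E * W_EE > 1`) a step increase in
#' inhibitory drive produces a brief *increase* in `r_I` before the
#' paradoxical steady-state suppression.
#'
#' @param params An [two_pop_params()] object.
#' @param taus A [time_constants()] object (ms).
#' @param laser Either a single intensity (constant stimulus) or a function
#'   of time (ms) returning intensity, e.g. [laser_step()].
#' @param T_ms Total simulated time (ms).
#' @param dt Euler step (ms); must satisfy `dt <= min(tau_E, tau_I) / 10`.
#' @param init Initial rates, a list/vector with elements `r_E`, `r_I`.
#'   Defaults to the fixed point at the initial laser intensity.
#' @param rate_ceiling Rates above this value mark the trajectory as
#'   divergent; rates are capped there and the returned object carries
#'   `attr(, "diverged") = TRUE`.
#'
#' @return A data frame of class `isn_trace` with columns `time_ms`, `r_E`,
#'   `r_I`, `laser`.
#' @export
simulate_dynamics <- function(params, taus, laser, T_ms, dt = 0.1,
                              init = NULL, rate_ceiling = 1e6) {
  stopifnot(inherits(params, "isn_params"), inherits(taus, "isn_taus"))
  if (dt > min(taus$tau_E, taus$tau_I) / 10)
    stop("dt too large: must be <= min(tau_E, tau_I) / 10")
  L_fun <- if (is.function(laser)) laser else function(t) rep(laser, length(t))
  times <- seq(0, T_ms, by = dt)
  n <- length(times)
  Lt <- L_fun(times)
  if (is.null(init)) {
    fp <- fixed_point(params, Lt[1])
    init <- c(r_E = fp$r_E, r_I = fp$r_I)
  }
  rE <- numeric(n); rI <- numeric(n)
  rE[1] <- init[["r_E"]]; rI[1] <- init[["r_I"]]
  g <- params
  diverged <- FALSE
  ## hoist the common rectified-linear case out of the step loop
  relu_only <- g$tf_E$kind == "rectified_linear" && g$tf_I$kind == "rectified_linear"
  aE <- g$tf_E$gain; x0E <- g$tf_E$threshold
  aI <- g$tf_I$gain; x0I <- g$tf_I$threshold
  cE <- dt / taus$tau_E; cI <- dt / taus$tau_I
  for (k in seq_len(n - 1)) {
    xE <- g$W_EE * rE[k] - g$W_EI * rI[k] + g$I_EX
    xI <- g$W_IE * rE[k] - g$W_II * rI[k] + g$I_IX + g$lambda * Lt[k]
    if (relu_only) {
      phiE <- aE * max(xE - x0E, 0)
      phiI <- aI * max(xI - x0I, 0)
    } else {
      phiE <- evaluate_tf(xE, g$tf_E)
      phiI <- evaluate_tf(xI, g$tf_I)
    }
    rE[k + 1] <- rE[k] + cE * (phiE - rE[k])
    rI[k + 1] <- rI[k] + cI * (phiI - rI[k])
    if (rE[k + 1] > rate_ceiling || rI[k + 1] > rate_ceiling) {
      diverged <- TRUE
      rE[k + 1] <- min(rE[k + 1], rate_ceiling)
      rI[k + 1] <- min(rI[k + 1], rate_ceiling)
    }
  }
  out <- data.frame(time_ms = times, r_E = rE, r_I = rI, laser = Lt)
  class(out) <- c("isn_trace", class(out))
  attr(out, "diverged") <- diverged
  out
}

#' Write a simulated rate trace to CSV
#'
#' Columns: `time_ms, r_E, r_I, laser`.
#'
#' @param trace Output of [simulate_dynamics()].
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(all(c("time_ms", "r_E", "r_I", "laser") %in% names(trace)))
  utils::write.csv(as.data.frame(trace)[, c("time_ms", "r_E", "r_I", "laser")],
                   path, row.names = FALSE)
  invisible(path)
}
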