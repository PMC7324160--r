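#' Three-population (E, I, P) network parameters
#'
#' Rate model with one excitatory population (E) and two inhibitory
#' populations: P, the opsin-expressing stimulated subset, and I, the
#' remaining (non-stimulated) inhibitory cells. Weight magnitudes are stored
#' non-negative in a 3x3 matrix indexed `(post, pre)` over `E, I, P`; the
#' sign convention is fixed by the equations (presynaptic E excites, I and P
#' inhibit). Optogenetic drive `lambda * L` enters the P population only.
#'
#' @param W 3x3 non-negative matrix of weight magnitudes, rows = postsynaptic
#'   `(E, I, P)`, columns = presynaptic `(E, I, P)`.
#' @param I_X Length-3 external inputs `(I_EX, I_IX, I_PX)`.
#' @param x0 Length-3 thresholds.
#' @param lambda Non-negative opsin efficacy (applied to P).
#' @param frac Fraction of inhibitory cells in the stimulated subset,
#'   in `(0, 1]`.
#' @return An object of class `isn_params3`.
#' @export
three_pop_params <- function(W, I_X, x0, lambda, frac = 1) {
  W <- as.matrix(W)
  stopifnot(identical(dim(W), c(3L, 3L)), length(I_X) == 3, length(x0) == 3,
            all(is.finite(W)), all(is.finite(I_X)), all(is.finite(x0)),
            is.finite(lambda), is.finite(frac))
  if (any(W < 0)) stop("weight magnitudes must be non-negative")
  if (lambda < 0) stop("lambda must be non-negative")
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  dimnames(W) <- list(c("E", "I", "P"), c("E", "I", "P"))
  names(I_X) <- names(x0) <- c("E", "I", "P")
  structure(list(W = W, I_X = I_X, x0 = x0, lambda = lambda, frac = frac),
            class = "isn_params3")
}

#' Build the three-population model from a two-population fit
#'
#' Splits the inhibitory population of a fitted two-population model into a
#' stimulated subset P (fraction `frac`) and a non-stimulated remainder I.
#' The construction keeps the excitatory row (`W_EE`, `I_EX`, `x0_E`) from
#' the source; each population's inhibitory input is split `frac : (1-frac)`
#' between P and I from the source inhibitory weight onto that population;
#' and the I and P rows copy the source inhibitory row (`W_IE`, `I_IX`,
#' `x0_I`). Consequently the column-splitting conservation
#' `W_XI + W_XP = ` (source inhibitory weight onto X) holds exactly, and at
#' `frac = 1` the (E, P) subsystem reduces to the source two-population
#' model with I decoupled from the feedback loop.
#'
#' @param source An [two_pop_params()] object (rectified-linear).
#' @param frac Stimulated fraction in `(0, 1]`.
#' @return An [three_pop_params()] object.
#' @export
build_three_pop <- function(source, frac) {
  stopifnot(inherits(source, "isn_params"))
  if (!is.finite(frac) || frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  W <- rbind(
    E = c(source$W_EE, (1 - frac) * source$W_EI, frac * source$W_EI),
    I = c(source$W_IE, (1 - frac) * source$W_II, frac * source$W_II),
    P = c(source$W_IE, (1 - frac) * source$W_II, frac * source$W_II))
  three_pop_params(W,
                   I_X = c(source$I_EX, source$I_IX, source$I_IX),
                   x0 = c(source$tf_E$threshold, source$tf_I$threshold,
                          source$tf_I$threshold),
                   lambda = source$lambda,
                   frac = frac)
}

## Signed connectivity matrix (E column +, I and P columns -) used by the
## dynamics and the active-set solver.
signed_W3 <- function(params) {
  params$W %*% diag(c(1, -1, -1))
}

#' Simulate the three-population rate dynamics
#'
#' Fixed-step explicit Euler integration of the E/I/P rate equations with
#' rectified-linear transfer (unit gains).
#'
#' @param params An [three_pop_params()] object.
#' @param taus Length-3 positive time constants (ms) for `(E, I, P)`.
#' @param L Constant laser intensity (drives P).
#' @param T_ms Total time (ms).
#' @param dt Euler step (ms).
#' @param init Length-3 initial rates; defaults to zeros.
#' @param rate_ceiling Divergence cap.
#' @return Data frame `time_ms, r_E, r_I, r_P` with attribute `diverged`.
#' @export
simulate_dynamics_3pop <- function(params, taus = c(10, 10, 10), L = 0,
                                   T_ms = 500, dt = 0.5, init = c(0, 0, 0),
                                   rate_ceiling = 1e6) {
  stopifnot(inherits(params, "isn_params3"), all(taus > 0))
  if (dt > min(taus) / 10) stop("dt too large: must be <= min(tau) / 10")
  Ws <- signed_W3(params)
  drive <- params$I_X + c(0, 0, params$lambda * L)
  times <- seq(0, T_ms, by = dt)
  n <- length(times)
  R <- matrix(0, n, 3)
  R[1, ] <- init
  cvec <- dt / taus
  diverged <- FALSE
  for (k in seq_len(n - 1)) {
    x <- Ws %*% R[k, ] + drive
    phi <- pmax(x - params$x0, 0)
    R[k + 1, ] <- R[k, ] + cvec * (phi - R[k, ])
    if (any(R[k + 1, ] > rate_ceiling)) {
      diverged <- TRUE
      R[k + 1, ] <- pmin(R[k + 1, ], rate_ceiling)
    }
  }
  out <- data.frame(time_ms = times, r_E = R[, 1], r_I = R[, 2], r_P = R[, 3])
  attr(out, "diverged") <- diverged
  out
}

#' Fixed point of the three-population model
#'
#' Solves the piecewise-linear equilibrium by enumerating the 8 rectification
#' patterns (each population either active or silenced), tested in order of
#' decreasing number of active populations. A pattern is self-consistent when
#' the active subsystem's linear solution is positive and every silenced
#' population's input stays at or below threshold. When several patterns are
#' self-consistent, the one reached by integrating the dynamics from the
#' `L = 0` state is returned. If the dynamics diverge (no stable pattern is
#' reached) an `"unstable"` verdict is returned with `NA` rates.
#'
#' @param params An [three_pop_params()] object.
#' @param L Laser intensity (scalar).
#' @param taus Time constants used for the tie-breaking integration.
#' @return A list with `rates` (named length-3 vector), `active` (logical
#'   vector over E, I, P) and `verdict` (`"ok"` or `"unstable"`).
#' @export
fixed_point_3pop <- function(params, L, taus = c(10, 10, 10)) {
  stopifnot(inherits(params, "isn_params3"), length(L) == 1, is.finite(L))
  Ws <- signed_W3(params)
  drive <- params$I_X + c(0, 0, params$lambda * L)
  patterns <- expand.grid(E = c(TRUE, FALSE), I = c(TRUE, FALSE), P = c(TRUE, FALSE))
  patterns <- patterns[order(-rowSums(patterns)), , drop = FALSE]
  candidates <- list()
  for (i in seq_len(nrow(patterns))) {
    act <- unlist(patterns[i, ])
    r <- c(E = 0, I = 0, P = 0)
    if (any(act)) {
      A <- diag(sum(act)) - Ws[act, act, drop = FALSE]
      b <- drive[act] - params$x0[act]
      sol <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(sol) || any(!is.finite(sol)) || any(sol <= 0)) next
      r[act] <- sol
    }
    x <- drop(Ws %*% r) + drive
    if (any(x[!act] - params$x0[!act] > 1e-9)) next
    candidates[[length(candidates) + 1L]] <- list(rates = r, active = act)
  }
  if (length(candidates) == 0L)
    return(list(rates = c(E = NA_real_, I = NA_real_, P = NA_real_),
                active = c(E = NA, I = NA, P = NA), verdict = "unstable"))
  if (length(candidates) > 1L) {
    ## tie-break by following the dynamics from the resting (L = 0) state
    init <- if (L != 0) {
      fp0 <- fixed_point_3pop(params, 0, taus)
      if (fp0$verdict == "ok") fp0$rates else c(0, 0, 0)
    } else c(0, 0, 0)
    tr <- simulate_dynamics_3pop(params, taus, L, T_ms = 200 * max(taus),
                                 dt = min(taus) / 20, init = unname(init))
    if (isTRUE(attr(tr, "diverged")))
      return(list(rates = c(E = NA_real_, I = NA_real_, P = NA_real_),
                  active = c(E = NA, I = NA, P = NA), verdict = "unstable"))
    final <- unlist(tr[nrow(tr), c("r_E", "r_I", "r_P")])
    d <- vapply(candidates, function(cd) sum(abs(cd$rates - final)), 0)
    candidates <- candidates[order(d)][1]
  }
  c(candidates[[1]], list(verdict = "ok"))
}

#' Equilibrium response of the stimulated population (closed form)
#'
#' In the regime where all three populations are above threshold at `0` and
#' `L`, the steady-state rate change of the stimulated population is
#' \deqn{r_P(L) - r_P(0) = \frac{(1 - W_{EE})(W_{II} + 1) + W_{EI} W_{IE}}{N}\,\lambda L}
#' with
#' `N = (1 - W_EE)[(W_II+1)(W_PP+1) - W_IP W_PI] - W_EI[W_IP W_PE - W_IE (W_PP+1)]
#'  + W_EP[(W_II+1) W_PE - W_IE W_PI]`.
#' A negative value is the paradoxical effect.
#'
#' @param params An [three_pop_params()] object.
#' @param L Laser intensity.
#' @return Rate change of P (spk/s) with attribute `"paradoxical"`.
#' @export
delta_rP <- function(params, L) {
  stopifnot(inherits(params, "isn_params3"))
  W <- params$W
  N <- (1 - W["E", "E"]) * ((W["I", "I"] + 1) * (W["P", "P"] + 1) -
                              W["I", "P"] * W["P", "I"]) -
    W["E", "I"] * (W["I", "P"] * W["P", "E"] - W["I", "E"] * (W["P", "P"] + 1)) +
    W["E", "P"] * ((W["I", "I"] + 1) * W["P", "E"] - W["I", "E"] * W["P", "I"])
  if (abs(N) < 1e-12) stop("singular three-population model: N = 0")
  num <- (1 - W["E", "E"]) * (W["I", "I"] + 1) + W["E", "I"] * W["I", "E"]
  out <- num / N * params$lambda * L
  attr(out, "paradoxical") <- unname(out < 0)
  out
}

#' Paradoxical-effect criterion in the presynaptic-identity model
#'
#' In the simplified network whose connectivity depends only on the identity
#' of the presynaptic population (`W_.E = W`, `W_.I = kI * W`,
#' `W_.P = kP * W`), the steady-state response factor of the stimulated
#' population is
#' \deqn{\frac{1 + (k_I - 1) W}{1 + (k_P + k_I - 1) W}.}
#' Stimulation is paradoxical iff the factor is negative; in the large-`W`
#' limit this reduces to `kI < 1 && kP > 1 - kI`, and as `W -> 0` the factor
#' tends to 1 (no paradox without recurrence).
#'
#' @param W Positive presynaptic-excitatory weight.
#' @param kI,kP Positive inhibitory scaling factors.
#' @return List with `factor` and `paradoxical`.
#' @export
simplified_paradox <- function(W, kI, kP) {
  stopifnot(is.finite(W), is.finite(kI), is.finite(kP),
            W > 0, kI > 0, kP > 0)
  den <- 1 + (kP + kI - 1) * W
  if (abs(den) < 1e-12) stop("singular simplified model: zero denominator")
  factor <- (1 + (kI - 1) * W) / den
  list(factor = factor, paradoxical = factor < 0)
}

#' Numeric eigenvalues of the three-population Jacobian
#'
#' Plumbing for stability checks of the E/I/P model in the all-active
#' regime: eigendecomposition of
#' `diag(1/taus) %*% (signed W - identity)`.
#'
#' @param params An [three_pop_params()] object.
#' @param taus Length-3 positive time constants (ms).
#' @return Complex eigenvalues (1/ms), plus attribute `"stable"`.
#' @export
eigenvalues_3pop <- function(params, taus = c(10, 10, 10)) {
  stopifnot(inherits(params, "isn_params3"), all(taus > 0))
  J <- diag(1 / taus) %*% (signed_W3(params) - diag(3))
  ev <- eigen(J, only.values = TRUE)$values
  attr(ev, "stable") <- max(Re(ev)) < 0
  ev
}

#' Dose-response curves of the three-population model
#'
#' Tabulates the equilibrium rates of the E, I and P populations over a grid
#' of laser intensities, e.g. to examine how subset stimulation weakens the
#' paradoxical suppression of the stimulated cells.
#'
#' @param params An [three_pop_params()] object, e.g. from
#'   [build_three_pop()].
#' @param L Numeric vector of intensities.
#' @param taus Time constants passed to [fixed_point_3pop()].
#' @return Data frame `L, r_E, r_I, r_P, verdict`.
#' @export
pv_response_curve <- function(params, L, taus = c(10, 10, 10)) {
  rows <- lapply(L, function(l) {
    fp <- fixed_point_3pop(params, l, taus)
    data.frame(L = l, r_E = fp$rates[["E"]], r_I = fp$rates[["I"]],
               r_P = fp$rates[["P"]], verdict = fp$verdict)
  })
  do.call(rbind, rows)
}
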