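#' Jacobian of the linearized two-population dynamics
#'
#' At an interior fixed point (both populations above threshold) of the
#' rectified-linear model the linearized dynamics have Jacobian
#' `[[ (a_E W_EE - 1)/tau_E, -a_E W_EI/tau_E ],
#'   [  a_I W_IE/tau_I,     -(a_I W_II + 1)/tau_I ]]` (units 1/ms).
#'
#' @param params An [two_pop_params()] object.
#' @param taus A [time_constants()] object.
#' @return A 2x2 numeric matrix.
#' @export
jacobian_2pop <- function(params, taus) {
  stopifnot(inherits(params, "isn_params"), inherits(taus, "isn_taus"))
  aE <- params$tf_E$gain; aI <- params$tf_I$gain
  matrix(c((aE * params$W_EE - 1) / taus$tau_E, -aE * params$W_EI / taus$tau_E,
           aI * params$W_IE / taus$tau_I, -(aI * params$W_II + 1) / taus$tau_I),
         nrow = 2, byrow = TRUE)
}

#' Closed-form eigenvalues of the linearized dynamics
#'
#' Evaluates the analytic eigenvalue pair of the two-population Jacobian at
#' an interior fixed point,
#' \deqn{\lambda_\pm = \frac{a_E W_{EI}}{2\tau_E}\left[(A - rB) \pm
#'   \sqrt{(A + rB)^2 - 4r}\right]}
#' with `A = (a_E W_EE - 1)/(a_E W_EI)`, `B = (a_I W_II + 1)/(a_I W_IE)` and
#' `r = tau_E a_I W_IE / (tau_I a_E W_EI)`. The pair is either real or a
#' complex-conjugate pair; a nonzero imaginary part signals damped
#' oscillations, and the fixed point is linearly stable iff the maximal real
#' part is negative.
#'
#' @param params An [two_pop_params()] object (rectified-linear regime;
#'   `W_EI`, `W_IE` must be positive for the closed form).
#' @param taus A [time_constants()] object.
#'
#' @return An object of class `isn_eigen` with fields `lambda_plus`,
#'   `lambda_minus` (complex, 1/ms), `max_real`, `stable`, `oscillatory`.
#' @export
eigenvalues_closed_form <- function(params, taus) {
  stopifnot(inherits(params, "isn_params"), inherits(taus, "isn_taus"))
  if (taus$tau_E <= 0 || taus$tau_I <= 0) stop("time constants must be positive")
  aE <- params$tf_E$gain; aI <- params$tf_I$gain
  if (params$W_EI <= 0)
    stop("closed-form eigenvalues require W_EI > 0")
  A <- (aE * params$W_EE - 1) / (aE * params$W_EI)
  r <- taus$tau_E * aI * params$W_IE / (taus$tau_I * aE * params$W_EI)
  ## r * B with B = (a_I W_II + 1)/(a_I W_IE); W_IE cancels in the product,
  ## keeping the formula finite at W_IE = 0 (triangular case)
  rB <- taus$tau_E * (aI * params$W_II + 1) / (taus$tau_I * aE * params$W_EI)
  pref <- aE * params$W_EI / (2 * taus$tau_E)
  disc <- as.complex((A + rB)^2 - 4 * r)
  root <- sqrt(disc)
  lp <- pref * ((A - rB) + root)
  lm_ <- pref * ((A - rB) - root)
  max_real <- max(Re(lp), Re(lm_))
  structure(list(lambda_plus = lp, lambda_minus = lm_,
                 max_real = max_real,
                 stable = max_real < 0,
                 oscillatory = abs(Im(lp)) > 0),
            class = "isn_eigen")
}

#' @export
print.isn_eigen <- function(x, ...) {
  cat("<isn_eigen>\n")
  cat(sprintf("  lambda+ = %.6g %+.6gi /ms\n", Re(x$lambda_plus), Im(x$lambda_plus)))
  cat(sprintf("  lambda- = %.6g %+.6gi /ms\n", Re(x$lambda_minus), Im(x$lambda_minus)))
  cat(sprintf("  max real part: %.6g /ms; %s%s\n", x$max_real,
              if (x$stable) "stable" else "UNSTABLE",
              if (x$oscillatory) ", oscillatory (damped oscillations)" else ""))
  invisible(x)
}

#' Maximal stable ratio of inhibitory to excitatory time constants
#'
#' Scans the real part of the Jacobian eigenvalues as a function of the
#' ratio `tau_I / tau_E` and returns, by bisection, the supremum of ratios
#' for which the interior fixed point is linearly stable. For
#' `a_E * W_EE <= 1` the network is stable at every ratio and `Inf` is
#' returned; for `a_E * W_EE > 1` (the ISN regime) the boundary is the simple
#' root of the trace, which equals `(a_I W_II + 1) / (a_E W_EE - 1)` in
#' closed form.
#'
#' @param params An [two_pop_params()] object; the equilibrium determinant
#'   must be positive (saddle-free regime).
#' @param bracket Ratio scan bracket.
#' @param tol Bisection tolerance on the ratio.
#'
#' @return The maximal stable ratio (possibly `Inf`).
#' @export
stability_boundary_ratio <- function(params, bracket = c(1e-3, 1e3), tol = 1e-8) {
  stopifnot(inherits(params, "isn_params"))
  D <- model_determinant(params)
  if (D <= 0)
    stop("unstable: equilibrium determinant D <= 0, no stable ratio exists")
  aE <- params$tf_E$gain
  if (aE * params$W_EE <= 1) return(Inf)
  f <- function(ratio)
    eigenvalues_closed_form(params, time_constants(1, ratio))$max_real
  lo <- bracket[1]; hi <- bracket[2]
  if (f(lo) > 0)
    stop("unstable: no stable ratio inside the scan bracket")
  if (f(hi) <= 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Is the network inhibition-stabilized?
#'
#' An operating point is in the ISN regime iff the excitatory subnetwork is
#' unstable on its own, i.e. `a_E * W_EE > 1` (strict). Optionally the test
#' is applied after a pharmacological blocker transform, since blockade can
#' move a network out of the ISN regime.
#'
#' @param params An [two_pop_params()] object.
#' @param phase Optional phase for [apply_blockers()].
#' @param eff Blocker efficacies used when `phase` is given.
#' @return Logical.
#' @export
is_isn <- function(params, phase = NULL, eff = blocker_efficacy()) {
  stopifnot(inherits(params, "isn_params"))
  if (!is.null(phase)) params <- apply_blockers(params, phase, eff)
  params$tf_E$gain * params$W_EE > 1
}

#' Eigenvalues over a grid of time-constant ratios
#'
#' Tabulates the closed-form eigenvalue pair as `tau_I / tau_E` varies,
#' suitable for plotting the stability diagram (real part crossing zero at
#' the stability boundary; nonzero imaginary part marking the damped
#' oscillation band).
#'
#' @param params An [two_pop_params()] object.
#' @param ratios Numeric vector of `tau_I / tau_E` values.
#' @param tau_E Excitatory time constant (ms) fixing the overall time scale.
#' @return A data frame `ratio, re_plus, im_plus, re_minus, im_minus`.
#' @export
eigenvalue_grid <- function(params, ratios = seq(0.1, 10, by = 0.1), tau_E = 1) {
  rows <- lapply(ratios, function(rt) {
    e <- eigenvalues_closed_form(params, time_constants(tau_E, tau_E * rt))
    data.frame(ratio = rt,
               re_plus = Re(e$lambda_plus), im_plus = Im(e$lambda_plus),
               re_minus = Re(e$lambda_minus), im_minus = Im(e$lambda_minus))
  })
  do.call(rbind, rows)
}
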