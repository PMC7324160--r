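#' Two-population E/I network parameters
#'
#' Container for the parameters of the standard two-population rate model
#'
#' \deqn{\tau_E \dot r_E = -r_E + \phi_E(W_{EE} r_E - W_{EI} r_I + I_{EX})}
#' \deqn{\tau_I \dot r_I = -r_I + \phi_I(W_{IE} r_E - W_{II} r_I + I_{IX} + \lambda L)}
#'
#' Weight magnitudes are stored non-negative; excitatory/inhibitory signs are
#' applied in the equations. `lambda` is the opsin efficacy converting laser
#' intensity `L` into inhibitory drive. Transfer functions default to
#' rectified-linear with unit gain, the convention under which all equilibrium
#' analysis in this package is exact.
#'
#' @param W_EE,W_EI,W_IE,W_II Non-negative connection strengths (post, pre).
#' @param I_EX,I_IX External inputs (spk/s-equivalent).
#' @param lambda Non-negative opsin efficacy (spk/s per intensity unit).
#' @param tf_E,tf_I [transfer_function()] objects for the E and I populations.
#'
#' @return An object of class `isn_params`.
#' @export
two_pop_params <- function(W_EE, W_EI, W_IE, W_II, I_EX, I_IX, lambda = 0,
                           tf_E = transfer_function(), tf_I = transfer_function()) {
  w <- c(W_EE = W_EE, W_EI = W_EI, W_IE = W_IE, W_II = W_II)
  stopifnot(all(is.finite(w)), is.finite(I_EX), is.finite(I_IX), is.finite(lambda))
  if (any(w < 0)) stop("connection weights must be non-negative")
  if (lambda < 0) stop("opsin efficacy lambda must be non-negative")
  stopifnot(inherits(tf_E, "isn_tf"), inherits(tf_I, "isn_tf"))
  structure(list(W_EE = W_EE, W_EI = W_EI, W_IE = W_IE, W_II = W_II,
                 I_EX = I_EX, I_IX = I_IX, lambda = lambda,
                 tf_E = tf_E, tf_I = tf_I),
            class = "isn_params")
}

#' @export
print.isn_params <- function(x, ...) {
  cat("<isn_params>\n")
  cat(sprintf("  W_EE=%g W_EI=%g W_IE=%g W_II=%g\n", x$W_EE, x$W_EI, x$W_IE, x$W_II))
  cat(sprintf("  I_EX=%g I_IX=%g lambda=%g\n", x$I_EX, x$I_IX, x$lambda))
  cat(sprintf("  tf_E: %s (a=%g, x0=%g)  tf_I: %s (a=%g, x0=%g)\n",
              x$tf_E$kind, x$tf_E$gain, x$tf_E$threshold,
              x$tf_I$kind, x$tf_I$gain, x$tf_I$threshold))
  invisible(x)
}

#' Rate-dynamics time constants
#'
#' @param tau_E,tau_I Positive time constants (ms) of the E and I population
#'   rate dynamics.
#' @return An object of class `isn_taus`.
#' @export
time_constants <- function(tau_E, tau_I) {
  stopifnot(is.finite(tau_E), is.finite(tau_I))
  if (tau_E <= 0 || tau_I <= 0) stop("time constants must be positive")
  structure(list(tau_E = tau_E, tau_I = tau_I), class = "isn_taus")
}

#' Pharmacological blocker efficacies
#'
#' Survival factors of synaptic strength under blockade: 1 means no blockade,
#' 0 complete blockade. The excitatory factor also scales glutamatergic
#' external inputs.
#'
#' @param eps_E,eps_I Reals in `[0, 1]`.
#' @return An object of class `isn_eps`.
#' @export
blocker_efficacy <- function(eps_E = 1, eps_I = 1) {
  stopifnot(is.finite(eps_E), is.finite(eps_I))
  if (eps_E < 0 || eps_E > 1 || eps_I < 0 || eps_I > 1)
    stop("blocker efficacies must lie in [0, 1]")
  structure(list(eps_E = eps_E, eps_I = eps_I), class = "isn_eps")
}

#' Pharmacological phase labels
#'
#' The three experimental phases: recurrent connectivity intact, excitatory
#' synapses blocked, and excitatory plus inhibitory synapses blocked.
#' @export
isn_phases <- c("intact", "e_blocked", "ei_blocked")

match_phase <- function(phase) {
  match.arg(phase, isn_phases)
}

#' Effective network parameters under pharmacological blockade
#'
#' Applies the blocker transforms: with excitatory blockers
#' `{W_EE, I_EX, W_IE, I_IX}` are scaled by `eps_E` (external glutamatergic
#' inputs are blocked along with recurrent excitatory synapses); with
#' inhibitory blockers additionally `{W_EI, W_II}` are scaled by `eps_I`.
#' The opsin efficacy `lambda` is never scaled: direct optogenetic drive is
#' unaffected by synaptic blockade.
#'
#' @param params An [two_pop_params()] object.
#' @param phase One of `"intact"`, `"e_blocked"`, `"ei_blocked"`.
#' @param eff A [blocker_efficacy()] object.
#'
#' @return A transformed `isn_params` object.
#' @export
apply_blockers <- function(params, phase = isn_phases, eff = blocker_efficacy()) {
  stopifnot(inherits(params, "isn_params"), inherits(eff, "isn_eps"))
  phase <- match_phase(phase)
  if (phase == "intact") return(params)
  out <- params
  out$W_EE <- eff$eps_E * params$W_EE
  out$I_EX <- eff$eps_E * params$I_EX
  out$W_IE <- eff$eps_E * params$W_IE
  out$I_IX <- eff$eps_E * params$I_IX
  if (phase == "ei_blocked") {
    out$W_EI <- eff$eps_I * params$W_EI
    out$W_II <- eff$eps_I * params$W_II
  }
  out
}

#' Determinant of the equilibrium system
#'
#' `D = W_EI * W_IE - (W_II + 1) * (W_EE - 1)`, computed on the gain-absorbed
#' weights. `D != 0` is required for the interior fixed point to exist;
#' `D > 0` is the saddle-free regime in which the paradoxical-slope law
#' `d r_I / dL = -(W_EE - 1) * lambda / D` holds.
#'
#' @param params An [two_pop_params()] object.
#' @return The scalar determinant.
#' @export
model_determinant <- function(params) {
  g <- absorb_gains(params)
  g$W_EI * g$W_IE - (g$W_II + 1) * (g$W_EE - 1)
}

## Fold transfer-function gains into weights/inputs/thresholds so that all
## equilibrium formulas can assume a_E = a_I = 1. Firing rates are unchanged
## by this substitution (r = a * (x - x0)+ becomes r = (a*x - a*x0)+).
absorb_gains <- function(params) {
  aE <- params$tf_E$gain; aI <- params$tf_I$gain
  list(W_EE = aE * params$W_EE, W_EI = aE * params$W_EI,
       W_IE = aI * params$W_IE, W_II = aI * params$W_II,
       I_EX = aE * params$I_EX, I_IX = aI * params$I_IX,
       x0_E = aE * params$tf_E$threshold, x0_I = aI * params$tf_I$threshold,
       lambda = aI * params$lambda)
}

#' Rescale parameters along the equilibrium-invariant family
#'
#' The equilibrium solution determines the parameters only up to one
#' multiplicative constant per population. This function applies the
#' two-parameter transformation
#' `{W_EE - 1, W_EI, I_EX, x0_E} -> gamma_E * {...}` and
#' `{W_IE, W_II + 1, I_IX, x0_I, lambda} -> gamma_I * {...}`,
#' under which all fixed-point rates are invariant.
#'
#' @param params An [two_pop_params()] object (rectified-linear transfer).
#' @param gamma_E,gamma_I Positive scale factors.
#' @return The transformed `isn_params` object.
#' @export
rescale_params <- function(params, gamma_E = 1, gamma_I = 1) {
  stopifnot(inherits(params, "isn_params"))
  if (!is.finite(gamma_E) || !is.finite(gamma_I) || gamma_E <= 0 || gamma_I <= 0)
    stop("rescaling factors must be positive")
  W_EE <- gamma_E * (params$W_EE - 1) + 1
  W_II <- gamma_I * (params$W_II + 1) - 1
  if (W_EE < 0)
    stop("rescaling would make W_EE negative; leaving the non-negative weight region")
  if (W_II < 0)
    stop("rescaling would make W_II negative; leaving the non-negative weight region")
  two_pop_params(
    W_EE = W_EE,
    W_EI = gamma_E * params$W_EI,
    W_IE = gamma_I * params$W_IE,
    W_II = W_II,
    I_EX = gamma_E * params$I_EX,
    I_IX = gamma_I * params$I_IX,
    lambda = gamma_I * params$lambda,
    tf_E = transfer_function(params$tf_E$kind, params$tf_E$gain,
                             gamma_E * params$tf_E$threshold, params$tf_E$smoothing),
    tf_I = transfer_function(params$tf_I$kind, params$tf_I$gain,
                             gamma_I * params$tf_I$threshold, params$tf_I$smoothing))
}

#' Read and write model parameters as flat JSON
#'
#' The on-disk format is a flat JSON object with keys
#' `W_EE, W_EI, W_IE, W_II, I_EX, I_IX, x0_E, x0_I, a_E, a_I, b_E, b_I,
#' lambda, tau_E_ms, tau_I_ms`. Missing `b_E`/`b_I` imply rectified-linear
#' transfer functions; missing gains default to 1; missing time constants
#' yield `taus = NULL`.
#'
#' @param path File path.
#' @return `read_params_json()` returns `list(params, taus)`.
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("W_EE", "W_EI", "W_IE", "W_II", "I_EX", "I_IX", "lambda")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("parameter file missing keys: ", paste(miss, collapse = ", "))
  gE <- if (!is.null(x$a_E)) x$a_E else 1
  gI <- if (!is.null(x$a_I)) x$a_I else 1
  tf_E <- if (!is.null(x$b_E))
    transfer_function("softplus", gE, x$x0_E %||% 0, x$b_E)
  else transfer_function("rectified_linear", gE, x$x0_E %||% 0)
  tf_I <- if (!is.null(x$b_I))
    transfer_function("softplus", gI, x$x0_I %||% 0, x$b_I)
  else transfer_function("rectified_linear", gI, x$x0_I %||% 0)
  params <- two_pop_params(x$W_EE, x$W_EI, x$W_IE, x$W_II, x$I_EX, x$I_IX,
                           x$lambda, tf_E = tf_E, tf_I = tf_I)
  taus <- if (!is.null(x$tau_E_ms) && !is.null(x$tau_I_ms))
    time_constants(x$tau_E_ms, x$tau_I_ms) else NULL
  list(params = params, taus = taus)
}

#' @rdname read_params_json
#' @param params An [two_pop_params()] object.
#' @param taus Optional [time_constants()] object.
#' @export
write_params_json <- function(params, path, taus = NULL) {
  stopifnot(inherits(params, "isn_params"))
  x <- list(W_EE = params$W_EE, W_EI = params$W_EI, W_IE = params$W_IE,
            W_II = params$W_II, I_EX = params$I_EX, I_IX = params$I_IX,
            x0_E = params$tf_E$threshold, x0_I = params$tf_I$threshold,
            a_E = params$tf_E$gain, a_I = params$tf_I$gain,
            lambda = params$lambda)
  if (!is.null(params$tf_E$smoothing)) x$b_E <- params$tf_E$smoothing
  if (!is.null(params$tf_I$smoothing)) x$b_I <- params$tf_I$smoothing
  if (!is.null(taus)) { x$tau_E_ms <- taus$tau_E; x$tau_I_ms <- taus$tau_I }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
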