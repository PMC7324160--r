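#' Fixed point of the two-population model
#'
#' Solves the equilibrium of the rectified-linear rate model at laser
#' intensity `L`. Two branches exist. On the *interior* branch both
#' populations are above threshold and
#' \deqn{r_E = \frac{(W_{II}+1)(I_{EX}-x_{0E}) - W_{EI}(I_{IX}+\lambda L-x_{0I})}{D}}
#' \deqn{r_I = \frac{W_{IE}(I_{EX}-x_{0E}) - (W_{EE}-1)(I_{IX}+\lambda L-x_{0I})}{D}}
#' with `D = W_EI W_IE - (W_II+1)(W_EE-1)`. When the interior solution is not
#' self-consistent (its `r_E` or `r_I` would be negative) the *boundary*
#' branch applies: the excitatory population is silenced and
#' `r_E = 0, r_I = max((I_IX + lambda L - x0_I) / (W_II + 1), 0)`.
#' If both branches are simultaneously self-consistent (a bistable
#' configuration) the interior branch is returned and the `bistable` flag is
#' set; single-valued response curves are assumed throughout the package.
#'
#' Transfer-function gains are absorbed before solving, so any positive gains
#' are supported; transfer functions must be rectified-linear.
#'
#' @param params An [two_pop_params()] object with rectified-linear transfer
#'   functions.
#' @param L Numeric vector of laser intensities (normalized units).
#'
#' @return A data frame with columns `L`, `r_E`, `r_I`, `branch`
#'   (`"interior"` or `"boundary"`) and `bistable` (logical).
#' @export
fixed_point <- function(params, L) {
  stopifnot(inherits(params, "isn_params"), is.numeric(L), all(is.finite(L)))
  if (params$tf_E$kind != "rectified_linear" || params$tf_I$kind != "rectified_linear")
    stop("fixed_point requires rectified-linear transfer functions")
  g <- absorb_gains(params)
  D <- g$W_EI * g$W_IE - (g$W_II + 1) * (g$W_EE - 1)
  if (abs(D) < 1e-12)
    stop("singular model: equilibrium determinant D = 0")
  gE <- g$I_EX - g$x0_E
  gI <- g$I_IX + g$lambda * L - g$x0_I
  rE_int <- ((g$W_II + 1) * gE - g$W_EI * gI) / D
  rI_int <- (g$W_IE * gE - (g$W_EE - 1) * gI) / D
  interior_ok <- rE_int > 0 & rI_int > 0
  rI_bnd <- pmax(gI / (g$W_II + 1), 0)
  ## boundary self-consistency: with r_E = 0 the E input must stay at or
  ## below threshold, i.e. I_EX - W_EI * r_I <= x0_E
  boundary_ok <- (gE - g$W_EI * rI_bnd) <= 0
  r_E <- ifelse(interior_ok, rE_int, 0)
  r_I <- ifelse(interior_ok, rI_int, rI_bnd)
  data.frame(L = L,
             r_E = r_E,
             r_I = r_I,
             branch = ifelse(interior_ok, "interior", "boundary"),
             bistable = interior_ok & boundary_ok)
}

## Vectorized fixed-point rates over heterogeneous effective parameters, the
## inner loop of the least-squares residual. All arguments are vectors of the
## same length (already gain-absorbed, rectified-linear). Points with a
## near-singular determinant get a large finite penalty rate rather than an
## error so that optimizers can step through them.
fixed_point_vec <- function(W_EE, W_EI, W_IE, W_II, I_EX, I_IX,
                            x0_E, x0_I, lambda, L,
                            singular_penalty = 1e6) {
  D <- W_EI * W_IE - (W_II + 1) * (W_EE - 1)
  gE <- I_EX - x0_E
  gI <- I_IX + lambda * L - x0_I
  rE_int <- ((W_II + 1) * gE - W_EI * gI) / D
  rI_int <- (W_IE * gE - (W_EE - 1) * gI) / D
  ok <- abs(D) > 1e-9 & is.finite(rE_int) & is.finite(rI_int) &
    rE_int > 0 & rI_int > 0
  r_E <- ifelse(ok, rE_int, 0)
  r_I <- ifelse(ok, rI_int, pmax(gI / (W_II + 1), 0))
  bad <- !is.finite(r_E) | !is.finite(r_I)
  r_E[bad] <- singular_penalty
  r_I[bad] <- singular_penalty
  list(r_E = r_E, r_I = r_I)
}
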