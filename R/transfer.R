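#' Static transfer function (f-I curve) of a rate population
#'
#' Constructs the specification of the static nonlinearity mapping net input
#' to firing rate. Two families are supported: a rectified-linear function
#' `a * max(x - x0, 0)`, which is zero below the threshold `x0` and increases
#' with gain `a` above it, and a softplus function
#' `b * log(1 + exp((a / b) * (x - x0)))` which smooths the threshold kink;
#' the smoothing width `b` controls the size of the exponential region around
#' threshold and the softplus converges to the rectified-linear curve as
#' `b -> 0`.
#'
#' @param kind Either `"rectified_linear"` or `"softplus"`.
#' @param gain Positive gain `a` (spk/s per input unit).
#' @param threshold Threshold `x0` (input units, spk/s-equivalent).
#' @param smoothing Positive smoothing width `b` (softplus only).
#'
#' @return An object of class `isn_tf`.
#' @seealso [evaluate_tf()]
#' @export
transfer_function <- function(kind = c("rectified_linear", "softplus"),
                              gain = 1, threshold = 0, smoothing = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(gain), length(gain) == 1L, is.finite(gain),
            is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  if (gain <= 0) stop("transfer-function gain must be positive")
  if (kind == "softplus") {
    if (is.null(smoothing) || !is.finite(smoothing) || smoothing <= 0)
      stop("softplus transfer function requires a positive smoothing width")
  } else {
    smoothing <- NULL
  }
  structure(list(kind = kind, gain = gain, threshold = threshold,
                 smoothing = smoothing),
            class = "isn_tf")
}

#' Evaluate a transfer function
#'
#' Applies the static nonlinearity to (vectorized) net input. The softplus
#' branch is overflow-guarded so that inputs with magnitude up to `1e6` are
#' handled without `Inf`/`NaN`: for large positive scaled input `z` it uses
#' the asymptote `b * (z + log1p(exp(-z)))`.
#'
#' @param x Numeric vector of net inputs. Must be finite.
#' @param tf An [transfer_function()] object.
#'
#' @return Non-negative firing rates (spk/s), same length as `x`.
#' @export
evaluate_tf <- function(x, tf) {
  stopifnot(inherits(tf, "isn_tf"))
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("transfer-function input must be finite numeric")
  if (tf$kind == "rectified_linear") {
    tf$gain * pmax(x - tf$threshold, 0)
  } else {
    b <- tf$smoothing
    z <- (tf$gain / b) * (x - tf$threshold)
    out <- numeric(length(z))
    hi <- z > 30
    out[hi] <- b * (z[hi] + log1p(exp(-z[hi])))
    out[!hi] <- b * log1p(exp(z[!hi]))
    out
  }
}

#' @export
print.isn_tf <- function(x, ...) {
  cat("<isn_tf>", x$kind, sprintf("gain=%g threshold=%g", x$gain, x$threshold))
  if (!is.null(x$smoothing)) cat(sprintf(" smoothing=%g", x$smoothing))
  cat("\n")
  invisible(x)
}
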