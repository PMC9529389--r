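#' Scaled exponential linear unit (SELU)
#'
#' `selu(x)` is `lambda * x` for `x > 0` and `lambda * alpha * (exp(x) - 1)`
#' for `x <= 0`. With the standard constants `alpha = 1.6733`,
#' `lambda = 1.0507` the activation drives the mean and variance of
#' layer activations toward 0 and 1 ("self-normalization") when weights are
#' drawn with variance `1/fan_in`. The function is continuous at 0 (both
#' branches vanish); the implementation assigns `x = 0` to the negative
#' branch. The negative branch saturates at `-lambda * alpha` (about
#' -1.7581) for large negative inputs.
#'
#' @param x numeric vector or array.
#' @param alpha,lambda SELU constants.
#' @return Same shape as `x`.
#' @examples
#' selu(c(-30, 0, 1))   # approx -1.7581, 0, 1.0507
#' @export
selu <- function(x, alpha = 1.6733, lambda = 1.0507) {
  out <- x
  pos <- x > 0
  out[pos] <- lambda * x[pos]
  out[!pos] <- lambda * alpha * expm1(x[!pos])
  out
}

# derivative wrt pre-activation, evaluated at pre-activation x
selu_grad <- function(x, alpha = 1.6733, lambda = 1.0507) {
  g <- x
  pos <- x > 0
  g[pos] <- lambda
  g[!pos] <- lambda * alpha * exp(x[!pos])
  g
}

# Alpha-dropout: dropped activations are set to the SELU negative-saturation
# value -lambda*alpha rather than 0, followed by an affine correction that
# restores zero mean / unit variance for standardized inputs. Returns the
# transformed activations plus what backward needs (keep mask and scale a):
# out = a * (x * keep + alpha' * (1 - keep)) + b, with q = 1 - rate,
# a = (q + alpha'^2 * rate * q)^(-1/2), b = -a * rate * alpha'.
alpha_dropout <- function(x, rate, alpha = 1.6733, lambda = 1.0507) {
  if (rate <= 0) return(list(out = x, keep = NULL, a = 1))
  ap <- -lambda * alpha
  q <- 1 - rate
  keep <- array(runif(length(x)) >= rate, dim = dim(x) %||% length(x))
  a <- (q + ap^2 * rate * q)^(-0.5)
  b <- -a * rate * ap
  out <- a * (x * keep + ap * (1 - keep)) + b
  list(out = out, keep = keep, a = a)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
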