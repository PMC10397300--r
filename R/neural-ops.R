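#' Numerically stable softmax
#'
#' Converts a logit vector (or a k x n matrix of column logits) into class
#' probabilities, `p_i = exp(phi_i) / sum_j exp(phi_j)`.  The maximum logit is
#' subtracted before exponentiation so that arbitrarily large logits do not
#' overflow; the result is unchanged because softmax is shift-invariant.
#'
#' @param phi numeric vector of logits, or a matrix with one logit vector per
#'   column.
#' @return probabilities of the same shape; each vector/column sums to 1.
#' @examples
#' softmaxProbs(c(1, 2, 3))
#' @export
softmaxProbs <- function(phi) {
  if (length(phi) == 0L) stop("softmaxProbs: empty logit vector")
  if (!all(is.finite(phi))) stop("softmaxProbs: logits must be finite")
  if (is.matrix(phi)) {
    z <- exp(sweep(phi, 2L, apply(phi, 2L, max)))
    return(sweep(z, 2L, colSums(z), "/"))
  }
  z <- exp(phi - max(phi))
  z / sum(z)
}

#' Leaky rectified linear activation
#'
#' Passes non-negative values unchanged and scales negative values by `slope`,
#' so gradients also flow through negative responses.
#'
#' @param x numeric array.
#' @param slope negative-region gain in `[0, 1)`; `0` gives the ordinary ReLU.
#' @return array of the same shape.
#' @export
leakyReLU <- function(x, slope = 0.01) {
  if (slope < 0 || slope >= 1) stop("leakyReLU: slope must be in [0, 1)")
  pmax(x, 0) + slope * pmin(x, 0)
}

#' Local response normalisation across channels
#'
#' Divisive normalisation of a (C, H, W) feature tensor: each activation is
#' divided by `(t + alpha * sum_j a_j^2)^beta`, where the sum runs over a
#' sliding window of `n` neighbouring channels (clipped at the tensor edges).
#' Encourages competition between adjacent feature maps, which helps
#' generalisation in networks without saturating activations.
#'
#' @param a numeric array `(C, H, W)` or `(C, H, W, N)`.
#' @param t additive constant of the denominator.
#' @param alpha scale of the squared-activation sum.
#' @param beta exponent of the denominator; `beta = 0` is the identity.
#' @param n channel neighbourhood size.
#' @return normalised array of the same shape.
#' @export
localResponseNorm <- function(a, t = 2, alpha = 1e-4, beta = 0.75, n = 5) {
  if (t <= 0 && alpha <= 0)
    stop("localResponseNorm: denominator would be zero (t = alpha = 0)")
  if (n < 1) stop("localResponseNorm: n must be >= 1")
  if (beta < 0) stop("localResponseNorm: beta must be >= 0")
  a * (t + alpha * .lrnWindowSum(a * a, n))^(-beta)
}

# Sliding-window sum over the channel (first) dimension, window i-n/2 .. i+n/2
# clipped to 1..C.  Works for (C, ...) arrays of rank 3 or 4.
.lrnWindowSum <- function(a2, n) {
  .winSumChannels(a2, dim(a2)[1], as.integer(n))
}

#' Global pooling over the spatial or channel axis
#'
#' Spatial pooling collapses each channel map to a single statistic (a length-C
#' vector); channel pooling collapses the channel stack at each position (a
#' `1 x H x W` map).  Both the mean (`"avg"`) and the maximum (`"max"`)
#' statistic are available, matching the two contextual descriptors used by
#' the attention modules.
#'
#' @param x numeric array `(C, H, W)`.
#' @param mode `"avg"` or `"max"`.
#' @param axis `"spatial"` (returns a length-C vector) or `"channel"`
#'   (returns a `1 x H x W` array).
#' @return pooled statistic (see `axis`).
#' @export
globalPool <- function(x, mode = c("avg", "max"), axis = c("spatial", "channel")) {
  mode <- match.arg(mode)
  axis <- match.arg(axis)
  d <- dim(x)
  if (length(d) != 3L) stop("globalPool: x must be a (C, H, W) array")
  if (any(d == 0L)) stop("globalPool: empty extent along pooled axis")
  if (axis == "spatial") {
    m <- matrix(x, nrow = d[1])
    if (mode == "avg") rowMeans(m) else apply(m, 1L, max)
  } else {
    if (mode == "avg") array(colMeans(x, dims = 1L), c(1L, d[2], d[3]))
    else array(apply(x, c(2L, 3L), max), c(1L, d[2], d[3]))
  }
}
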