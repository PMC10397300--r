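# Residual / channel / spatial attention primitives.  All public functions
# operate on a single (C, H, W) feature tensor; the batched training-time
# versions in layers-attention.R reuse the same index machinery.

# Permutation applied by channelShuffle: channel c (0-based) decomposes as
# (group n, subgroup s, offset k) and moves to position s*(C/S) + n*(C/(N*S)) + k,
# i.e. the (N, S) transpose-interleave.  Returns 1-based destination indices.
.shufflePerm <- function(C, N, S) {
  if (C %% (N * S) != 0L)
    stop(sprintf("channel count %d is not divisible by N*S = %d", C, N * S))
  blk <- C %/% (N * S)
  c0 <- 0:(C - 1L)
  n <- c0 %/% (C %/% N)
  rem <- c0 %% (C %/% N)
  s <- rem %/% blk
  k <- rem %% blk
  pos <- s * (C %/% S) + n * blk + k
  pos + 1L
}

#' Channel shuffle
#'
#' Permutes the channels of a feature tensor by the (N, S) transpose-interleave
#' so that information mixes across the N feature groups and their S subgroups.
#' The output is an exact permutation of the input channel slices; applying
#' `channelShuffle(x, S, N)` afterwards restores the original order.
#'
#' @param x numeric array `(C, H, W)`.
#' @param N number of feature groups.
#' @param S subgroups per group; `N * S` must divide C.
#' @return array of the same shape with channels permuted.
#' @export
channelShuffle <- function(x, N, S) {
  d <- dim(x)
  if (length(d) != 3L) stop("channelShuffle: x must be a (C, H, W) array")
  pos <- .shufflePerm(d[1], N, S)
  y <- x
  y[pos, , ] <- x
  y
}

# One counter-clockwise quarter turn of the spatial axes of a (C, H, W) array.
.rot90ccw3 <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(1L, 3L, 2L))          # y[c, i, j] = x[c, j, i]
  y[, rev(seq_len(d[2])), , drop = FALSE]
}

#' Rotate the spatial map of a subgroup
#'
#' Applies the r * 90-degree rotation about the grid centre to every channel of
#' a square feature tensor.  The channel axis is untouched and the multiset of
#' spatial values is conserved; four single quarter turns compose to the
#' identity.
#'
#' @param x numeric array `(C, H, W)` with `H == W`.
#' @param r rotation index in `0..3` (counter-clockwise quarter turns).
#' @return rotated array of the same shape.
#' @export
rotateSubgroup <- function(x, r) {
  d <- dim(x)
  if (length(d) != 3L) stop("rotateSubgroup: x must be a (C, H, W) array")
  if (d[2] != d[3]) stop("rotateSubgroup: spatial map must be square (H == W)")
  if (!(r %in% 0:3)) stop("rotateSubgroup: r must be an integer in 0..3")
  for (i in seq_len(r)) x <- .rot90ccw3(x)
  x
}

# Plain (ungrouped) same-padding stride-1 convolution of a (C, H, W) tensor.
.conv3 <- function(x, W) {
  d <- dim(x)
  y <- .conv2dFwd(array(x, c(d, 1L)), dim(array(x, c(d, 1L))),
                  W, dim(W), 1L, 1L)
  array(y, dim(y)[1:3])
}

#' Residual attention block
#'
#' Splits a feature tensor into N groups of S subgroups, rotates subgroup s by
#' s quarter turns, pushes every subgroup through one shared 3 x 3 convolution
#' K, and modulates subgroups `s > 0` by the Hadamard product with the group's
#' base response `y0`:
#' `y_0 = K(x_0)`, `y_s = K(g_s(x_s)) * y_0` for `0 < s < S`.
#' Outputs the subgroup responses concatenated back to the input shape.
#'
#' @param x numeric array `(C, H, W)` with square spatial map.
#' @param K shared convolution weights, array `(3, 3, C/(N*S), C/(N*S))`.
#' @param N number of feature groups.
#' @param S subgroups per group (the rotation index runs over `0..S-1`).
#' @return array of the same shape as `x`.
#' @export
residualAttentionBlock <- function(x, K, N = 1L, S = 4L) {
  d <- dim(x)
  if (length(d) != 3L) stop("residualAttentionBlock: x must be (C, H, W)")
  if (d[2] != d[3]) stop("residualAttentionBlock: spatial map must be square")
  if (d[1] %% (N * S) != 0L)
    stop(sprintf("residualAttentionBlock: subgroup count mismatch: %d channels cannot form %d x %d subgroups",
                 d[1], N, S))
  cs <- d[1] %/% (N * S)
  if (!identical(dim(K), c(3L, 3L, cs, cs)) && !identical(dim(K), c(3L, 3L, as.integer(cs), as.integer(cs))))
    stop(sprintf("residualAttentionBlock: K must be (3, 3, %d, %d)", cs, cs))
  y <- x
  for (n in seq_len(N)) {
    base <- (n - 1L) * (d[1] %/% N)
    y0 <- NULL
    for (s in 0:(S - 1L)) {
      ch <- base + s * cs + seq_len(cs)
      zs <- .conv3(rotateSubgroup(x[ch, , , drop = FALSE], s %% 4L), K)
      if (s == 0L) y0 <- zs else zs <- zs * y0
      y[ch, , ] <- zs
    }
  }
  y
}

#' Initialise channel-attention weights
#'
#' Creates the two shared fully connected layers of the channel-attention
#' module: a squeeze layer of width `ceiling(channels / reduction)` with ReLU,
#' and an excitation layer back to `channels` with sigmoid.
#'
#' @param channels channels per feature group (C/N).
#' @param reduction bottleneck ratio of the squeeze layer.
#' @param init `"he"` for random fan-in-scaled weights, `"zero"` for all-zero.
#' @param seed RNG seed used for `"he"` initialisation.
#' @return list with `fc1W`, `fc1b`, `fc2W`, `fc2b`.
#' @export
initChannelAttention <- function(channels, reduction = 16L, init = c("he", "zero"),
                                 seed = 1L) {
  init <- match.arg(init)
  if (reduction < 1L) stop("initChannelAttention: reduction must be >= 1")
  hidden <- max(1L, as.integer(ceiling(channels / reduction)))
  if (init == "zero") {
    list(fc1W = matrix(0, hidden, channels), fc1b = numeric(hidden),
         fc2W = matrix(0, channels, hidden), fc2b = numeric(channels))
  } else {
    rng <- .seededRNG(seed)
    list(fc1W = matrix(rng$rnorm(hidden * channels, sd = sqrt(2 / channels)),
                       hidden, channels),
         fc1b = numeric(hidden),
         fc2W = matrix(rng$rnorm(channels * hidden, sd = sqrt(2 / hidden)),
                       channels, hidden),
         fc2b = numeric(channels))
  }
}

#' Channel attention map of one feature group
#'
#' Global average pooling over spatial positions gathers one statistic per
#' channel; two shared fully connected layers (ReLU then sigmoid) turn the
#' pooled vector into per-channel gates strictly inside (0, 1).
#'
#' @param g numeric array `(C/N, H, W)`: one feature group.
#' @param params weight list from [initChannelAttention()].
#' @return numeric vector of per-channel attention weights in (0, 1).
#' @export
channelAttention <- function(g, params) {
  d <- dim(g)
  if (length(d) != 3L) stop("channelAttention: g must be (C, H, W)")
  if (d[2] * d[3] == 0L) stop("channelAttention: empty spatial extent")
  p <- rowMeans(matrix(g, nrow = d[1]))
  h <- pmax(drop(params$fc1W %*% p) + params$fc1b, 0)
  drop(stats::plogis(drop(params$fc2W %*% h) + params$fc2b))
}

#' Group-summed channel-attention output
#'
#' Applies per-group channel gates and sums the gated groups:
#' `C = sum_n (C^n * G^n)`, producing a tensor with `C/N` channels.
#'
#' @param groups list of N feature groups, each `(C/N, H, W)`, or a single
#'   `(C, H, W)` tensor together with `N`.
#' @param maps list of N per-group attention-weight vectors (length C/N each).
#' @param N number of groups when `groups` is a single tensor.
#' @return numeric array `(C/N, H, W)`.
#' @export
applyChannelAttention <- function(groups, maps, N = length(maps)) {
  if (!is.list(groups)) {
    d <- dim(groups)
    if (d[1] %% N != 0L) stop("applyChannelAttention: N must divide the channel count")
    cg <- d[1] %/% N
    groups <- lapply(seq_len(N), function(n)
      groups[(n - 1L) * cg + seq_len(cg), , , drop = FALSE])
  }
  if (length(groups) != length(maps))
    stop("applyChannelAttention: need one attention map per group")
  d <- dim(groups[[1]])
  out <- array(0, d)
  for (n in seq_along(groups)) {
    g <- groups[[n]]
    if (!identical(dim(g), d)) stop("applyChannelAttention: group shape mismatch")
    if (length(maps[[n]]) != d[1]) stop("applyChannelAttention: map length mismatch")
    out <- out + g * as.numeric(maps[[n]])   # weights recycle along channels
  }
  out
}

#' Spatial descriptor (average and max maps)
#'
#' Stacks the channel-wise average map and channel-wise maximum map of a
#' feature tensor into a `2 x H x W` descriptor.  The max map dominates the
#' average map at every position.
#'
#' @param x numeric array `(C, H, W)`.
#' @return array `(2, H, W)`: average map first, max map second.
#' @export
spatialDescriptor <- function(x) {
  avg <- globalPool(x, "avg", "channel")
  mx <- globalPool(x, "max", "channel")
  out <- array(0, c(2L, dim(x)[2], dim(x)[3]))
  out[1L, , ] <- avg[1L, , ]
  out[2L, , ] <- mx[1L, , ]
  out
}

#' Initialise spatial-attention weights
#'
#' @param variant `"concat"` (3 x 3 convolution over the stacked 2-channel
#'   descriptor) or `"sum"` (descriptors added first, 1-channel convolution).
#' @param init `"he"` or `"zero"` weight initialisation.
#' @param seed RNG seed for `"he"` initialisation.
#' @return list with convolution weights `W` `(3, 3, 2 or 1, 1)` and bias `b`.
#' @export
initSpatialAttention <- function(variant = c("concat", "sum"),
                                 init = c("he", "zero"), seed = 1L) {
  variant <- match.arg(variant)
  init <- match.arg(init)
  cin <- if (variant == "concat") 2L else 1L
  W <- if (init == "zero") array(0, c(3L, 3L, cin, 1L))
  else {
    rng <- .seededRNG(seed)
    array(rng$rnorm(9L * cin, sd = sqrt(2 / (9 * cin))), c(3L, 3L, cin, 1L))
  }
  list(W = W, b = 0, variant = variant)
}

#' Spatial attention
#'
#' Builds the channel-pooled average/max descriptor of the input, reduces it to
#' a single map with a 3 x 3 convolution, squashes the map through a sigmoid,
#' and modulates every channel of the input with the resulting per-position
#' gate in (0, 1).  The op is therefore a contraction in max-norm.
#'
#' @param x numeric array `(C, H, W)`.
#' @param params weight list from [initSpatialAttention()].
#' @return gated array of the same shape as `x`.
#' @export
spatialAttention <- function(x, params) {
  d <- dim(x)
  if (length(d) != 3L) stop("spatialAttention: x must be (C, H, W)")
  if (!all(is.finite(x))) stop("spatialAttention: x must be finite")
  sc <- spatialDescriptor(x)
  if (params$variant == "sum")
    sc <- array(sc[1L, , ] + sc[2L, , ], c(1L, d[2], d[3]))
  m <- .conv3(sc, params$W) + params$b
  gate <- stats::plogis(m[1L, , ])
  x * rep(as.numeric(gate), each = d[1])
}
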