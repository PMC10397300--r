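test_that("channel shuffle is the (N,S) transpose-interleave permutation", {
  # worked 4-channel example: channels (0,1,2,3) -> (0,2,1,3)
  x <- array(0, c(4, 2, 2))
  for (c0 in 1:4) x[c0, , ] <- c0 - 1
  y <- channelShuffle(x, N = 2, S = 2)
  expect_equal(y[, 1, 1], c(0, 2, 1, 3))
  # degenerate groupings are the identity
  x <- randTensor(8, 3, 3)
  expect_equal(channelShuffle(x, 1, 1), x)
  expect_equal(channelShuffle(x, 1, 2), oracleShuffle(x, 1, 2))
  # involution: shuffle(N,S) then shuffle(S,N) restores the input
  set.seed(41)
  for (i in 1:10) {
    C <- sample(c(8, 16, 24), 1)
    x <- randTensor(C, 3, 3)
    expect_equal(channelShuffle(channelShuffle(x, 2, 4), 4, 2), x)
    # multiset of channel slices preserved (exact sum conservation)
    expect_identical(sum(channelShuffle(x, 4, 2)), sum(x))
    expect_equal(channelShuffle(x, 2, 2), oracleShuffle(x, 2, 2))
  }
  expect_error(channelShuffle(randTensor(6, 2, 2), 2, 4), "divisible")
})

test_that("subgroup rotation matches the quarter-turn coordinate map", {
  # 2x2 worked example: r=1 sends [[a,b],[c,d]] to [[b,d],[a,c]]
  x <- array(c(1, 3, 2, 4), c(1, 2, 2))      # [[1,2],[3,4]] per channel
  y <- rotateSubgroup(x, 1)
  expect_equal(y[1, , ], matrix(c(2, 1, 4, 3), 2))   # [[2,4],[1,3]]
  set.seed(42)
  for (i in 1:10) {
    x <- randTensor(3, 5, 5)
    expect_equal(rotateSubgroup(x, 0), x)
    for (r in 0:3) expect_equal(rotateSubgroup(x, r), oracleRotate(x, r))
    # full turn is the identity; r=2 equals two applications of r=1
    expect_equal(rotateSubgroup(rotateSubgroup(
      rotateSubgroup(rotateSubgroup(x, 1), 1), 1), 1), x)
    expect_equal(rotateSubgroup(x, 2),
                 rotateSubgroup(rotateSubgroup(x, 1), 1))
    # multiset of spatial values conserved
    expect_equal(sort(as.vector(rotateSubgroup(x, 3))), sort(as.vector(x)))
  }
  expect_error(rotateSubgroup(randTensor(2, 3, 4), 1), "square")
})

test_that("residual attention block composes rotation, shared conv and gating", {
  # identity-preserving 1-channel conv on constant subgroups: y0 = c, ys = c^2
  K <- array(0, c(3, 3, 1, 1)); K[2, 2, 1, 1] <- 1
  x <- array(3, c(4, 2, 2))                  # 4 constant subgroups of 1 channel
  y <- residualAttentionBlock(x, K, N = 1, S = 4)
  expect_equal(y[1, , ], matrix(3, 2, 2))    # s = 0: K(x0)
  for (s in 2:4) expect_equal(y[s, , ], matrix(9, 2, 2))  # s > 0: K(xs) * y0
  # y0 = 0 forces every modulated subgroup to 0
  x0 <- x; x0[1, , ] <- 0
  y <- residualAttentionBlock(x0, K, N = 1, S = 4)
  expect_true(all(y[2:4, , ] == 0))
  # S = 1 reduces to the plain shared convolution
  set.seed(43)
  x <- randTensor(2, 4, 4)
  K2 <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  expect_equal(residualAttentionBlock(x, K2, N = 1, S = 1),
               oracleConv(x, K2), tolerance = 1e-10)
  # full hand-built oracle: rotate, conv, multiply by y0, per group
  for (i in 1:5) {
    x <- randTensor(8, 4, 4)
    Ks <- array(rnorm(9), c(3, 3, 1, 1))
    got <- residualAttentionBlock(x, Ks, N = 2, S = 4)
    want <- x
    for (n in 0:1) {
      y0 <- oracleConv(x[n * 4 + 1, , , drop = FALSE], Ks)
      want[n * 4 + 1, , ] <- y0
      for (s in 1:3)
        want[n * 4 + s + 1, , ] <-
          oracleConv(oracleRotate(x[n * 4 + s + 1, , , drop = FALSE], s), Ks)[1, , ] * y0[1, , ]
    }
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(residualAttentionBlock(randTensor(6, 4, 4), K, N = 2, S = 4),
               "subgroup")
})

test_that("channel attention gates match the pooled two-layer oracle", {
  # zero-initialised FC layers give sigmoid(0) = 0.5 everywhere
  g <- array(7, c(4, 3, 3))
  p0 <- initChannelAttention(4, reduction = 2, init = "zero")
  expect_equal(channelAttention(g, p0), rep(0.5, 4))
  set.seed(44)
  p <- initChannelAttention(4, reduction = 2, seed = 9)
  for (i in 1:10) {
    g <- randTensor(4, 3, 3)
    got <- channelAttention(g, p)
    expect_equal(got, oracleChannelAttention(g, p), tolerance = 1e-6)
    expect_true(all(got > 0 & got < 1))
    # permuting spatial positions leaves the GAP statistics unchanged
    perm <- sample(9)
    gp <- array(matrix(g, 4)[, perm], dim(g))
    expect_equal(channelAttention(gp, p), got)
  }
})

test_that("group-summed channel attention follows the weighted-sum contract", {
  set.seed(45)
  # N = 1: plain elementwise gating; unit weights: plain group sum
  x <- randTensor(4, 3, 3)
  expect_equal(applyChannelAttention(x, list(rep(1, 4)), N = 1), x)
  w <- runif(4)
  expect_equal(applyChannelAttention(x, list(w), N = 1), x * w)
  x8 <- randTensor(8, 3, 3)
  expect_equal(applyChannelAttention(x8, list(rep(1, 4), rep(1, 4)), N = 2),
               x8[1:4, , ] + x8[5:8, , ])
  # random instances against an explicit loop oracle
  for (i in 1:10) {
    x8 <- randTensor(8, 4, 4)
    maps <- list(runif(4), runif(4))
    got <- applyChannelAttention(x8, maps, N = 2)
    want <- array(0, c(4, 4, 4))
    for (n in 1:2) for (c0 in 1:4)
      want[c0, , ] <- want[c0, , ] + maps[[n]][c0] * x8[(n - 1) * 4 + c0, , ]
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(applyChannelAttention(x8, list(runif(4)), N = 2), "map")
})

test_that("spatial attention is a sigmoid-gated contraction", {
  set.seed(46)
  # constant input: avg and max descriptors coincide
  k <- array(1.5, c(3, 4, 4))
  sd0 <- spatialDescriptor(k)
  expect_equal(sd0[1, , ], sd0[2, , ])
  x <- randTensor(4, 5, 5)
  sdx <- spatialDescriptor(x)
  expect_true(all(sdx[2, , ] >= sdx[1, , ]))
  for (variant in c("concat", "sum")) {
    p <- initSpatialAttention(variant, seed = 5)
    for (i in 1:5) {
      x <- randTensor(8, 5, 5)
      got <- spatialAttention(x, p)
      expect_equal(got, oracleSpatialAttention(x, p), tolerance = 1e-6)
      # gate in (0,1): |S| <= |C| elementwise, contraction in max-norm
      expect_true(all(abs(got) <= abs(x) + 1e-12))
      expect_lte(max(abs(got)), max(abs(x)) + 1e-12)
    }
  }
})
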