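# A small configuration exercising every architectural element (bottlenecks,
# grouped convs, projections, attention, LRN) at toy scale.
tinyConfig <- function(numClasses = 3L, inputSize = c(25L, 25L),
                       attention = list(groups = 2L, subgroups = 4L, reduction = 4L),
                       lrn = TRUE) {
  burnNeXtConfig(numClasses = numClasses, cardinality = 2L, widthFactor = 1 / 16,
                 inputSize = inputSize, attention = attention, lrn = lrn)
}

test_that("stock configurations reproduce the two stage-table topologies", {
  cfg <- burnNeXtConfig()
  widths <- vapply(cfg@stages, function(s) s@ops[[length(s@ops)]]$out, 0L)
  expect_equal(widths, c(256L, 128L, 256L, 512L, 1024L))
  rx <- resNeXt50Config()
  expect_equal(vapply(rx@stages, function(s) s@ops[[length(s@ops)]]$out, 0L),
               c(64L, 256L, 512L, 1024L, 2048L))
  expect_equal(cfg@cardinality, 32L)
  expect_equal(cfg@stages[[1]]@ops[[1]]$k, c(5L, 5L))
  expect_equal(rx@stages[[1]]@ops[[1]]$k, c(7L, 7L))
  # invariant violations are configuration errors naming the stage
  expect_error(stageSpec("conv2", list(list(k = 1, out = 32, groups = 1)),
                         repeats = 0L), "repeats")
  expect_error(stageSpec("conv3", list(list(k = 3, out = 30, groups = 32))),
               "conv3")
  expect_error(buildModel(burnNeXtConfig(widthFactor = 0.5)), "divide")
})

test_that("shape derivation follows ceil-mode stride arithmetic", {
  sh <- deriveShapes(burnNeXtConfig())
  expect_equal(sh$stage, c("conv1", "pool", "conv2", "conv3", "conv4", "conv5", "gap"))
  expect_equal(sh$C, c(256L, 256L, 128L, 256L, 512L, 1024L, 1024L))
  expect_equal(sh$H, c(50L, 25L, 25L, 13L, 7L, 4L, 1L))
  expect_equal(sh$W, sh$H)
  # stride-1 everywhere preserves the spatial size
  cfg1 <- tinyConfig()
  for (i in seq_along(cfg1@stages)) {
    cfg1@stages[[i]]@stride <- 1L
    cfg1@stages[[i]]@pool <- NULL
  }
  sh1 <- deriveShapes(cfg1)
  expect_true(all(sh1$H[sh1$stage != "gap"] == 25L))
  # degenerate 1x1 input stays 1x1 under ceil mode
  shd <- deriveShapes(burnNeXtConfig(inputSize = c(1L, 1L)))
  expect_true(all(shd$H == 1L))
})

test_that("forward pass yields row-stochastic outputs and matches the trace", {
  cfg <- tinyConfig()
  m <- buildModel(cfg, seed = 2)
  set.seed(52)
  batch <- array(runif(2 * 3 * 25 * 25), c(2, 3, 25, 25))
  p <- forwardPass(m, batch, trace = TRUE)
  expect_equal(dim(p), c(2L, 3L))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # duplicated inputs give identical outputs (deterministic inference)
  dup <- array(0, c(2, 3, 25, 25)); dup[1, , , ] <- batch[1, , , ]; dup[2, , , ] <- batch[1, , , ]
  pd <- forwardPass(m, dup)
  expect_equal(pd[1, ], pd[2, ], tolerance = 1e-12)
  # forward shape trace equals the derived trace
  sh <- deriveShapes(cfg)
  tr <- attr(p, "shapes")
  for (nm in c("conv1", "conv2", "conv3", "conv4", "conv5")) {
    row <- sh[sh$stage == nm, ]
    expect_equal(unname(tr[[nm]][1:3]), c(row$C, row$H, row$W), info = nm)
  }
  expect_equal(unname(tr[["pool_conv1"]][1:3]),
               unname(unlist(sh[sh$stage == "pool", c("C", "H", "W")])))
  expect_equal(tr[["gap"]][1], sh$C[sh$stage == "gap"])
  # zero-weight classifier head gives uniform probabilities
  m0 <- m
  m0@net$modules$fc$params$W[] <- 0
  m0@net$modules$fc$params$b[] <- 0
  p0 <- forwardPass(m0, batch)
  expect_equal(as.vector(p0), rep(1 / 3, 6), tolerance = 1e-12)
  expect_error(forwardPass(m, array(1, c(2, 3, 10, 10))), "shape")
})

test_that("parameter accounting matches independent arithmetic and is monotone", {
  cfg <- burnNeXtConfig()
  rx <- resNeXt50Config()
  # independent per-layer sums over the stage tables (computed by hand with
  # k_h*k_w*(C_in/g)*C_out and frozen here)
  expect_identical(countParameters(cfg, "stage_tabulation"), 4898912)
  expect_identical(countParameters(rx, "stage_tabulation"), 20142784)
  expect_identical(countParameters(rx, "full_backbone"), 22911680)
  # printed rounded counts: 5 x 10^6 and 23 x 10^6
  expect_equal(round(countParameters(cfg, "stage_tabulation") / 1e6), 5)
  expect_equal(round(countParameters(rx, "full_backbone") / 1e6), 23)
  # monotone under the three conventions
  for (cc in list(cfg, rx)) {
    a <- countParameters(cc, "stage_tabulation")
    b <- countParameters(cc, "full_backbone")
    d <- countParameters(cc, "all")
    expect_lte(a, b); expect_lte(b, d)
  }
  expect_error(countParameters(cfg, "bogus"), "arg")
  # per-stage breakdown sums to the total
  br <- parameterBreakdown(cfg, "stage_tabulation")
  expect_equal(sum(br$params), countParameters(cfg, "stage_tabulation"))
})

test_that("zeroed bottleneck with identity shortcut is the identity on non-negative maps", {
  ns <- asNamespace("BurnNeXt")
  blk <- ns$.mkBlock(8L, 4L, 8L, 2L, 1L, 0.01, ns$.seededRNG(3))
  expect_null(blk$children$sc)            # identity shortcut
  flat <- ns$.gatherParams(blk)
  for (k in grep("/W$", names(flat), value = TRUE)) flat[[k]][] <- 0
  blk0 <- ns$.setParams(blk, flat)
  x <- array(abs(rnorm(8 * 5 * 5 * 2)), c(8, 5, 5, 2))
  y <- ns$.modFwd(blk0, x, training = TRUE)$y
  expect_identical(y, x)
})

test_that("grouped convolution equals the per-group loop oracle", {
  set.seed(53)
  ns <- asNamespace("BurnNeXt")
  for (i in 1:10) {
    x <- randTensor(8, 5, 5)
    W <- array(rnorm(3 * 3 * 2 * 8), c(3, 3, 2, 8))   # 4 groups of 2 channels
    got <- ns$.conv2dFwd(array(x, c(8, 5, 5, 1)), c(8L, 5L, 5L, 1L),
                         W, dim(W), 1L, 4L)
    expect_equal(array(got, c(8, 5, 5)), oracleConv(x, W, 1, 4), tolerance = 1e-10)
    # cardinality equivalence: grouped conv = sum of per-group convs on the
    # channel partition (each group written into its own output slots)
    for (g in 1:4) {
      sub <- oracleConv(x[(g - 1) * 2 + 1:2, , , drop = FALSE],
                        W[, , , (g - 1) * 2 + 1:2, drop = FALSE], 1, 1)
      expect_equal(array(got, c(8, 5, 5))[(g - 1) * 2 + 1:2, , ], sub,
                   tolerance = 1e-10)
    }
  }
})

test_that("checkpoints round-trip weights, history and config", {
  cfg <- tinyConfig()
  m <- buildModel(cfg, seed = 4)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(m, path)
  m2 <- loadCheckpoint(path)
  set.seed(54)
  batch <- array(runif(3 * 25 * 25), c(1, 3, 25, 25))
  expect_equal(forwardPass(m, batch), forwardPass(m2, batch), tolerance = 1e-12)
  expect_equal(m2@config@numClasses, 3L)
  cfgPath <- tempfile(fileext = ".yaml")
  writeModelConfig(cfg, cfgPath)
  cfg2 <- readModelConfig(cfgPath)
  expect_equal(deriveShapes(cfg2), deriveShapes(cfg))
  expect_equal(countParameters(cfg2, "all"), countParameters(cfg, "all"))
})
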