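test_that("stratified k-fold splits partition the ids", {
  labs <- factor(rep(c("a", "b", "c"), each = 20))
  folds <- kfoldSplit(1:60, k = 5, seed = 3, strata = labs)
  expect_equal(length(folds), 5L)
  vals <- lapply(folds, `[[`, "val")
  expect_equal(sort(unlist(vals)), 1:60)                      # union = all ids
  expect_equal(sum(duplicated(unlist(vals))), 0L)             # pairwise disjoint
  for (f in folds) {
    expect_equal(length(f$val), 12L)                          # 20% each
    expect_equal(sort(c(f$train, f$val)), 1:60)
    expect_length(intersect(f$train, f$val), 0L)              # no leakage
    expect_equal(as.vector(table(labs[f$val])), rep(4L, 3))   # stratified
  }
  # deterministic under the seed
  expect_identical(folds, kfoldSplit(1:60, k = 5, seed = 3, strata = labs))
  expect_false(identical(vals,
                         lapply(kfoldSplit(1:60, 5, seed = 4, strata = labs),
                                `[[`, "val")))
  # unstratified: 100 ids -> five folds of 20
  f100 <- kfoldSplit(1:100, k = 5, seed = 1)
  expect_true(all(vapply(f100, function(f) length(f$val), 0L) == 20L))
  expect_error(kfoldSplit(1:3, k = 5), "at least")
})

test_that("confusion matrices count true-by-predicted pairs", {
  cm <- confusionMatrix(c(0, 0, 1, 1), c(0, 1, 1, 1), k = 2)
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 2L), 2))
  expect_equal(sum(cm), 4L)
  # perfect predictions give a diagonal matrix
  y <- sample(0:2, 30, replace = TRUE)
  cmd <- confusionMatrix(y, y, k = 3)
  expect_true(all(cmd[upper.tri(cmd) | lower.tri(cmd)] == 0L))
  expect_equal(sum(diag(cmd)), 30L)
  # factors carry their level names
  f <- factor(c("x", "y", "x"), levels = c("x", "y"))
  cmf <- confusionMatrix(f, f)
  expect_equal(rownames(cmf), c("x", "y"))
  expect_error(confusionMatrix(c(0, 3), c(0, 1), k = 2), "range")
  expect_error(confusionMatrix(c(0, 1), c(0), k = 2), "length")
})

test_that("the metric suite reproduces the worked TP=9/FP=1/FN=1/TN=9 example", {
  cm <- matrix(c(9L, 1L, 1L, 9L), 2, byrow = TRUE)   # TP=9 FN=1 / FP=1 TN=9
  std <- metricsFromCM(cm, "standard")
  expect_equal(std@perClass$Precision[1], 90)
  expect_equal(std@perClass$Recall[1], 90)
  expect_equal(std@perClass$F1[1], 90)
  expect_equal(std@perClass$Accuracy[1], 90)
  expect_equal(std@perClass$Specificity[1], 90)       # TN/(TN+FP)
  lit <- metricsFromCM(cm, "paper_literal")
  expect_equal(lit@perClass$Specificity[1], 50)       # TN/(TP+TN) as printed
  expect_equal(lit@perClass$Recall, std@perClass$Recall)
  # perfect diagonal: every metric 100
  perf <- metricsFromCM(diag(c(5L, 7L, 9L)))
  expect_true(all(as.matrix(perf@perClass) == 100))
  expect_equal(perf@overallAccuracy, 100)
  expect_error(metricsFromCM(matrix(0L, 2, 2)), "all-zero")
})

test_that("metrics agree with the exact-arithmetic oracle on random matrices", {
  set.seed(71)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    cm <- matrix(rpois(k * k, lambda = sample(c(0.5, 3, 20), 1)), k)
    if (sum(cm) == 0) cm[1, 1] <- 1L
    for (literal in c(FALSE, TRUE)) {
      rep <- metricsFromCM(cm, if (literal) "paper_literal" else "standard")
      want <- oracleMetrics(cm, literal)
      got <- as.matrix(rep@perClass)
      dimnames(got) <- NULL; dimnames(want) <- NULL
      expect_equal(got, want, tolerance = 1e-9)
      # recall and sensitivity identical by definition
      expect_identical(rep@perClass$Recall, rep@perClass$Sensitivity)
      # undefined cells are flagged, never zero-filled
      expect_equal(sum(is.na(got)), sum(is.na(want)))
      if (anyNA(got)) expect_gt(length(rep@flags), 0)
    }
  }
})

test_that("ROC curves are monotone and match the rank-statistic AUC", {
  # scores identical to labels rank perfectly
  expect_equal(rocCurve(c(0, 1, 0, 1), c(0, 1, 0, 1))$auc, 1)
  # constant scores are chance
  expect_equal(rocCurve(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  set.seed(72)
  for (i in 1:30) {
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(20), 2)                 # rounded scores force ties
    r <- rocCurve(y, s)
    expect_equal(r$auc, oracleAUC(y, s), tolerance = 1e-9)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
    expect_equal(tail(r$points$fpr, 1), 1); expect_equal(tail(r$points$tpr, 1), 1)
  }
  # single-class truth: undefined AUC with a flag
  r1 <- rocCurve(rep(1, 5), runif(5))
  expect_true(is.na(r1$auc))
  expect_match(r1$flag, "single-class")
  # multiclass one-vs-rest: one curve per class
  labs <- factor(c("a", "b", "c", "a", "b", "c"))
  sc <- matrix(runif(18), 6, dimnames = list(NULL, c("a", "b", "c")))
  sc <- sc / rowSums(sc)
  rs <- rocCurve(labs, sc)
  expect_equal(names(rs), c("a", "b", "c"))
  expect_error(rocCurve(c(0, 1), c(-0.2, 0.5)), "0, 1")
})

test_that("cross-validation solves a perfectly separable toy problem", {
  # labels encoded in a solid colour (red / green / blue), with slight pixel
  # noise so mini-batch normalisation statistics are non-degenerate
  n <- 10
  imgs <- list(); labels <- character()
  cols <- list(superficial = c(230, 40, 40), deep_dermal = c(40, 230, 40),
               full_thickness = c(40, 40, 230))
  set.seed(73)
  k <- 0
  for (lbl in names(cols)) for (i in 1:n) {
    px <- array(0, c(20, 20, 3))
    for (ch in 1:3) px[, , ch] <- cols[[lbl]][ch]
    px <- px + array(rnorm(1200, 0, 8), dim(px))
    px <- array(as.integer(pmin(pmax(round(px), 0), 255)), dim(px))
    k <- k + 1
    imgs[[k]] <- px; labels[k] <- lbl
  }
  ds <- new("BurnImageSet", images = imgs,
            manifest = data.frame(id = sprintf("t%02d", 1:k), label = labels,
                                  source = "synthetic"))
  cfg <- burnNeXtConfig(numClasses = 3, cardinality = 2, widthFactor = 1 / 8,
                        inputSize = c(20, 20), attention = FALSE, lrn = FALSE)
  hp <- trainingHyperparams(lr = 1e-2, batchSize = 15, epochs = 60, seed = 2)
  cv <- runCVExperiment(ds, "degree", cfg, params = hp, k = 5, seed = 11)
  tab <- metricsTable(cv)
  expect_equal(nrow(tab), 6L)                        # 5 folds + average
  expect_equal(tab$Fold, c(paste0("Fold", 1:5), "Average"))
  expect_true(all(tab$Accuracy == 100))
  expect_true(all(tab$Precision == 100))
  # average row is the arithmetic mean of the fold rows
  expect_equal(unlist(tab[6, -1]), colMeans(tab[1:5, -1]), tolerance = 0.01)
  # pooled per-class AUC is perfect on a separable problem
  expect_true(all(cv@auc == 1))
  # the run log records policy and reproducibility anchors
  expect_equal(cv@log$seed, 11)
  expect_equal(cv@log$augmentPolicy, "training folds only")
  expect_true(is.integer(cv@log$configHash))
  # reports can be written out
  dir <- tempfile("cvout")
  paths <- writeCVReport(cv, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(nrow(read.csv(file.path(dir, "metrics.csv"))), 6L)
  # arity mismatch is an error
  expect_error(runCVExperiment(ds, "graft", cfg, params = hp, seed = 1),
               "classes")
})
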