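test_that("the generator is a pure function of its configuration", {
  cfg <- synthConfig(nPerClass = 4, imageSize = c(40, 40), seed = 7)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(d1@images, d2@images)
  expect_identical(manifest(d1), manifest(d2))
  # a different seed changes pixels but not the class balance
  d3 <- generateDataset(synthConfig(nPerClass = 4, imageSize = c(40, 40), seed = 8))
  expect_false(identical(d1@images, d3@images))
  expect_equal(table(manifest(d3)$label), table(manifest(d1)$label))
})

test_that("dataset counts, labels and manifest are consistent", {
  cfg <- synthConfig(nPerClass = 5, imageSize = c(32, 32), seed = 1)
  ds <- generateDataset(cfg)
  expect_equal(nImages(ds), 15L)
  expect_equal(as.vector(table(manifest(ds)$label)), rep(5L, 3))
  expect_setequal(unique(manifest(ds)$label),
                  c("superficial", "deep_dermal", "full_thickness"))
  expect_equal(levels(imageLabels(ds)),
               c("superficial", "deep_dermal", "full_thickness"))
  for (i in seq_len(nImages(ds))) {
    px <- imageData(ds, i)
    expect_equal(dim(px), c(32L, 32L, 3L))
    expect_true(all(px >= 0L & px <= 255L))
    expect_true(is.integer(px))
  }
})

test_that("lesion palettes carry the class colour semantics", {
  # noiseless superficial lesion: red channel dominates blue
  cfg <- synthConfig(nPerClass = 1, imageSize = c(60, 60), seed = 3, noiseSD = 0)
  img <- generateBurnImage("superficial", cfg, seed = 3)
  expect_equal(img$label, "superficial")
  expect_equal(img$source, "synthetic")
  px <- img$pixels
  expect_gt(mean(px[, , 1]), mean(px[, , 3]))
  # palettes are well-formed for every class
  for (lbl in c("superficial", "deep_dermal", "full_thickness")) {
    pal <- classPalette(lbl)
    expect_equal(sum(pal$weights), 1)
    for (a in pal$anchors) expect_true(all(a >= 0 & a <= 255))
  }
  expect_error(classPalette("fourth_degree"), "arg")
  # same seed gives bit-identical images
  i1 <- generateBurnImage("deep_dermal", cfg, seed = 11)
  i2 <- generateBurnImage("deep_dermal", cfg, seed = 11)
  expect_identical(i1$pixels, i2$pixels)
})

test_that("classes are colour-separable at default noise", {
  # default geometry (100x100, semi-axes 20-35, centre jitter 10): the
  # central patch always lies inside the lesion, so its mean approximates
  # the lesion colour without knowing the mask
  cfg <- synthConfig(nPerClass = 100, seed = 19)
  ds <- generateDataset(cfg)
  labs <- imageLabels(ds)
  centerPatch <- function(px) {
    i <- 44:57
    c(mean(px[i, i, 1]), mean(px[i, i, 2]), mean(px[i, i, 3]))
  }
  lesion <- t(vapply(ds@images, centerPatch, numeric(3)))
  lcents <- do.call(rbind, lapply(levels(labs), function(l)
    colMeans(lesion[labs == l, , drop = FALSE])))
  # per-class sample means of lesion colour pairwise separated by > 2*noiseSD
  for (i in 1:2) for (j in (i + 1):3)
    expect_gt(sqrt(sum((lcents[i, ] - lcents[j, ])^2)), 2 * cfg@noiseSD)
  # trivial whole-image mean-colour centroid classifier reaches 95%
  feats <- t(vapply(ds@images, function(px)
    c(mean(px[, , 1]), mean(px[, , 2]), mean(px[, , 3])), numeric(3)))
  cents <- do.call(rbind, lapply(levels(labs), function(l)
    colMeans(feats[labs == l, , drop = FALSE])))
  pred <- apply(feats, 1, function(f) which.min(colSums((t(cents) - f)^2)))
  expect_gte(mean(levels(labs)[pred] == as.character(labs)), 0.95)
})

test_that("burn depths map onto the grafting decision", {
  expect_equal(as.character(toBinaryLabels("superficial")), "non_graft")
  expect_equal(as.character(toBinaryLabels("deep_dermal")), "graft")
  expect_equal(as.character(toBinaryLabels("full_thickness")), "graft")
  # total and 2-valued over the 3 labels
  all3 <- toBinaryLabels(c("superficial", "deep_dermal", "full_thickness"))
  expect_false(anyNA(all3))
  expect_equal(levels(all3), c("non_graft", "graft"))
  expect_error(toBinaryLabels("sunburn"), "unknown")
})
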