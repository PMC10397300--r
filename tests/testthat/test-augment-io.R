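testImage <- function(H = 20, W = 20, seed = 1) {
  set.seed(seed)
  array(sample(0:255, H * W * 3, replace = TRUE), c(H, W, 3L))
}

test_that("the default augmentation set yields original plus four transforms", {
  px <- testImage()
  out <- augmentImage(px, augmentationSet())
  expect_equal(length(out), 5L)
  expect_equal(names(out), c("original", "hflip", "vflip", "rot30", "rot-30"))
  expect_identical(out$original, px)
  for (o in out) expect_equal(dim(o), dim(px))
  # without the original flag: one image per transform
  out2 <- augmentImage(px, augmentationSet(includeOriginal = FALSE))
  expect_equal(length(out2), 4L)
  expect_error(augmentationSet(c("hflip", "hflip")), "distinct")
  expect_error(augmentationSet("swirl"), "unknown")
})

test_that("flips are involutive exact pixel permutations", {
  px <- testImage(15, 17)
  aug <- function(tf) augmentImage(px, augmentationSet(tf, FALSE))[[1]]
  expect_identical(augmentImage(aug("hflip"),
                                augmentationSet("hflip", FALSE))[[1]], px)
  expect_identical(augmentImage(aug("vflip"),
                                augmentationSet("vflip", FALSE))[[1]], px)
  # histogram (multiset of pixel values) conserved exactly by flips and
  # quarter turns
  for (tf in c("hflip", "vflip", "rot90", "rot270")) {
    out <- augmentImage(testImage(12, 12, 2), augmentationSet(tf, FALSE))[[1]]
    expect_identical(sort(as.vector(out)), sort(as.vector(testImage(12, 12, 2))))
  }
  # rot90 then rot270 is the identity
  sq <- testImage(12, 12, 3)
  r90 <- augmentImage(sq, augmentationSet("rot90", FALSE))[[1]]
  expect_identical(augmentImage(r90, augmentationSet("rot270", FALSE))[[1]], sq)
})

test_that("30-degree rotations preserve shape but not pixels", {
  px <- testImage(24, 24, 4)
  r <- augmentImage(px, augmentationSet(c("rot30", "rot-30"), FALSE))
  expect_equal(dim(r$rot30), dim(px))
  expect_equal(dim(r$`rot-30`), dim(px))
  expect_false(identical(r$rot30, px))
  # rot+30 then rot-30 is not exact (interpolation + reflect fill) but stays
  # the same shape and close in mean intensity
  back <- augmentImage(r$rot30, augmentationSet("rot-30", FALSE))[[1]]
  expect_equal(dim(back), dim(px))
  expect_lt(abs(mean(back) - mean(px)), 20)
})

test_that("datasets round-trip through PNG + manifest", {
  cfg <- synthConfig(nPerClass = 2, imageSize = c(24, 24), seed = 5)
  ds <- generateDataset(cfg)
  dir <- file.path(tempfile("dsdir"))
  mp <- writeDataset(ds, dir, cfg)
  expect_true(file.exists(mp))
  expect_true(file.exists(file.path(dir, "synth_config.yaml")))
  back <- loadDataset(mp, size = c(24, 24))
  expect_equal(nImages(back), nImages(ds))
  expect_equal(manifest(back)$label, manifest(ds)$label)
  # lossless PNG round trip at equal size: identical pixels
  expect_identical(back@images, ds@images)
})

test_that("loading resizes and reports corrupt rows without aborting", {
  cfg <- synthConfig(nPerClass = 2, imageSize = c(40, 30), seed = 6)
  ds <- generateDataset(cfg)
  dir <- file.path(tempfile("dsdir2"))
  mp <- writeDataset(ds, dir)
  # non-square source resized to the requested square
  rs <- loadDataset(mp, size = c(25, 25))
  expect_equal(dim(imageData(rs, 1)), c(25L, 25L, 3L))
  # corrupt one row: missing file; and one row: bad label
  man <- read.csv(mp, stringsAsFactors = FALSE)
  man$path[2] <- "images/does_not_exist.png"
  man$label[4] <- "frostbite"
  write.csv(man, mp, row.names = FALSE)
  expect_warning(bad <- loadDataset(mp, size = c(24, 24)), "row 2")
  expect_equal(nImages(bad), nrow(man) - 2L)
  errs <- attr(bad, "errors")
  expect_equal(errs$row, c(2L, 4L))
  expect_match(errs$message[2], "frostbite")
  expect_error(loadDataset(file.path(dir, "nope.csv")), "not found")
})

test_that("oversampling reaches an arbitrary target count deterministically", {
  cfg <- synthConfig(nPerClass = 2, imageSize = c(20, 20), seed = 9)
  ds <- generateDataset(cfg)
  big <- oversampleDataset(ds, 15, seed = 3)
  expect_equal(nImages(big), 15L)
  big2 <- oversampleDataset(ds, 15, seed = 3)
  expect_identical(big@images, big2@images)
  expect_error(oversampleDataset(ds, 3), ">=")
})
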