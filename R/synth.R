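# Synthetic burn-image generator.  Real clinical burn photographs are not
# redistributable, so the package ships a generator that emulates the one
# property the classifier exploits: the three burn depths are colour- and
# texture-separable.  Superficial burns present red/pale-pink, deep dermal
# burns blotchy red/white, and full-thickness burns white/brown/deep-red with
# a dark centre, on a beige skin-tone background.

#' Synthetic dataset configuration
#'
#' @param nPerClass images generated per class.
#' @param imageSize height/width of generated images (square).
#' @param seed seed fixing the entire dataset bit-exactly.
#' @param noiseSD standard deviation of additive Gaussian pixel noise
#'   (8-bit units).
#' @param axesRange range of elliptical lesion semi-axes in pixels.
#' @param centerJitter maximal lesion-centre displacement in pixels.
#' @return a [SynthConfig-class].
#' @export
synthConfig <- function(nPerClass = 200L, imageSize = c(100L, 100L), seed = 42L,
                        noiseSD = 8, axesRange = c(26, 33), centerJitter = 10) {
  new("SynthConfig", nPerClass = as.integer(nPerClass),
      imageSize = as.integer(rep(imageSize, length.out = 2L)),
      seed = as.integer(seed), noiseSD = noiseSD,
      axesRange = as.numeric(axesRange), centerJitter = as.numeric(centerJitter))
}

#' Colour palette of a burn class
#'
#' RGB anchor colours and the texture used to paint the lesion of each class:
#' superficial burns mix red and pale pink uniformly; deep dermal burns are
#' blotchy patches of red and white; full-thickness burns grade from a dark
#' brown charred centre through deep red to a white rim.
#'
#' @param label one of `"superficial"`, `"deep_dermal"`, `"full_thickness"`.
#' @return list with `label`, `anchors` (named RGB vectors), `weights`
#'   (mixing weights summing to 1) and `texture`.
#' @export
classPalette <- function(label) {
  label <- match.arg(label, burnClasses())
  switch(label,
    superficial = list(
      label = label,
      anchors = list(red = c(215, 85, 80), pale_pink = c(240, 180, 170)),
      weights = c(0.5, 0.5), texture = "uniform"),
    deep_dermal = list(
      label = label,
      anchors = list(red = c(175, 40, 45), white = c(232, 228, 220)),
      weights = c(0.67, 0.33), texture = "blotchy"),
    full_thickness = list(
      label = label,
      anchors = list(white = c(228, 222, 212), brown = c(105, 62, 40),
                     deep_red = c(125, 22, 28)),
      weights = c(0.4, 0.3, 0.3), texture = "charred_center"))
}

# Coarse Gaussian field bilinearly upsampled to H x W; smooth blotch pattern.
.smoothField <- function(H, W, coarse, rng) {
  g <- matrix(rng$rnorm(coarse * coarse), coarse, coarse)
  arr <- array(0, c(coarse, coarse, 3L))
  for (ch in 1:3) arr[, , ch] <- g
  si <- (seq_len(H) - 0.5) * coarse / H + 0.5
  sj <- (seq_len(W) - 0.5) * coarse / W + 0.5
  grid <- expand.grid(i = si, j = sj)
  matrix(.bilinearSample(arr, grid$i, grid$j)[, 1L], H, W)
}

#' Generate one synthetic burn image
#'
#' Paints a beige skin background, an elliptical lesion filled from the class
#' palette with the class texture, and additive Gaussian pixel noise clipped
#' to 0..255.  Bit-exactly reproducible from the RNG state.
#'
#' @param label burn class.
#' @param config a [SynthConfig-class].
#' @param rng RNG stream from an internal seeded generator; `NULL` derives one
#'   from `seed`.
#' @param seed seed used when `rng` is `NULL`.
#' @param id record identifier.
#' @return list with `pixels` (H x W x 3 integer array), `label`, `source`
#'   (`"synthetic"`) and `id`.
#' @export
generateBurnImage <- function(label, config = synthConfig(), rng = NULL,
                              seed = config@seed, id = "syn") {
  label <- match.arg(label, burnClasses())
  if (is.null(rng)) rng <- .seededRNG(seed)
  H <- config@imageSize[1]; W <- config@imageSize[2]
  pal <- classPalette(label)

  # skin-tone background with per-image brightness jitter
  bgAnchor <- c(222, 188, 160) + rng$runif(1, -4, 4)
  img <- array(0, c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- bgAnchor[ch]

  # elliptical lesion geometry
  axes <- rng$runif(2, config@axesRange[1], config@axesRange[2])
  if (any(axes <= 0)) stop("generateBurnImage: degenerate ellipse axis")
  ci <- H / 2 + rng$runif(1, -config@centerJitter, config@centerJitter)
  cj <- W / 2 + rng$runif(1, -config@centerJitter, config@centerJitter)
  th <- rng$runif(1, 0, pi)
  ii <- matrix(seq_len(H), H, W)
  jj <- matrix(seq_len(W), H, W, byrow = TRUE)
  di <- ii - ci; dj <- jj - cj
  u <- (cos(th) * di + sin(th) * dj) / axes[1]
  v <- (-sin(th) * di + cos(th) * dj) / axes[2]
  rho <- sqrt(u * u + v * v)          # elliptical radius, 1 on the boundary
  inside <- rho <= 1

  fill <- matrix(0, sum(inside), 3L)
  A <- pal$anchors
  if (pal$texture == "uniform") {
    w <- rng$runif(1, 0.4, 0.6)
    field <- .smoothField(H, W, 6L, rng)[inside]
    w <- pmin(pmax(w + 0.1 * field, 0), 1)
    for (ch in 1:3) fill[, ch] <- w * A$red[ch] + (1 - w) * A$pale_pink[ch]
  } else if (pal$texture == "blotchy") {
    field <- .smoothField(H, W, 14L, rng)[inside]
    tau <- rng$runif(1, -0.5, -0.4)          # red-dominant blotch threshold
    w <- .sigmoid((field - tau) / 0.15)      # red blotches vs white ground
    for (ch in 1:3) fill[, ch] <- w * A$red[ch] + (1 - w) * A$white[ch]
  } else {                                    # charred_center
    r <- rho[inside]
    wB <- pmax(1 - r / 0.4, 0)                # brown charred core
    wR <- pmax(1 - abs(r - 0.5) / 0.3, 0)     # deep-red annulus
    wW <- pmax((r - 0.6) / 0.4, 0)            # whitening rim
    tot <- wB + wR + wW + 1e-9
    for (ch in 1:3)
      fill[, ch] <- (wB * A$brown[ch] + wR * A$deep_red[ch] + wW * A$white[ch]) / tot
  }
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[inside] <- fill[, ch]
    img[, , ch] <- plane
  }

  if (config@noiseSD > 0)
    img <- img + array(rng$rnorm(H * W * 3L, sd = config@noiseSD), c(H, W, 3L))
  pixels <- array(as.integer(pmin(pmax(round(img), 0), 255)), c(H, W, 3L))
  list(pixels = pixels, label = label, source = "synthetic", id = id)
}

#' Generate a labelled synthetic dataset
#'
#' `nPerClass` images per burn class, deterministically shuffled; the whole
#' set is a pure function of the configuration (seed included).
#'
#' @param config a [SynthConfig-class].
#' @return a [BurnImageSet-class] with a `manifest` of `id`, `label`, `source`.
#' @examples
#' ds <- generateDataset(synthConfig(nPerClass = 3, imageSize = c(32, 32)))
#' nImages(ds)
#' @export
generateDataset <- function(config = synthConfig()) {
  validObject(config)
  rng <- .seededRNG(config@seed)
  labels <- rep(burnClasses(), each = config@nPerClass)
  n <- length(labels)
  ord <- rng$sample(n)
  labels <- labels[ord]
  images <- vector("list", n)
  ids <- sprintf("syn_%05d", seq_len(n))
  for (i in seq_len(n))
    images[[i]] <- generateBurnImage(labels[i], config, rng = rng, id = ids[i])$pixels
  new("BurnImageSet", images = images,
      manifest = data.frame(id = ids, label = labels, source = "synthetic",
                            stringsAsFactors = FALSE))
}

#' Write a dataset to disk
#'
#' PNG per image under `dir/images/`, a `manifest.csv` (`id,path,label,split`)
#' and, when a configuration is given, a frozen YAML copy of it.
#'
#' @param set a [BurnImageSet-class].
#' @param dir output directory.
#' @param config optional [SynthConfig-class] to freeze alongside the data.
#' @return path of the manifest, invisibly.
#' @export
writeDataset <- function(set, dir, config = NULL) {
  imgDir <- file.path(dir, "images")
  dir.create(imgDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(imgDir)) stop("writeDataset: cannot create ", imgDir)
  man <- manifest(set)
  paths <- file.path("images", paste0(man$id, ".png"))
  for (i in seq_len(nImages(set)))
    writeImagePNG(set@images[[i]], file.path(dir, paths[i]))
  out <- data.frame(id = man$id, path = paths, label = man$label,
                    split = if ("split" %in% names(man)) man$split else "",
                    stringsAsFactors = FALSE)
  manifestPath <- file.path(dir, "manifest.csv")
  write.csv(out, manifestPath, row.names = FALSE)
  if (!is.null(config))
    yaml::write_yaml(list(
      n_per_class = config@nPerClass, image_size = config@imageSize,
      seed = config@seed, noise_sd = config@noiseSD,
      axes_range = config@axesRange, center_jitter = config@centerJitter),
      file.path(dir, "synth_config.yaml"))
  invisible(manifestPath)
}

#' Load a dataset from a manifest
#'
#' Reads the images referenced by a `manifest.csv` (columns `id`, `path`,
#' `label`, optional `split`), decodes PNG/JPEG, resizes every image to
#' `size`, and validates labels.  A corrupt row (missing file, unknown label,
#' non-RGB image) is reported by row and id via a warning and skipped; the
#' remaining rows load normally.  The per-row error report is attached as
#' attribute `"errors"`.
#'
#' @param manifestPath path to the manifest CSV.
#' @param size target image size `c(height, width)`.
#' @return a [BurnImageSet-class].
#' @export
loadDataset <- function(manifestPath, size = c(100L, 100L)) {
  if (!file.exists(manifestPath)) stop("manifest not found: ", manifestPath)
  man <- read.csv(manifestPath, stringsAsFactors = FALSE)
  base <- dirname(manifestPath)
  images <- list(); keep <- integer(); errs <- list()
  for (i in seq_len(nrow(man))) {
    res <- tryCatch({
      if (!man$label[i] %in% burnClasses())
        stop("unknown label '", man$label[i], "'")
      p <- man$path[i]
      if (!file.exists(p)) p <- file.path(base, man$path[i])
      if (!file.exists(p)) stop("missing file '", man$path[i], "'")
      resizeImage(readImageFile(p), size)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        row = i, id = as.character(man$id[i]), message = conditionMessage(res))
    } else {
      images[[length(images) + 1L]] <- res
      keep <- c(keep, i)
    }
  }
  if (length(errs)) {
    errDf <- do.call(rbind, errs)
    warning(sprintf("loadDataset: %d row(s) failed: %s", nrow(errDf),
                    paste(sprintf("row %d (%s): %s", errDf$row, errDf$id,
                                  errDf$message), collapse = "; ")))
  } else errDf <- NULL
  man <- man[keep, , drop = FALSE]
  man$source <- "file"
  set <- new("BurnImageSet", images = images, manifest = man)
  attr(set, "errors") <- errDf
  set
}
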