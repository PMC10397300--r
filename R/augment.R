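# Flip and rotation augmentation.  Flips and quarter-turn rotations are exact
# pixel permutations (they conserve the pixel-value histogram); +/-30 degree
# rotations use bilinear interpolation with reflect fill.

.augTransforms <- c("hflip", "vflip", "rot30", "rot-30", "rot90", "rot270")

#' Define an augmentation set
#'
#' The default four transforms are horizontal flip, vertical flip, and the two
#' 30-degree rotations (counter-clockwise and clockwise); the quarter-turn
#' rotations `rot90`/`rot270` are also available.
#'
#' @param transforms character vector of distinct transform names from
#'   `hflip`, `vflip`, `rot30`, `rot-30`, `rot90`, `rot270`.
#' @param includeOriginal prepend the untransformed image to the output.
#' @return a list with class `"augmentationSet"`.
#' @export
augmentationSet <- function(transforms = c("hflip", "vflip", "rot30", "rot-30"),
                            includeOriginal = TRUE) {
  bad <- setdiff(transforms, .augTransforms)
  if (length(bad))
    stop("unknown transform(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(transforms)) stop("transforms must be distinct")
  structure(list(transforms = transforms, includeOriginal = includeOriginal),
            class = "augmentationSet")
}

.applyTransform <- function(pixels, tf) {
  d <- dim(pixels)
  switch(tf,
    hflip = pixels[, d[2]:1, , drop = FALSE],
    vflip = pixels[d[1]:1, , , drop = FALSE],
    rot90 = aperm(pixels, c(2L, 1L, 3L))[d[2]:1, , , drop = FALSE],
    rot270 = aperm(pixels, c(2L, 1L, 3L))[, d[1]:1, , drop = FALSE],
    rot30 = .rotateBilinear(pixels, 30),
    `rot-30` = .rotateBilinear(pixels, -30),
    stop("unknown transform: ", tf))
}

#' Augment one image
#'
#' @param pixels H x W x 3 integer array.
#' @param aug an [augmentationSet()].
#' @return named list of pixel arrays: the original (if requested) followed by
#'   one entry per transform.
#' @export
augmentImage <- function(pixels, aug = augmentationSet()) {
  if (length(dim(pixels)) != 3L) stop("augmentImage: pixels must be H x W x 3")
  out <- list()
  if (aug$includeOriginal) out$original <- pixels
  for (tf in aug$transforms) out[[tf]] <- .applyTransform(pixels, tf)
  out
}

#' Augment a whole image set
#'
#' @param set a [BurnImageSet-class].
#' @param aug an [augmentationSet()].
#' @return expanded [BurnImageSet-class]; ids gain a transform suffix.
#' @export
augmentDataset <- function(set, aug = augmentationSet()) {
  images <- list(); rows <- list()
  man <- manifest(set)
  for (i in seq_len(nImages(set))) {
    pieces <- augmentImage(set@images[[i]], aug)
    for (nm in names(pieces)) {
      images[[length(images) + 1L]] <- pieces[[nm]]
      r <- man[i, , drop = FALSE]
      r$id <- paste0(r$id, "_", nm)
      rows[[length(rows) + 1L]] <- r
    }
  }
  newMan <- do.call(rbind, rows)
  row.names(newMan) <- NULL
  new("BurnImageSet", images = images, manifest = newMan)
}

#' Oversample a set with randomised augmentation
#'
#' Expands a dataset to an arbitrary target count by repeatedly applying a
#' random flip and/or a random rotation between -30 and 30 degrees to drawn
#' source images.  Useful when the fixed transform set cannot reach the
#' desired count.
#'
#' @param set a [BurnImageSet-class].
#' @param targetCount desired total number of images (>= `nImages(set)`).
#' @param seed RNG seed.
#' @return expanded [BurnImageSet-class].
#' @export
oversampleDataset <- function(set, targetCount, seed = 1L) {
  n <- nImages(set)
  if (targetCount < n) stop("targetCount must be >= current size")
  rng <- .seededRNG(.deriveSeed(seed, "oversample"))
  images <- set@images
  man <- manifest(set)
  rows <- list(man)
  for (j in seq_len(targetCount - n)) {
    i <- rng$sample(n, 1L)
    px <- set@images[[i]]
    if (rng$runif(1) < 0.5)
      px <- .applyTransform(px, if (rng$runif(1) < 0.5) "hflip" else "vflip")
    px <- .rotateBilinear(px, rng$runif(1, -30, 30))
    images[[n + j]] <- px
    r <- man[i, , drop = FALSE]
    r$id <- sprintf("%s_aug%04d", r$id, j)
    rows[[length(rows) + 1L]] <- r
  }
  newMan <- do.call(rbind, rows)
  row.names(newMan) <- NULL
  new("BurnImageSet", images = images, manifest = newMan)
}
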