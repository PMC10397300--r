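# Image reading/writing and bilinear resampling.
# Pixel arrays are H x W x 3 integers in 0..255 throughout the package.

# Reflect a continuous coordinate into [1, n] (mirror at both borders).
.reflectIdx <- function(x, n) {
  if (n == 1L) return(rep(1, length(x)))
  p <- 2 * (n - 1)
  abs(((x - 1) %% p + p) %% p - (n - 1)) + 1
}

# Bilinear sample of an H x W x 3 array at fractional coordinates (si, sj),
# with reflect indexing outside the grid.  si/sj are equal-length vectors; the
# result is length(si) x 3.
.bilinearSample <- function(img, si, sj) {
  H <- dim(img)[1]; W <- dim(img)[2]
  si <- .reflectIdx(si, H); sj <- .reflectIdx(sj, W)
  i0 <- pmin(pmax(floor(si), 1), H); i1 <- pmin(i0 + 1, H)
  j0 <- pmin(pmax(floor(sj), 1), W); j1 <- pmin(j0 + 1, W)
  fi <- si - i0; fj <- sj - j0
  out <- matrix(0, length(si), 3L)
  for (ch in 1:3) {
    m <- img[, , ch]
    out[, ch] <- (1 - fi) * (1 - fj) * m[cbind(i0, j0)] +
      fi * (1 - fj) * m[cbind(i1, j0)] +
      (1 - fi) * fj * m[cbind(i0, j1)] +
      fi * fj * m[cbind(i1, j1)]
  }
  out
}

#' Resize an image with bilinear interpolation
#'
#' @param pixels H x W x 3 integer array (0..255).
#' @param size target `c(height, width)`.
#' @return resized integer array.
#' @export
resizeImage <- function(pixels, size = c(100L, 100L)) {
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  Ho <- size[1]; Wo <- size[2]
  if (H == Ho && W == Wo) return(pixels)
  si <- (seq_len(Ho) - 0.5) * H / Ho + 0.5
  sj <- (seq_len(Wo) - 0.5) * W / Wo + 0.5
  grid <- expand.grid(i = si, j = sj)
  v <- .bilinearSample(pixels, grid$i, grid$j)
  out <- array(0L, c(Ho, Wo, 3L))
  for (ch in 1:3) out[, , ch] <- as.integer(pmin(pmax(round(v[, ch]), 0), 255))
  out
}

# Rotate an image counter-clockwise by `angle` degrees about its centre,
# bilinear interpolation with reflect-padding fill (no black corners that
# would leak label-independent cues into augmented sets).
.rotateBilinear <- function(pixels, angle) {
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  th <- angle * pi / 180
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  grid <- expand.grid(i = seq_len(H), j = seq_len(W))
  di <- grid$i - ci; dj <- grid$j - cj
  # inverse rotation of the output grid back onto the source
  si <- ci + cos(th) * di - sin(th) * dj
  sj <- cj + sin(th) * di + cos(th) * dj
  v <- .bilinearSample(pixels, si, sj)
  out <- array(0L, c(H, W, 3L))
  for (ch in 1:3) out[, , ch] <- as.integer(pmin(pmax(round(v[, ch]), 0), 255))
  out
}

#' Read an RGB image file
#'
#' PNG and JPEG are supported.  Alpha channels are dropped; grayscale images
#' are rejected (the burn palettes are colour-defined).
#'
#' @param path file path ending in .png, .jpg or .jpeg.
#' @return H x W x 3 integer array in 0..255.
#' @export
readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("non-RGB image: ", path)
  img <- img[, , 1:3, drop = FALSE]
  array(as.integer(pmin(pmax(round(img * 255), 0), 255)), dim(img))
}

#' Write an image as PNG
#'
#' @param pixels H x W x 3 integer array (0..255).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeImagePNG <- function(pixels, path) {
  png::writePNG(pixels / 255, path)
  invisible(path)
}
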