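#' Images as numeric grids
#'
#' Throughout the package an image is a plain numeric `H x W` matrix
#' (grayscale) or `H x W x 3` array (RGB) with intensities in `[0, 1]`.
#' Pixel coordinates are `(row, col)`, 1-based, origin at the top-left
#' corner; this single convention is used by every function in the package.
#' 8-bit files are converted to float on read by dividing by 255 and back on
#' write, so no operation ever sees quantized integers.
#'
#' @param x object to validate or coerce.
#' @param allow_rgb should 3-channel arrays be accepted?
#' @return `as_image()` returns the validated numeric matrix or array.
#' @examples
#' img <- as_image(matrix(runif(64), 8, 8))
#' @export
as_image <- function(x, allow_rgb = TRUE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.numeric(x)) abort("an image must be numeric")
  if (is.matrix(x)) {
    if (nrow(x) < 1 || ncol(x) < 1) abort("image must have H >= 1, W >= 1")
  } else if (is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 3) {
    if (!allow_rgb) abort("this operation accepts single-channel images; convert with to_gray() first")
  } else {
    abort("an image must be an H x W matrix or an H x W x 3 array")
  }
  if (!all(is.finite(x))) abort("image contains non-finite values")
  x
}

#' @rdname as_image
#' @export
is_rgb <- function(x) is.array(x) && !is.matrix(x) && length(dim(x)) == 3 && dim(x)[3] == 3

#' @rdname as_image
#' @export
to_gray <- function(x) {
  x <- as_image(x)
  if (!is_rgb(x)) return(x)
  (x[, , 1] + x[, , 2] + x[, , 3]) / 3
}

#' Read and write images
#'
#' Thin wrappers over \pkg{png} and \pkg{tiff}. PNG files are 8-bit and are
#' rescaled to float `[0, 1]` on read; TIFF files are written as float32 and
#' read back unscaled. Format is chosen from the file extension.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param image numeric matrix or `H x W x 3` array in `[0, 1]`.
#' @return `read_image()` returns a numeric matrix or array; `write_image()`
#'   returns `path` invisibly.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported image extension: .", ext))
  )
  if (is.array(img) && !is.matrix(img) && dim(img)[3] == 4) img <- img[, , 1:3]  # drop alpha
  if (is.array(img) && !is.matrix(img) && dim(img)[3] == 1) img <- img[, , 1]
  as_image(img)
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  image <- as_image(image)
  ext <- tolower(tools::file_ext(path))
  clipped <- pmin(pmax(image, 0), 1)
  switch(ext,
    png = png::writePNG(clipped, target = path),
    tif = ,
    tiff = tiff::writeTIFF(clipped, where = path, bits.per.sample = 32, reduce = FALSE),
    abort(paste0("unsupported image extension: .", ext))
  )
  invisible(path)
}

# Replicate-pad a matrix by the given margins (clamped-index border policy).
pad_replicate <- function(m, top, bottom, left, right) {
  ri <- c(rep(1L, top), seq_len(nrow(m)), rep(nrow(m), bottom))
  ci <- c(rep(1L, left), seq_len(ncol(m)), rep(ncol(m), right))
  m[ri, ci, drop = FALSE]
}

# Valid-mode cross-correlation (no kernel flip) by shift-and-add; exact, no FFT.
correlate_valid <- function(m, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  oh <- nrow(m) - kh + 1L; ow <- ncol(m) - kw + 1L
  if (oh < 1 || ow < 1) abort("image smaller than the kernel")
  out <- matrix(0, oh, ow)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (kern[i, j] != 0) {
        out <- out + kern[i, j] * m[i:(i + oh - 1L), j:(j + ow - 1L)]
      }
    }
  }
  out
}

# Full-size correlation under the replicate (clamped-index) border policy.
# pad_* give the margins added before the valid-mode pass; for a centred
# (2r+1) kernel all four margins are r.
correlate_replicate <- function(m, kern, top, bottom, left, right) {
  correlate_valid(pad_replicate(m, top, bottom, left, right), kern)
}
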