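#' Gaussian-windowed corner response
#'
#' At each pixel the 2 x 2 structure tensor
#' `M = sum_w w(x, y) [[Ix^2, Ix Iy], [Ix Iy, Iy^2]]`
#' is accumulated under a two-dimensional Gaussian window `w`, and the corner
#' response is `R = det(M) - k * trace(M)^2`. `R` is large and positive at
#' corners (two strong eigenvalues), negative along edge interiors (one
#' dominant eigenvalue, so `det(M)` is near zero while `trace(M)` is large),
#' and near zero in flat regions. The derivatives `Ix`, `Iy` are computed
#' with the Sobel templates; border pixels use the replicate (clamped-index)
#' policy throughout.
#'
#' The sensitivity constant `k` is conventionally taken in `[0.04, 0.2]`; a
#' value outside that interval is accepted with a warning. At a fixed pixel
#' `R` is strictly decreasing in `k` whenever `trace(M)^2 > 0`.
#'
#' @param image single-channel numeric matrix.
#' @param k sensitivity constant, default `0.04`.
#' @param window_sigma standard deviation (pixels) of the Gaussian window;
#'   the discrete window has radius `ceiling(3 * window_sigma)`.
#' @return `H x W` matrix of response values `R`.
#' @examples
#' img <- matrix(0, 32, 32); img[8:24, 8:24] <- 1
#' r <- corner_response(img)
#' which(r == max(r), arr.ind = TRUE)[1, ]  # near a square vertex
#' @export
corner_response <- function(image, k = 0.04, window_sigma = 1.0) {
  image <- as_image(image, allow_rgb = FALSE)
  if (!is.numeric(window_sigma) || window_sigma <= 0) abort("window_sigma must be > 0")
  if (k < 0.04 || k > 0.2) {
    warn(paste0("k = ", k, " is outside the conventional interval [0.04, 0.2]"))
  }
  g <- apply_edge_operator(image, "sobel")
  w <- gaussian_window(window_sigma)
  r <- attr(w, "radius")
  sm <- function(m) correlate_replicate(m, w, r, r, r, r)
  A <- sm(g$gx^2)
  B <- sm(g$gy^2)
  C <- sm(g$gx * g$gy)
  A * B - C^2 - k * (A + B)^2
}

# Normalized discrete Gaussian window of radius ceiling(3*sigma).
gaussian_window <- function(sigma) {
  r <- as.integer(ceiling(3 * sigma))
  u <- (-r):r
  g1 <- exp(-u^2 / (2 * sigma^2))
  w <- outer(g1, g1)
  w <- w / sum(w)
  attr(w, "radius") <- r
  w
}

#' Select corners from a response grid
#'
#' Greedy thresholding with non-maximum suppression: candidate pixels with
#' response at or above `threshold` are visited in order of descending
#' response (ties broken by `(row, col)` lexicographic order) and a candidate
#' is retained only if no already-retained corner lies within `nms_radius`
#' in Chebyshev (chessboard) distance. An empty result is valid.
#'
#' @param response `H x W` numeric matrix of corner response values.
#' @param threshold minimum retained response (absolute units of `R`).
#' @param nms_radius suppression radius in pixels, `>= 1`.
#' @return a `corner_set`: a tibble with columns `row`, `col`, `response`,
#'   carrying the selection parameters as attributes.
#' @export
detect_corners <- function(response, threshold, nms_radius = 3L) {
  stopifnot(is.matrix(response), is.numeric(response))
  if (nms_radius < 1) abort("nms_radius must be >= 1")
  idx <- which(response >= threshold)
  if (length(idx) == 0) {
    return(new_corner_set(tibble(row = integer(), col = integer(), response = double()),
                          threshold, nms_radius))
  }
  rows <- ((idx - 1L) %% nrow(response)) + 1L
  cols <- ((idx - 1L) %/% nrow(response)) + 1L
  vals <- response[idx]
  ord <- order(-vals, rows, cols)
  rows <- rows[ord]; cols <- cols[ord]; vals <- vals[ord]
  keep_r <- integer(0); keep_c <- integer(0); keep_v <- double(0)
  for (i in seq_along(rows)) {
    if (length(keep_r) == 0 ||
        all(pmax(abs(keep_r - rows[i]), abs(keep_c - cols[i])) > nms_radius)) {
      keep_r <- c(keep_r, rows[i]); keep_c <- c(keep_c, cols[i]); keep_v <- c(keep_v, vals[i])
    }
  }
  new_corner_set(tibble(row = keep_r, col = keep_c, response = keep_v),
                 threshold, nms_radius)
}

new_corner_set <- function(tbl, threshold, nms_radius, k = NA_real_, window_sigma = NA_real_) {
  structure(tbl,
            class = c("corner_set", class(tbl)),
            threshold = threshold, nms_radius = nms_radius,
            k = k, window_sigma = window_sigma)
}

#' Detect corners in an image in one call
#'
#' Convenience wrapper: [corner_response()] followed by [detect_corners()].
#' `threshold_rel` sets the absolute threshold as a fraction of the maximum
#' response, which adapts across images of different contrast.
#'
#' @inheritParams corner_response
#' @inheritParams detect_corners
#' @param threshold_rel threshold as a fraction of `max(response)`; ignored
#'   when `threshold` is given. The default 0.02 keeps corners of
#'   low-contrast structures: the response scales like the fourth power of
#'   local contrast, so a feature at ~40% of the strongest contrast still
#'   clears the cut, while flat regions (response near zero) and edges
#'   (negative response) never do.
#' @param threshold absolute response threshold (optional).
#' @return a `corner_set` tibble.
#' @export
find_corners <- function(image, k = 0.04, window_sigma = 1.0,
                         threshold = NULL, threshold_rel = 0.02, nms_radius = 3L) {
  r <- corner_response(image, k = k, window_sigma = window_sigma)
  if (is.null(threshold)) {
    mx <- max(r)
    threshold <- if (mx > 0) threshold_rel * mx else Inf
  }
  out <- detect_corners(r, threshold = threshold, nms_radius = nms_radius)
  attr(out, "k") <- k
  attr(out, "window_sigma") <- window_sigma
  out
}

#' Normalized cross-correlation of two patches
#'
#' `NCC = sum((I1 - u1) (I2 - u2)) / sqrt(sum((I1 - u1)^2) sum((I2 - u2)^2))`
#' where `u1`, `u2` are the patch means. The score lies in `[-1, 1]`, is
#' symmetric in its arguments, and is invariant to affine intensity changes
#' `a * I + b` (`a > 0`) of either patch. A zero-variance patch makes the
#' score undefined; `NA` is returned.
#'
#' @param p1,p2 numeric matrices of equal dimensions.
#' @return scalar in `[-1, 1]`, or `NA` for a zero-variance patch.
#' @export
ncc <- function(p1, p2) {
  stopifnot(all(dim(p1) == dim(p2)))
  d1 <- p1 - mean(p1)
  d2 <- p2 - mean(p2)
  denom <- sqrt(sum(d1^2) * sum(d2^2))
  if (denom == 0) return(NA_real_)
  v <- sum(d1 * d2) / denom
  max(-1, min(1, v))
}

extract_patch <- function(image, row, col, radius) {
  image[(row - radius):(row + radius), (col - radius):(col + radius), drop = FALSE]
}

in_patch_bounds <- function(image, row, col, radius) {
  row - radius >= 1 && col - radius >= 1 &&
    row + radius <= nrow(image) && col + radius <= ncol(image)
}

#' Match corners between two images by normalized cross-correlation
#'
#' Every corner of `corners_a` is scored by [ncc()] against every corner of
#' `corners_b` over square patches of half-width `patch_radius`. A pair is
#' accepted only if it is each endpoint's best-scoring partner (mutual best),
#' making the matching one-to-one, and its score is at least `min_ncc`.
#' Corners whose patch would leave the image are skipped; zero-variance
#' patches are skipped pairwise (their NCC is undefined).
#'
#' @param image_a,image_b single-channel numeric matrices.
#' @param corners_a,corners_b `corner_set` tibbles (or any data frame with
#'   `row` and `col` columns).
#' @param patch_radius half-width of the square comparison patch (pixels).
#' @param min_ncc minimum accepted score, default `0.8`.
#' @return a `match_set`: a tibble with columns `row_a`, `col_a`, `row_b`,
#'   `col_b`, `ncc`, sorted by descending score.
#' @export
ncc_match <- function(image_a, image_b, corners_a, corners_b,
                      patch_radius = 4L, min_ncc = 0.8) {
  image_a <- as_image(image_a, allow_rgb = FALSE)
  image_b <- as_image(image_b, allow_rgb = FALSE)
  ca <- as_tibble(corners_a)[, c("row", "col")]
  cb <- as_tibble(corners_b)[, c("row", "col")]
  ok_a <- vapply(seq_len(nrow(ca)), function(i)
    in_patch_bounds(image_a, ca$row[i], ca$col[i], patch_radius), logical(1))
  ok_b <- vapply(seq_len(nrow(cb)), function(i)
    in_patch_bounds(image_b, cb$row[i], cb$col[i], patch_radius), logical(1))
  if (any(!ok_a) || any(!ok_b)) {
    message(sum(!ok_a) + sum(!ok_b), " corner(s) too close to the border skipped")
  }
  ca <- ca[ok_a, , drop = FALSE]
  cb <- cb[ok_b, , drop = FALSE]
  na <- nrow(ca); nb <- nrow(cb)
  empty <- tibble(row_a = integer(), col_a = integer(),
                  row_b = integer(), col_b = integer(), ncc = double())
  if (na == 0 || nb == 0) return(new_match_set(empty, patch_radius, min_ncc))
  pa <- lapply(seq_len(na), function(i) extract_patch(image_a, ca$row[i], ca$col[i], patch_radius))
  pb <- lapply(seq_len(nb), function(j) extract_patch(image_b, cb$row[j], cb$col[j], patch_radius))
  scores <- matrix(NA_real_, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) scores[i, j] <- ncc(pa[[i]], pb[[j]])
  scores[is.na(scores)] <- -Inf
  best_for_a <- apply(scores, 1, which.max)
  best_for_b <- apply(scores, 2, which.max)
  pairs <- empty
  for (i in seq_len(na)) {
    j <- best_for_a[i]
    s <- scores[i, j]
    if (is.finite(s) && s >= min_ncc && best_for_b[j] == i) {
      pairs <- bind_rows(pairs, tibble(
        row_a = ca$row[i], col_a = ca$col[i],
        row_b = cb$row[j], col_b = cb$col[j], ncc = s))
    }
  }
  pairs <- arrange(pairs, desc(.data$ncc), .data$row_a, .data$col_a)
  new_match_set(pairs, patch_radius, min_ncc)
}

new_match_set <- function(tbl, patch_radius, min_ncc) {
  structure(tbl, class = c("match_set", class(tbl)),
            patch_radius = patch_radius, min_ncc = min_ncc)
}
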