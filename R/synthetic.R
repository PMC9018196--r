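#' Synthetic corner scenes with planted ground truth
#'
#' Generates a grayscale image of axis-aligned bright rectangles on a dark
#' background. The ground truth is geometric, never the output of any
#' detector: the four vertex pixels of every rectangle form `corner_truth`,
#' and the rectangle outlines form the `edge_mask`. With `noise_sigma = 0`
#' the image is piecewise constant away from the planted edges. All
#' randomness is governed by `seed`; identical arguments give bit-identical
#' scenes, and the caller's RNG state is untouched.
#'
#' @param n_shapes number of rectangles; each contributes 4 ground-truth
#'   corners.
#' @param size `(H, W)` image size, both at least 32.
#' @param noise_sigma standard deviation of additive Gaussian noise in
#'   intensity units (the image is clipped back to `[0, 1]`).
#' @param seed integer seed.
#' @param side_range closed range of rectangle side lengths (pixels).
#' @param margin minimum clearance (pixels) between rectangles and from the
#'   image border.
#' @return a `synthetic_scene`: list with `image`, `corner_truth` (tibble of
#'   `row`, `col`, `shape`), `edge_mask` (logical `H x W`), `noise_sigma`,
#'   `seed`.
#' @examples
#' sc <- make_corner_scene(2, c(64, 64), noise_sigma = 0, seed = 7)
#' nrow(sc$corner_truth)  # 8
#' @export
make_corner_scene <- function(n_shapes, size = c(64L, 64L), noise_sigma = 0,
                              seed = 0L, side_range = c(10L, 18L), margin = 6L) {
  if (n_shapes < 1) abort("n_shapes must be >= 1")
  if (length(size) != 2 || any(size < 32)) abort("size must be (H, W) with both >= 32")
  H <- as.integer(size[1]); W <- as.integer(size[2])
  withr::with_seed(as.integer(seed), {
    rects <- place_rectangles(n_shapes, H, W, side_range, margin)
    bg <- 0.1
    image <- matrix(bg, H, W)
    edge_mask <- matrix(FALSE, H, W)
    fg <- runif(n_shapes, 0.55, 0.95)
    for (i in seq_len(n_shapes)) {
      r <- rects[i, ]
      image[r$r0:r$r1, r$c0:r$c1] <- fg[i]
      edge_mask[c(r$r0, r$r1), r$c0:r$c1] <- TRUE
      edge_mask[r$r0:r$r1, c(r$c0, r$c1)] <- TRUE
    }
    corner_truth <- bind_rows(lapply(seq_len(n_shapes), function(i) {
      r <- rects[i, ]
      tibble(row = c(r$r0, r$r0, r$r1, r$r1),
             col = c(r$c0, r$c1, r$c0, r$c1),
             shape = i)
    }))
    if (noise_sigma > 0) {
      image <- image + matrix(rnorm(H * W, sd = noise_sigma), H, W)
      image <- pmin(pmax(image, 0), 1)
    }
    structure(
      list(image = image, corner_truth = corner_truth, edge_mask = edge_mask,
           noise_sigma = noise_sigma, seed = as.integer(seed)),
      class = "synthetic_scene"
    )
  })
}

# Rejection-sample non-overlapping axis-aligned rectangles with a clearance
# margin; errors if the canvas cannot host them.
place_rectangles <- function(n, H, W, side_range, margin) {
  placed <- tibble(r0 = integer(), r1 = integer(), c0 = integer(), c1 = integer())
  max_attempts <- 400L * n
  attempts <- 0L
  while (nrow(placed) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(paste0("could not place ", n, " rectangles in a ", H, " x ", W,
                   " image without overlap"))
    }
    h <- sample(side_range[1]:side_range[2], 1)
    w <- sample(side_range[1]:side_range[2], 1)
    if (H - margin - h < margin + 1 || W - margin - w < margin + 1) next
    r0 <- sample((margin + 1):(H - margin - h), 1)
    c0 <- sample((margin + 1):(W - margin - w), 1)
    cand <- tibble(r0 = r0, r1 = r0 + h - 1L, c0 = c0, c1 = c0 + w - 1L)
    clash <- nrow(placed) > 0 && any(
      placed$r0 - margin <= cand$r1 & placed$r1 + margin >= cand$r0 &
      placed$c0 - margin <= cand$c1 & placed$c1 + margin >= cand$c0
    )
    if (!clash) placed <- bind_rows(placed, cand)
  }
  placed
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene> ", nrow(x$image), "x", ncol(x$image),
      " corners=", nrow(x$corner_truth),
      " sigma=", x$noise_sigma, " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Synthetic correspondences under a planted per-channel colour model
#'
#' Samples paired colour observations related by the diagonal linear model
#' `b_c = gain_c * a_c + offset_c` per channel `c`. A planted fraction of
#' pairs is replaced by uniform-random target values, independent per
#' channel — maximally uninformative contamination for robust-recovery
#' tests. Source intensities are drawn from the subinterval of `[0, 1]` that
#' keeps every transformed value inside `[0, 1]`, so the model holds exactly
#' before noise; Gaussian noise of standard deviation `noise_sigma` is then
#' added to the inlier targets (unclipped).
#'
#' A rendered image pair (`image_a`, `image_b`) carrying the sampled values
#' at random distinct pixel positions is included for I/O round-trips; the
#' `points` table is the authoritative data.
#'
#' @param n_points number of pairs, at least 10.
#' @param gain,offset numeric vectors of per-channel gain and offset
#'   (length 3 for RGB or 1 for grayscale); every gain must be positive.
#' @param outlier_fraction fraction in `[0, 0.5)` of pairs replaced by
#'   uniform noise; the planted count is `round(outlier_fraction * n_points)`.
#' @param noise_sigma additive Gaussian noise on inlier targets.
#' @param seed integer seed.
#' @return a `correspondence_scene`: list with `points` (tibble of `row`,
#'   `col`, `a` and `b` channel columns, `outlier` flag), matrices `a` and
#'   `b` (`n x C`), `true_gain`, `true_offset`, `outlier_fraction`,
#'   `outlier_indices`, `image_a`, `image_b`, `seed`.
#' @export
make_correspondence_scene <- function(n_points, gain = c(1, 1, 1), offset = c(0, 0, 0),
                                      outlier_fraction = 0, noise_sigma = 0, seed = 0L) {
  if (n_points < 10) abort("n_points must be >= 10")
  if (outlier_fraction < 0 || outlier_fraction >= 0.5) {
    abort("outlier_fraction must lie in [0, 0.5)")
  }
  if (length(gain) != length(offset)) abort("gain and offset must have equal length")
  if (any(gain == 0)) abort("zero gain component: colour model degenerate, not recoverable")
  if (any(gain < 0)) abort("gain components must be positive")
  C <- length(gain)
  withr::with_seed(as.integer(seed), {
    # per-channel source range keeping gain*a+offset inside [0,1]
    lo <- pmax(0, (0 - offset) / gain) + 0.01
    hi <- pmin(1, (1 - offset) / gain) - 0.01
    if (any(hi <= lo)) abort("gain/offset leave no admissible source intensity range")
    a <- sapply(seq_len(C), function(c) runif(n_points, lo[c], hi[c]))
    a <- matrix(a, n_points, C)
    b <- sweep(sweep(a, 2, gain, `*`), 2, offset, `+`)
    n_out <- round(outlier_fraction * n_points)
    outlier_indices <- if (n_out > 0) sort(sample.int(n_points, n_out)) else integer(0)
    if (n_out > 0) b[outlier_indices, ] <- matrix(runif(n_out * C), n_out, C)
    if (noise_sigma > 0) {
      inl <- setdiff(seq_len(n_points), outlier_indices)
      b[inl, ] <- b[inl, ] + matrix(rnorm(length(inl) * C, sd = noise_sigma), length(inl), C)
    }
    side <- as.integer(ceiling(sqrt(n_points)) + 2L)
    pos_idx <- sample.int(side * side, n_points)
    rows <- ((pos_idx - 1L) %% side) + 1L
    cols <- ((pos_idx - 1L) %/% side) + 1L
    blank <- function() if (C == 1) matrix(0.5, side, side) else array(0.5, c(side, side, 3))
    image_a <- blank(); image_b <- blank()
    for (c in seq_len(C)) {
      for (i in seq_len(n_points)) {
        if (C == 1) {
          image_a[rows[i], cols[i]] <- a[i, 1]
          image_b[rows[i], cols[i]] <- min(max(b[i, 1], 0), 1)
        } else {
          image_a[rows[i], cols[i], c] <- a[i, c]
          image_b[rows[i], cols[i], c] <- min(max(b[i, c], 0), 1)
        }
      }
    }
    ch <- if (C == 3) c("r", "g", "b") else "v"
    pts <- tibble(row = rows, col = cols)
    for (c in seq_len(C)) pts[[paste0("a_", ch[c])]] <- a[, c]
    for (c in seq_len(C)) pts[[paste0("b_", ch[c])]] <- b[, c]
    pts$outlier <- seq_len(n_points) %in% outlier_indices
    structure(
      list(points = pts, a = a, b = b,
           true_gain = gain, true_offset = offset,
           outlier_fraction = outlier_fraction, outlier_indices = outlier_indices,
           image_a = image_a, image_b = image_b, seed = as.integer(seed)),
      class = "correspondence_scene"
    )
  })
}

#' @export
print.correspondence_scene <- function(x, ...) {
  cat("<correspondence_scene> n=", nrow(x$a),
      " channels=", ncol(x$a),
      " outliers=", length(x$outlier_indices),
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Embed a template into an image at a known offset
#'
#' Replaces the region of `image` whose top-left pixel is `at = (row, col)`
#' with `template`, verbatim. Together with [ssd_scan()] this plants a
#' localization ground truth: the global SSD minimum of the returned image
#' against `template` is `at` with value 0 (in the noise-free case).
#'
#' @param image numeric matrix.
#' @param template numeric matrix no larger than `image`.
#' @param at `(row, col)` of the template's top-left pixel, 1-based.
#' @return the modified image.
#' @export
embed_template <- function(image, template, at) {
  image <- as_image(image, allow_rgb = FALSE)
  template <- as_image(template, allow_rgb = FALSE)
  r0 <- as.integer(at[1]); c0 <- as.integer(at[2])
  r1 <- r0 + nrow(template) - 1L; c1 <- c0 + ncol(template) - 1L
  if (r0 < 1 || c0 < 1 || r1 > nrow(image) || c1 > ncol(image)) {
    abort("template placement out of image bounds")
  }
  image[r0:r1, c0:c1] <- template
  image
}
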