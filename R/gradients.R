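#' Per-pixel image gradients
#'
#' `finite_difference_gradient()` computes the forward-difference
#' approximation `Gx(i, j) = f(i, j + 1) - f(i, j)` and
#' `Gy(i, j) = f(i + 1, j) - f(i, j)`, with the image replicate-padded on the
#' last row and column so the output keeps the input shape (the padded
#' differences there are 0). The magnitude is the Euclidean norm
#' `sqrt(Gx^2 + Gy^2)` and the angle is `atan2(Gy, Gx)` in `(-pi, pi]`.
#'
#' `gradient_magnitude_abs()` returns the cheaper `|Gx| + |Gy|`
#' approximation, which bounds the Euclidean magnitude from above.
#'
#' @param image single-channel numeric matrix, at least 2 x 2.
#' @param field a `gradient_field` object.
#' @return `finite_difference_gradient()` returns a `gradient_field`: a list
#'   with `gx`, `gy`, `magnitude`, `angle` (all `H x W`), a logical
#'   `valid_mask` marking pixels whose stencil lay fully inside the image,
#'   and the operator name. `gradient_magnitude_abs()` returns an `H x W`
#'   matrix.
#' @examples
#' g <- finite_difference_gradient(matrix(c(0, 2, 1, 3), 2, 2, byrow = TRUE))
#' g$gx[1, 1]  # 2
#' @export
finite_difference_gradient <- function(image) {
  image <- as_image(image, allow_rgb = FALSE)
  if (nrow(image) < 2 || ncol(image) < 2) abort("image must be at least 2 x 2")
  padded <- pad_replicate(image, 0, 1, 0, 1)
  H <- nrow(image); W <- ncol(image)
  gx <- padded[1:H, 2:(W + 1)] - image
  gy <- padded[2:(H + 1), 1:W] - image
  valid <- matrix(TRUE, H, W)
  valid[H, ] <- FALSE
  valid[, W] <- FALSE
  new_gradient_field(gx, gy, valid, "forward_difference")
}

#' @rdname finite_difference_gradient
#' @export
gradient_magnitude_abs <- function(field) {
  stopifnot(inherits(field, "gradient_field"))
  abs(field$gx) + abs(field$gy)
}

new_gradient_field <- function(gx, gy, valid_mask, operator) {
  structure(
    list(
      gx = gx, gy = gy,
      magnitude = sqrt(gx^2 + gy^2),
      angle = atan2(gy, gx),
      valid_mask = valid_mask,
      operator = operator
    ),
    class = "gradient_field"
  )
}

#' @export
print.gradient_field <- function(x, ...) {
  cat("<gradient_field> ", nrow(x$gx), "x", ncol(x$gx),
      " operator=", x$operator,
      " max|G|=", format(max(x$magnitude), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Directional edge-operator templates
#'
#' The three classical first-derivative templates, applied as correlation
#' (no kernel flip) so the printed orientation of each template is exactly
#' what slides over the image:
#' \describe{
#'   \item{Roberts}{`Gx = [[1, 0], [0, -1]]`, `Gy = [[0, 1], [-1, 0]]` (2 x 2,
#'     anchored at the top-left pixel of its support);}
#'   \item{Sobel}{`Gx = [[-1, 0, 1], [-2, 0, 2], [-1, 0, 1]]`,
#'     `Gy = [[1, 2, 1], [0, 0, 0], [-1, -2, -1]]`;}
#'   \item{Prewitt}{`Gx = [[-1, 0, 1], [-1, 0, 1], [-1, 0, 1]]`,
#'     `Gy = [[1, 1, 1], [0, 0, 0], [-1, -1, -1]]`.}
#' }
#' Outputs keep the input shape through replicate padding; `valid_mask` marks
#' pixels whose template support lay fully inside the image.
#'
#' @param image single-channel numeric matrix at least as large as the
#'   template.
#' @param op `"roberts"`, `"sobel"` or `"prewitt"`.
#' @return a `gradient_field` (see [finite_difference_gradient()]).
#' @examples
#' step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
#' f <- apply_edge_operator(step, "sobel")
#' max(abs(f$gx))  # 4 at the step
#' @export
apply_edge_operator <- function(image, op = c("roberts", "sobel", "prewitt")) {
  image <- as_image(image, allow_rgb = FALSE)
  if (!is.character(op) || !op[1] %in% c("roberts", "sobel", "prewitt")) {
    abort(paste0("unknown edge operator '", op[1],
                 "'; valid operators: roberts, sobel, prewitt"))
  }
  op <- op[1]
  k <- edge_templates(op)
  H <- nrow(image); W <- ncol(image)
  if (H < nrow(k$gx) || W < ncol(k$gx)) abort("image smaller than the operator template")
  if (op == "roberts") {
    # 2x2 support anchored top-left: clamp only the far row/column
    gx <- correlate_replicate(image, k$gx, 0, 1, 0, 1)
    gy <- correlate_replicate(image, k$gy, 0, 1, 0, 1)
    valid <- matrix(TRUE, H, W); valid[H, ] <- FALSE; valid[, W] <- FALSE
  } else {
    # separable smooth-then-difference: the final operation subtracts two
    # identically computed smoothed columns/rows, so constant regions cancel
    # exactly instead of leaving accumulation-order float residue
    w <- if (op == "sobel") 2 else 1
    P <- pad_replicate(image, 1, 1, 1, 1)
    sv <- P[1:H, ] + w * P[2:(H + 1), ] + P[3:(H + 2), ]   # vertical [1,w,1]
    gx <- sv[, 3:(W + 2)] - sv[, 1:W]
    sh <- P[, 1:W] + w * P[, 2:(W + 1)] + P[, 3:(W + 2)]   # horizontal [1,w,1]
    gy <- sh[1:H, ] - sh[3:(H + 2), ]
    valid <- matrix(FALSE, H, W)
    if (H > 2 && W > 2) valid[2:(H - 1), 2:(W - 1)] <- TRUE
  }
  new_gradient_field(gx, gy, valid, op)
}

#' @rdname apply_edge_operator
#' @export
edge_templates <- function(op = c("roberts", "sobel", "prewitt")) {
  op <- match.arg(op)
  switch(op,
    roberts = list(
      gx = matrix(c(1, 0, 0, -1), 2, 2, byrow = TRUE),
      gy = matrix(c(0, 1, -1, 0), 2, 2, byrow = TRUE)
    ),
    sobel = list(
      gx = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE),
      gy = matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3, byrow = TRUE)
    ),
    prewitt = list(
      gx = matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3, byrow = TRUE),
      gy = matrix(c(1, 1, 1, 0, 0, 0, -1, -1, -1), 3, 3, byrow = TRUE)
    )
  )
}
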