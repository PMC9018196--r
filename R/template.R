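#' Sum-of-squared-differences template scan
#'
#' Scores every full-overlap placement of `template` over `image` by
#' `SE(x, y) = sum_{i,j} (f_window(i, j) - T(i, j))^2`, the sum running over
#' the template support. Only valid placements are scored (a partial window
#' would leave the sum undefined), so the surface has size
#' `(H - N + 1) x (W - N + 1)` and is indexed by the window's top-left
#' anchor. `SE >= 0` everywhere and `SE = 0` exactly when the window equals
#' the template.
#'
#' Two algebraically identical routes are provided. `method = "direct"`
#' evaluates the squared difference window by window. `method = "expanded"`
#' (default, faster) uses the three-term expansion
#' `SE = sum f^2 - 2 sum f T + sum T^2`: a box sum of the squared image,
#' a cross-correlation with the template, and the template energy.
#'
#' @param image single-channel numeric matrix.
#' @param template single-channel numeric matrix, no larger than `image`.
#'   Square templates are the expected case; a non-square template is
#'   accepted with a warning.
#' @param method `"expanded"` or `"direct"`.
#' @return a `match_surface`: list with the SSD matrix `se`, `argmin`
#'   (`(row, col)` anchor of the global minimum, ties broken by smallest
#'   `(row, col)` lexicographically), `se_min`, `template_shape`, `method`.
#' @examples
#' img <- matrix(runif(64 * 64), 64, 64)
#' tpl <- img[11:18, 21:28]
#' ssd_scan(img, tpl)$argmin  # c(11, 21)
#' @export
ssd_scan <- function(image, template, method = c("expanded", "direct")) {
  image <- as_image(image, allow_rgb = FALSE)
  template <- as_image(template, allow_rgb = FALSE)
  method <- match.arg(method)
  th <- nrow(template); tw <- ncol(template)
  if (th > nrow(image) || tw > ncol(image)) abort("template larger than image")
  if (th != tw) warn("non-square template accepted; scoring uses its full support")
  se <- if (method == "direct") {
    ssd_direct(image, template)
  } else {
    ssd_expanded(image, template)
  }
  se <- pmax(se, 0)  # guard tiny negative float residue in the expanded route
  amin <- argmin_lex(se)
  structure(
    list(se = se, argmin = amin, se_min = se[amin[1], amin[2]],
         template_shape = c(th, tw), method = method),
    class = "match_surface"
  )
}

ssd_direct <- function(image, template) {
  th <- nrow(template); tw <- ncol(template)
  oh <- nrow(image) - th + 1L; ow <- ncol(image) - tw + 1L
  se <- matrix(0, oh, ow)
  for (y in seq_len(oh)) {
    for (x in seq_len(ow)) {
      w <- image[y:(y + th - 1L), x:(x + tw - 1L)]
      se[y, x] <- sum((w - template)^2)
    }
  }
  se
}

ssd_expanded <- function(image, template) {
  ones <- matrix(1, nrow(template), ncol(template))
  window_energy <- correlate_valid(image^2, ones)  # sum f^2 over each window
  cross <- correlate_valid(image, template)        # sum f * T
  window_energy - 2 * cross + sum(template^2)
}

# Global minimum with (row, col) lexicographic tie-break.
argmin_lex <- function(m) {
  mn <- min(m)
  idx <- which(m == mn)
  rows <- ((idx - 1L) %% nrow(m)) + 1L
  cols <- ((idx - 1L) %/% nrow(m)) + 1L
  o <- order(rows, cols)[1]
  c(rows[o], cols[o])
}

#' @export
print.match_surface <- function(x, ...) {
  cat("<match_surface> ", nrow(x$se), "x", ncol(x$se),
      " placements, template ", x$template_shape[1], "x", x$template_shape[2],
      "; min SE=", format(x$se_min, digits = 5),
      " at (", x$argmin[1], ", ", x$argmin[2], ")\n", sep = "")
  invisible(x)
}
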