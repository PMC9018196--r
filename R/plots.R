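image_raster_df <- function(image) {
  image <- to_gray(image)
  tibble(
    row = rep(seq_len(nrow(image)), times = ncol(image)),
    col = rep(seq_len(ncol(image)), each = nrow(image)),
    intensity = as.vector(image)
  )
}

#' Plot detected corners over their image
#'
#' @param object a `corner_set`.
#' @param image optional image the corners were detected in, drawn as a
#'   grayscale raster underneath.
#' @param ... unused.
#' @return a ggplot; the y axis is reversed so the origin sits top-left,
#'   matching the `(row, col)` convention.
#' @method autoplot corner_set
#' @export
autoplot.corner_set <- function(object, image = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    p <- p + ggplot2::geom_raster(
      data = image_raster_df(image),
      ggplot2::aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none")
  }
  p +
    ggplot2::geom_point(
      data = as_tibble(unclass_tbl(object)),
      ggplot2::aes(x = .data$col, y = .data$row, size = .data$response),
      colour = "red", shape = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col", y = "row", size = "R")
}

#' Plot a gradient field's magnitude
#'
#' @param object a `gradient_field`.
#' @param ... unused.
#' @method autoplot gradient_field
#' @export
autoplot.gradient_field <- function(object, ...) {
  df <- tidy.gradient_field(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste0("|G| (", object$operator, ")"))
}

#' Plot the objective trajectory of a robust colour-model fit
#'
#' @param object a `color_model`.
#' @param ... unused.
#' @method autoplot color_model
#' @export
autoplot.color_model <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$E_trajectory) - 1L,
               E = object$E_trajectory)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$E)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "refit iteration (0 = search stage)",
                  y = "truncated objective E")
}

#' Plot an SSD match surface
#'
#' @param object a `match_surface`.
#' @param ... unused.
#' @method autoplot match_surface
#' @export
autoplot.match_surface <- function(object, ...) {
  df <- tibble(
    row = rep(seq_len(nrow(object$se)), times = ncol(object$se)),
    col = rep(seq_len(ncol(object$se)), each = nrow(object$se)),
    se = as.vector(object$se)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$se)) +
    ggplot2::geom_raster() +
    ggplot2::annotate("point", x = object$argmin[2], y = object$argmin[1],
                      colour = "red", shape = 4, size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(fill = "SE")
}

#' Plot ranked evaluation scores
#'
#' @param object a `fuzzy_evaluation`.
#' @param ... unused.
#' @method autoplot fuzzy_evaluation
#' @export
autoplot.fuzzy_evaluation <- function(object, ...) {
  df <- object$scores
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$alternative, .data$score),
                                   y = .data$score)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "composite score")
}
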