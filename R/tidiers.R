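#' Tidy a fitted colour model
#'
#' @param x a `color_model` from [ransac_fit()].
#' @param ... unused.
#' @return one row per channel with `channel`, `gain`, `offset`.
#' @method tidy color_model
#' @export
tidy.color_model <- function(x, ...) {
  ch <- if (x$n_channels == 3) c("red", "green", "blue") else
    paste0("ch", seq_len(x$n_channels))
  tibble(channel = ch, gain = x$gain, offset = x$offset)
}

#' @rdname tidy.color_model
#' @return `glance()` returns a one-row fit summary.
#' @method glance color_model
#' @export
glance.color_model <- function(x, ...) {
  tibble(
    n = x$n,
    n_inliers = sum(x$inlier_mask),
    inlier_fraction = mean(x$inlier_mask),
    E = x$E,
    iterations = length(x$E_trajectory) - 1L,
    converged = x$converged,
    low_confidence = x$low_confidence
  )
}

#' @method tidy corner_set
#' @export
tidy.corner_set <- function(x, ...) as_tibble(unclass_tbl(x))

#' @method tidy match_set
#' @export
tidy.match_set <- function(x, ...) as_tibble(unclass_tbl(x))

#' @method tidy weight_vector
#' @export
tidy.weight_vector <- function(x, ...) as_tibble(unclass_tbl(x))

#' Tidy an evaluation result
#'
#' @param x a `fuzzy_evaluation` from [evaluate_alternatives()].
#' @param ... unused.
#' @return the ranked score table (`alternative`, `score`, `rank`).
#' @method tidy fuzzy_evaluation
#' @export
tidy.fuzzy_evaluation <- function(x, ...) x$scores

#' @rdname tidy.fuzzy_evaluation
#' @method glance fuzzy_evaluation
#' @export
glance.fuzzy_evaluation <- function(x, ...) {
  tibble(
    n_alternatives = nrow(x$scores),
    n_indicators = nrow(x$composite_weights),
    best = x$scores$alternative[1],
    best_score = x$scores$score[1]
  )
}

#' @method tidy gradient_field
#' @export
tidy.gradient_field <- function(x, ...) {
  tibble(
    row = rep(seq_len(nrow(x$gx)), times = ncol(x$gx)),
    col = rep(seq_len(ncol(x$gx)), each = nrow(x$gx)),
    gx = as.vector(x$gx),
    gy = as.vector(x$gy),
    magnitude = as.vector(x$magnitude),
    angle = as.vector(x$angle),
    valid = as.vector(x$valid_mask)
  )
}

#' @method tidy run_report
#' @export
tidy.run_report <- function(x, ...) x$stages

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("corner_set", "match_set", "weight_vector"))
  x
}
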