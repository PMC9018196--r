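#' Residuals of a per-channel linear colour model
#'
#' The colour model relates paired observations by a diagonal gain plus
#' offset per channel: `b_c = gain_c * a_c + offset_c`. The residual of a
#' pair is the Euclidean norm over channels of
#' `b - gain * a - offset`, a single `d_n` per pair pooling all channels.
#'
#' @param pairs correspondence values: a list with `n x C` matrices `a` and
#'   `b` (a `correspondence_scene` works), or a data frame with `a_*`/`b_*`
#'   channel columns.
#' @param gain,offset numeric per-channel vectors.
#' @return numeric vector of per-pair residual norms `d_n >= 0`.
#' @export
channel_residuals <- function(pairs, gain, offset) {
  ab <- pairs_to_matrices(pairs)
  if (length(gain) != ncol(ab$a)) abort("gain length must match the number of channels")
  if (!all(is.finite(gain)) || !all(is.finite(offset))) abort("model parameters must be finite")
  resid <- ab$b - sweep(sweep(ab$a, 2, gain, `*`), 2, offset, `+`)
  sqrt(rowSums(resid^2))
}

pairs_to_matrices <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs) && !is.null(pairs$a) && !is.null(pairs$b)) {
    return(list(a = as.matrix(pairs$a), b = as.matrix(pairs$b)))
  }
  if (is.data.frame(pairs)) {
    a_cols <- grep("^a_", names(pairs), value = TRUE)
    b_cols <- grep("^b_", names(pairs), value = TRUE)
    if (length(a_cols) == 0 || length(a_cols) != length(b_cols)) {
      abort("data frame pairs need matching a_* and b_* channel columns")
    }
    return(list(a = as.matrix(pairs[a_cols]), b = as.matrix(pairs[b_cols])))
  }
  abort("pairs must be a list with matrices a, b or a data frame with a_*/b_* columns")
}

#' Truncated squared-residual objective
#'
#' `E = sum_n T(d_n^2)` with `T(d_n^2) = d_n^2` when `d_n^2 < Thre^2` and
#' `T(d_n^2) = Thre^2` otherwise, i.e. `E = sum(pmin(d^2, Thre^2))`.
#' Truncation caps each pair's contribution so outliers cannot dominate:
#' `0 <= E <= n * Thre^2` always.
#'
#' @param residuals numeric vector of per-pair residual norms `d_n`.
#' @param thre truncation threshold `Thre > 0`, intensity units.
#' @return scalar objective value `E`.
#' @export
truncated_objective <- function(residuals, thre) {
  if (!is.numeric(thre) || thre <= 0) abort("thre must be > 0")
  sum(pmin(residuals^2, thre^2))
}

#' Robust colour-model fit by RANSAC with a truncated loss
#'
#' Purifies correspondences contaminated by mismatches by robustly fitting
#' the per-channel linear colour model. The procedure is
#' hypothesize-and-verify followed by iterative refinement:
#' \enumerate{
#'   \item draw `n_hypotheses` random samples of `n_sample` pairs; fit
#'     gain/offset per channel by least squares on each sample (degenerate
#'     samples with constant source values are redrawn); score every
#'     hypothesis by the truncated objective `E` over all pairs and keep the
#'     best;
#'   \item refit on the inliers of the best model (pairs with
#'     `d_n^2 < Thre^2`) and iterate the refit until `|dE| < converge_eps`
#'     or `max_iter` refits; `E` is non-increasing across refits.
#' }
#' The final inlier mask satisfies `d_n^2 < Thre^2` under the returned model.
#' A fit whose inlier fraction falls below `min_inlier_frac` is flagged
#' low-confidence (with fully contaminated data `E` approaches
#' `n * Thre^2`). Deterministic given `seed`; the caller's RNG state is
#' untouched.
#'
#' @param pairs correspondences (see [channel_residuals()]); at least 4.
#' @param thre truncation threshold `Thre`, default `0.05` intensity units
#'   for images in `[0, 1]`.
#' @param n_hypotheses random samples drawn in the search stage.
#' @param n_sample pairs per sample, `>= 2`.
#' @param max_iter cap on refinement iterations.
#' @param converge_eps stop when the objective changes by less than this.
#' @param min_inlier_frac inlier fraction below which the model is flagged
#'   low-confidence.
#' @param seed integer seed.
#' @return a `color_model`: list with `gain`, `offset`, `inlier_mask`,
#'   `residuals`, `E_trajectory` (objective after the search stage and after
#'   each refit), `E`, `thre`, `converged`, `low_confidence`, `n`, `seed`.
#' @examples
#' sc <- make_correspondence_scene(100, gain = c(2, 1, 0.5),
#'                                 offset = c(0.1, 0, -0.1),
#'                                 outlier_fraction = 0.2, seed = 1)
#' fit <- ransac_fit(sc, seed = 1)
#' round(fit$gain, 3)
#' @export
ransac_fit <- function(pairs, thre = 0.05, n_hypotheses = 500L, n_sample = 3L,
                       max_iter = 100L, converge_eps = 1e-8,
                       min_inlier_frac = 0.25, seed = 0L) {
  ab <- pairs_to_matrices(pairs)
  n <- nrow(ab$a); C <- ncol(ab$a)
  if (n < 4) abort("ransac_fit needs at least 4 pairs")
  if (n_sample < 2) abort("n_sample must be >= 2")
  if (thre <= 0) abort("thre must be > 0")
  withr::with_seed(as.integer(seed), {
    best <- NULL
    best_E <- Inf
    draws <- 0L
    while (draws < n_hypotheses) {
      idx <- sample.int(n, n_sample)
      m <- ls_channel_fit(ab$a[idx, , drop = FALSE], ab$b[idx, , drop = FALSE])
      if (is.null(m)) next  # degenerate sample: redraw without consuming a draw
      draws <- draws + 1L
      d <- channel_residuals(ab, m$gain, m$offset)
      E <- truncated_objective(d, thre)
      if (E < best_E) { best_E <- E; best <- m }
    }
    if (is.null(best)) abort("hypothesis stage failed: every sample was degenerate")
    model <- best
    E_traj <- best_E
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      d <- channel_residuals(ab, model$gain, model$offset)
      mask <- d^2 < thre^2
      if (sum(mask) < 2) {
        abort("refit stage failed: fewer than 2 inliers under the best model")
      }
      refit <- ls_channel_fit(ab$a[mask, , drop = FALSE], ab$b[mask, , drop = FALSE])
      if (is.null(refit)) break  # constant inlier sources: keep current model
      d_new <- channel_residuals(ab, refit$gain, refit$offset)
      E_new <- truncated_objective(d_new, thre)
      model <- refit
      delta <- abs(E_traj[length(E_traj)] - E_new)
      E_traj <- c(E_traj, E_new)
      if (delta < converge_eps) { converged <- TRUE; break }
    }
    d <- channel_residuals(ab, model$gain, model$offset)
    mask <- d^2 < thre^2
    structure(
      list(gain = model$gain, offset = model$offset,
           inlier_mask = mask, residuals = d,
           E_trajectory = E_traj, E = E_traj[length(E_traj)],
           thre = thre, converged = converged,
           low_confidence = mean(mask) < min_inlier_frac,
           n = n, n_channels = C, seed = as.integer(seed)),
      class = "color_model"
    )
  })
}

# Per-channel ordinary least squares for b = gain*a + offset.
# Returns NULL when any source channel is (numerically) constant.
ls_channel_fit <- function(a, b) {
  C <- ncol(a)
  gain <- numeric(C); offset <- numeric(C)
  for (c in seq_len(C)) {
    x <- a[, c]; y <- b[, c]
    sxx <- sum((x - mean(x))^2)
    if (sxx < 1e-12) return(NULL)
    g <- sum((x - mean(x)) * (y - mean(y))) / sxx
    gain[c] <- g
    offset[c] <- mean(y) - g * mean(x)
  }
  list(gain = gain, offset = offset)
}

#' @export
print.color_model <- function(x, ...) {
  cat("<color_model> channels=", x$n_channels,
      " inliers=", sum(x$inlier_mask), "/", x$n,
      " E=", format(x$E, digits = 5),
      if (x$low_confidence) " [LOW CONFIDENCE]" else "", "\n", sep = "")
  cat("  gain:   ", paste(format(x$gain, digits = 4), collapse = " "), "\n", sep = "")
  cat("  offset: ", paste(format(x$offset, digits = 4), collapse = " "), "\n", sep = "")
  invisible(x)
}
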