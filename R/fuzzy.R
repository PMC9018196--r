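#' Pairwise judgment matrices
#'
#' A judgment matrix records pairwise relative importances among indicators:
#' entry `a[i, j]` is the weight of indicator `i` relative to indicator `j`.
#' Validation enforces what pairwise comparison implies: all entries
#' positive, unit diagonal, and reciprocity `a[i, j] * a[j, i] = 1` within
#' `1e-6` (a matrix failing reciprocity is rejected with a repair
#' suggestion rather than silently accepted). Entries on the Saaty 1–9
#' scale are conventional, but any positive reals are accepted.
#'
#' @param a square numeric matrix of positive entries.
#' @param labels optional indicator names (defaults to column names or
#'   `I1..In`).
#' @return a `judgment_matrix` (the validated matrix with labels as
#'   dimnames).
#' @examples
#' judgment_matrix(matrix(c(1, 2, 0.5, 1), 2, 2, byrow = TRUE))
#' @export
judgment_matrix <- function(a, labels = NULL) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a)) abort("judgment matrix must be square")
  n <- nrow(a)
  bad <- which(!(is.finite(a) & a > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("non-positive judgment entry at [", bad[1, 1], ", ", bad[1, 2], "]"))
  }
  if (any(abs(diag(a) - 1) > 1e-9)) abort("judgment matrix diagonal must be 1")
  recip <- a * t(a)
  off <- which(abs(recip - 1) > 1e-6, arr.ind = TRUE)
  if (nrow(off) > 0) {
    i <- off[1, 1]; j <- off[1, 2]
    abort(paste0(
      "reciprocity violated at [", i, ", ", j, "]: a[i,j]*a[j,i] = ",
      format(recip[i, j], digits = 6),
      "; repair by setting a[j,i] = 1 / a[i,j]"))
  }
  if (is.null(labels)) labels <- colnames(a)
  if (is.null(labels)) labels <- paste0("I", seq_len(n))
  dimnames(a) <- list(labels, labels)
  structure(a, class = c("judgment_matrix", "matrix", "array"))
}

#' Geometric-mean weights from a judgment matrix
#'
#' The row-product weighting: `M_i = prod_j a[i, j]`, the n-th root
#' `wbar_i = M_i^(1/n)`, normalized to `w_i = wbar_i / sum(wbar)`. For a
#' perfectly consistent matrix built from planted weights
#' (`a[i, j] = p_i / p_j`) this recovers `p` exactly up to scale. Row
#' products are accumulated in log space so large matrices cannot overflow.
#'
#' @param m a [judgment_matrix()] (or a matrix passed through it).
#' @param level label attached to the result: `"criterion"`, `"measure"` or
#'   `"composite"`.
#' @return a `weight_vector`: tibble with columns `indicator`, `weight`
#'   (summing to 1), with the level as an attribute.
#' @examples
#' geometric_mean_weights(judgment_matrix(matrix(c(1, 2, 0.5, 1), 2, 2, byrow = TRUE)))
#' @export
geometric_mean_weights <- function(m, level = c("criterion", "measure", "composite")) {
  if (!inherits(m, "judgment_matrix")) m <- judgment_matrix(m)
  level <- match.arg(level)
  n <- nrow(m)
  log_root <- rowSums(log(m)) / n   # log of M_i^(1/n)
  wbar <- exp(log_root - max(log_root))
  w <- wbar / sum(wbar)
  new_weight_vector(tibble(indicator = rownames(m), weight = as.numeric(w)), level)
}

new_weight_vector <- function(tbl, level) {
  if (any(tbl$weight < 0)) abort("weights must be non-negative")
  if (abs(sum(tbl$weight) - 1) > 1e-9) abort("weights must sum to 1")
  structure(tbl, class = c("weight_vector", class(tbl)), level = level)
}

#' Composite weights over a two-level hierarchy
#'
#' In a two-level hierarchy (criteria above measures) the composite weight
#' of measure `j` under criterion `i` is the product `w_i * w_j` of the
#' criterion weight and the within-criterion measure weight. The flattened
#' composite vector sums to 1 by distributivity.
#'
#' @param criterion_w `weight_vector` over the criteria.
#' @param measure_w_per_criterion list with one measure-level
#'   `weight_vector` per criterion, in criterion order.
#' @return a composite `weight_vector`; indicators are labelled
#'   `criterion:measure`.
#' @export
composite_weights <- function(criterion_w, measure_w_per_criterion) {
  if (nrow(criterion_w) != length(measure_w_per_criterion)) {
    abort("need exactly one measure-level weight vector per criterion")
  }
  parts <- lapply(seq_len(nrow(criterion_w)), function(i) {
    mw <- measure_w_per_criterion[[i]]
    tibble(
      indicator = paste0(criterion_w$indicator[i], ":", mw$indicator),
      weight = criterion_w$weight[i] * mw$weight
    )
  })
  out <- bind_rows(parts)
  new_weight_vector(out, "composite")  # sums to 1 by distributivity
}

#' Score and rank alternatives under composite weights
#'
#' Each alternative's score is the weighted sum `E_a = sum_i w_i * v_i` of
#' its per-indicator evaluation values `v` under the composite weights `w`.
#' Scores are on whatever common scale the `v` values use (0–100 by
#' convention). Alternatives are ranked by descending score, ties broken by
#' name.
#'
#' @param composite composite `weight_vector` of length `n`.
#' @param score_matrix matrix or data frame of evaluation values, one row
#'   per alternative, `n` columns in composite-indicator order; row names
#'   (or a first column named `alternative`) name the alternatives.
#' @return a `fuzzy_evaluation`: list with `scores` (tibble `alternative`,
#'   `score`, `rank`), `composite_weights`, `score_matrix`.
#' @examples
#' cw <- composite_weights(
#'   geometric_mean_weights(consistent_judgment(c(3, 2))),
#'   list(geometric_mean_weights(consistent_judgment(c(1, 1))),
#'        geometric_mean_weights(consistent_judgment(c(1))))
#' )
#' evaluate_alternatives(cw, matrix(c(80, 60, 90), 1,
#'                       dimnames = list("chitosan", NULL)))
#' @export
evaluate_alternatives <- function(composite, score_matrix) {
  if (is.data.frame(score_matrix) && "alternative" %in% names(score_matrix)) {
    alts <- score_matrix$alternative
    score_matrix <- as.matrix(score_matrix[setdiff(names(score_matrix), "alternative")])
    rownames(score_matrix) <- alts
  } else {
    score_matrix <- as.matrix(score_matrix)
  }
  if (ncol(score_matrix) != nrow(composite)) {
    bad <- if (!is.null(rownames(score_matrix))) rownames(score_matrix)[1] else "row 1"
    abort(paste0("alternative '", bad, "': ", ncol(score_matrix),
                 " scores but ", nrow(composite), " composite weights"))
  }
  if (is.null(rownames(score_matrix))) {
    rownames(score_matrix) <- paste0("A", seq_len(nrow(score_matrix)))
  }
  ea <- as.numeric(score_matrix %*% composite$weight)
  scores <- tibble(alternative = rownames(score_matrix), score = ea)
  scores <- arrange(scores, desc(.data$score), .data$alternative)
  scores$rank <- seq_len(nrow(scores))
  structure(
    list(scores = scores, composite_weights = composite, score_matrix = score_matrix),
    class = "fuzzy_evaluation"
  )
}

#' @export
print.fuzzy_evaluation <- function(x, ...) {
  cat("<fuzzy_evaluation> ", nrow(x$scores), " alternatives\n", sep = "")
  print(as.data.frame(x$scores), row.names = FALSE)
  invisible(x)
}

#' Consistency ratio of a judgment matrix
#'
#' The standard coherence diagnostic: the principal eigenvalue
#' `lambda_max` of the matrix gives the consistency index
#' `CI = (lambda_max - n) / (n - 1)`, divided by the tabulated random index
#' `RI(n)` to give `CR = CI / RI`. A perfectly consistent matrix
#' (`a[i, j] = p_i / p_j`) has `lambda_max = n` and `CR = 0`. By convention
#' `CR = 0` for `n <= 2`; `CR <= 0.1` is the usual acceptance rule.
#'
#' @param m a [judgment_matrix()], `1 <= n <= 10`.
#' @return scalar consistency ratio.
#' @export
consistency_ratio <- function(m) {
  if (!inherits(m, "judgment_matrix")) m <- judgment_matrix(m)
  n <- nrow(m)
  if (n > 10) abort("consistency_ratio: random-index table covers n <= 10")
  if (n <= 2) return(0)
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)
  ev <- eigen(unclass(m), only.values = TRUE)$values
  lambda_max <- max(Re(ev[abs(Im(ev)) < 1e-8 * max(1, abs(Re(ev)))]))
  ci <- (lambda_max - n) / (n - 1)
  max(ci, 0) / ri[n]
}

#' Generate a judgment matrix from planted weights
#'
#' Builds `a[i, j] = p_i / p_j` from a planted positive weight vector,
#' optionally perturbed by symmetric multiplicative noise
#' (`a[i, j] * exp(e)`, `a[j, i]` set to the reciprocal) so reciprocity
#' still holds exactly. With `perturb = 0` the matrix is perfectly
#' consistent and [geometric_mean_weights()] recovers `p / sum(p)` exactly.
#'
#' @param p positive planted weights (any scale).
#' @param perturb standard deviation of log-normal entry noise.
#' @param seed integer seed (used only when `perturb > 0`).
#' @param labels optional indicator names.
#' @return a `judgment_matrix`.
#' @export
consistent_judgment <- function(p, perturb = 0, seed = 0L, labels = NULL) {
  if (any(p <= 0)) abort("planted weights must be positive")
  n <- length(p)
  a <- outer(p, p, `/`)
  if (perturb > 0) {
    withr::with_seed(as.integer(seed), {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          f <- exp(rnorm(1, sd = perturb))
          a[i, j] <- a[i, j] * f
          a[j, i] <- 1 / a[i, j]
        }
      }
    })
  }
  judgment_matrix(a, labels = labels)
}
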