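test_that("geometric-mean weights handle symmetric and hand-computed cases", {
  expect_equal(geometric_mean_weights(judgment_matrix(matrix(1, 3, 3)))$weight,
               rep(1 / 3, 3))
  # [[1, 2], [1/2, 1]]: row products (2, 1/2), square roots (sqrt2, sqrt(1/2))
  w <- geometric_mean_weights(judgment_matrix(matrix(c(1, 2, 0.5, 1), 2, 2, byrow = TRUE)))
  expect_equal(w$weight, c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("a consistent matrix built from planted weights recovers them exactly", {
  withr::with_seed(10, {
    for (rep in 1:20) {
      n <- sample(2:8, 1)
      p <- runif(n, 0.1, 5)
      w <- geometric_mean_weights(consistent_judgment(p))
      expect_lt(max(abs(w$weight - p / sum(p))), 1e-9)
      expect_equal(sum(w$weight), 1, tolerance = 1e-9)
      # scale invariance of the planted vector
      w5 <- geometric_mean_weights(consistent_judgment(5 * p))
      expect_equal(w$weight, w5$weight, tolerance = 1e-12)
    }
  })
})

test_that("judgment-matrix validation names the offending cell", {
  m <- matrix(c(1, 2, 0.5, 1), 2, 2, byrow = TRUE)
  bad <- m; bad[1, 2] <- -2
  expect_error(judgment_matrix(bad), "\\[1, 2\\]")
  bad <- m; bad[2, 1] <- 0.6
  expect_error(judgment_matrix(bad), "reciprocity")
  bad <- m; diag(bad) <- 2
  expect_error(judgment_matrix(bad), "diagonal")
})

test_that("composite weights multiply through the hierarchy and sum to one", {
  wv <- function(w, lab) geometric_mean_weights(consistent_judgment(w, labels = lab))
  comp <- composite_weights(wv(c(1, 1), c("c1", "c2")),
                            list(wv(1, "m"), wv(1, "m")))
  expect_equal(comp$weight, c(0.5, 0.5))
  comp <- composite_weights(wv(c(0.6, 0.4), c("c1", "c2")),
                            list(wv(c(1, 1), c("m1", "m2")), wv(1, "m1")))
  expect_equal(comp$weight, c(0.3, 0.3, 0.4), tolerance = 1e-12)
  expect_equal(comp$indicator, c("c1:m1", "c1:m2", "c2:m1"))
  expect_error(composite_weights(wv(c(1, 1), c("c1", "c2")), list(wv(1, "m"))),
               "one measure-level")
  withr::with_seed(14, {
    for (rep in 1:20) {
      k <- sample(2:5, 1)
      cw <- wv(runif(k, 0.2, 3), paste0("c", 1:k))
      mws <- lapply(1:k, function(i) {
        m <- sample(1:4, 1)
        wv(runif(m, 0.2, 3), paste0("m", 1:m))
      })
      expect_equal(sum(composite_weights(cw, mws)$weight), 1, tolerance = 1e-12)
    }
  })
})

test_that("alternative scores are weighted sums with a full ranking", {
  wv3 <- composite_weights(
    geometric_mean_weights(consistent_judgment(c(0.6, 0.4), labels = c("c1", "c2"))),
    list(geometric_mean_weights(consistent_judgment(c(1, 1), labels = c("m1", "m2"))),
         geometric_mean_weights(consistent_judgment(1, labels = "m1")))
  )  # weights (0.3, 0.3, 0.4)
  res <- evaluate_alternatives(wv3, matrix(c(80, 60, 90), 1,
                                           dimnames = list("chitosan", NULL)))
  expect_equal(res$scores$score, 78)
  # uniform weights and equal scores collapse to the common score
  u <- composite_weights(
    geometric_mean_weights(consistent_judgment(c(1, 1))),
    list(geometric_mean_weights(consistent_judgment(c(1, 1))),
         geometric_mean_weights(consistent_judgment(c(1, 1)))))
  res <- evaluate_alternatives(u, matrix(55, 2, 4))
  expect_equal(res$scores$score, c(55, 55))
  expect_error(evaluate_alternatives(wv3, matrix(1, 1, 5,
                                                 dimnames = list("filmX", NULL))),
               "filmX")
})

test_that("a weakly dominant alternative always ranks first", {
  withr::with_seed(15, {
    for (rep in 1:30) {
      n <- sample(3:6, 1)
      w <- geometric_mean_weights(consistent_judgment(runif(n, 0.2, 3)),
                                  level = "composite")
      scores <- matrix(runif(3 * n, 40, 90), 3)
      rownames(scores) <- c("material_A", "material_B", "material_C")
      scores[3, ] <- apply(scores, 2, max) + runif(n, 0.1, 5)  # C dominates
      res <- evaluate_alternatives(w, scores)
      expect_equal(res$scores$alternative[1], "material_C")
      expect_equal(res$scores$rank, 1:3)
    }
  })
})

test_that("permuting indicators leaves every alternative's score unchanged", {
  withr::with_seed(16, {
    p <- runif(5, 0.2, 3)
    w <- geometric_mean_weights(consistent_judgment(p), level = "composite")
    scores <- matrix(runif(15, 0, 100), 3,
                     dimnames = list(c("a", "b", "c"), NULL))
    perm <- sample(5)
    wp <- geometric_mean_weights(consistent_judgment(p[perm]), level = "composite")
    r1 <- evaluate_alternatives(w, scores)
    r2 <- evaluate_alternatives(wp, scores[, perm])
    expect_equal(r1$scores, r2$scores, tolerance = 1e-12)
  })
})

test_that("consistency ratio is zero for consistent matrices and matches eigen oracle", {
  withr::with_seed(17, {
    expect_lt(consistency_ratio(consistent_judgment(runif(6, 0.2, 3))), 1e-9)
  })
  expect_equal(consistency_ratio(judgment_matrix(matrix(c(1, 3, 1 / 3, 1), 2, 2,
                                                        byrow = TRUE))), 0)
  # a classic inconsistent triple: prefers 1 > 2 > 3 but also 3 over 1
  m <- judgment_matrix(matrix(c(1, 2, 0.5, 0.5, 1, 2, 2, 0.5, 1), 3, 3, byrow = TRUE))
  lam <- power_lambda_max(unclass(m))
  expect_equal(consistency_ratio(m), ((lam - 3) / 2) / 0.58, tolerance = 1e-6)
  expect_gt(consistency_ratio(m), 0.1)
  big <- diag(11); big[upper.tri(big)] <- 1; big[lower.tri(big)] <- 1
  expect_error(consistency_ratio(judgment_matrix(big)), "n <= 10")
})
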