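test_that("channel residuals pool channels into a Euclidean norm per pair", {
  pairs <- list(a = matrix(0.2, 1, 3), b = matrix(0.2 * c(2, 1, 0.5) + c(0.1, 0, -0.1), 1, 3))
  expect_equal(channel_residuals(pairs, c(2, 1, 0.5), c(0.1, 0, -0.1)), 0)
  # identity model, offsets (0.3, 0.4, 0): a 3-4-5 norm
  pairs <- list(a = matrix(0, 1, 3), b = matrix(c(0.3, 0.4, 0), 1, 3))
  expect_equal(channel_residuals(pairs, c(1, 1, 1), c(0, 0, 0)), 0.5)
  withr::with_seed(2, {
    a <- matrix(runif(30), 10, 3); b <- matrix(runif(30), 10, 3)
    g <- runif(3, 0.5, 2); o <- runif(3, -0.1, 0.1)
    hand <- sqrt(rowSums((b - t(t(a) * g + o))^2))
    expect_equal(channel_residuals(list(a = a, b = b), g, o), hand, tolerance = 1e-12)
  })
})

test_that("the truncated objective clamps each squared residual at Thre^2", {
  expect_equal(truncated_objective(rep(0, 10), 0.2), 0)
  expect_equal(truncated_objective(c(0.1, 0.5), 0.2), 0.01 + 0.04)
  expect_error(truncated_objective(c(0.1), 0), "> 0")
  withr::with_seed(5, {
    for (rep in 1:10) {
      d <- runif(100, 0, 0.3)
      thre <- runif(1, 0.01, 0.2)
      oracle <- sum(ifelse(d^2 < thre^2, d^2, thre^2))
      E <- truncated_objective(d, thre)
      expect_equal(E, oracle, tolerance = 1e-15)
      expect_gte(E, 0)
      expect_lte(E, 100 * thre^2)
    }
  })
})

test_that("clean correspondences are recovered to numerical precision", {
  sc <- make_correspondence_scene(80, gain = c(1.4, 0.9, 0.6),
                                  offset = c(0.05, 0, -0.05),
                                  outlier_fraction = 0, noise_sigma = 0, seed = 1)
  fit <- ransac_fit(sc, thre = 0.05, seed = 1)
  expect_lt(max(abs(fit$gain - sc$true_gain)), 1e-9)
  expect_lt(max(abs(fit$offset - sc$true_offset)), 1e-9)
  expect_true(all(fit$inlier_mask))
  expect_false(fit$low_confidence)
})

test_that("a 30% contaminated scene is purified with the planted model recovered", {
  sc <- make_correspondence_scene(200, gain = c(2, 1, 0.5), offset = c(0.1, 0, -0.1),
                                  outlier_fraction = 0.3, noise_sigma = 0.005, seed = 3)
  fit <- ransac_fit(sc, thre = 0.05, seed = 3)
  expect_lt(max(abs(fit$gain - sc$true_gain)), 0.02)
  expect_lt(max(abs(fit$offset - sc$true_offset)), 0.02)
  true_in <- setdiff(1:200, sc$outlier_indices)
  expect_gte(mean(fit$inlier_mask[true_in]), 0.95)
  expect_lte(mean(fit$inlier_mask[sc$outlier_indices]), 0.05)
  # final inliers satisfy the truncation condition under the final model
  expect_true(all(fit$residuals[fit$inlier_mask]^2 < fit$thre^2))
})

test_that("fully contaminated data saturates the objective and is flagged", {
  withr::with_seed(4, {
    pairs <- list(a = matrix(runif(600), 200, 3), b = matrix(runif(600), 200, 3))
  })
  fit <- ransac_fit(pairs, thre = 0.05, seed = 4)
  expect_true(fit$low_confidence)
  expect_gte(fit$E, 0.8 * 200 * 0.05^2)
  expect_lte(fit$E, 200 * 0.05^2)
})

test_that("the objective trajectory never increases across refits", {
  for (seed in 1:6) {
    sc <- make_correspondence_scene(150, gain = c(1.8, 1.1, 0.7),
                                    offset = c(0.05, -0.02, 0.02),
                                    outlier_fraction = 0.25, noise_sigma = 0.01,
                                    seed = seed)
    fit <- ransac_fit(sc, thre = 0.05, seed = seed)
    expect_true(all(diff(fit$E_trajectory) <= 1e-12))
    expect_lte(fit$E, 150 * 0.05^2)
    expect_gte(fit$E, 0)
  }
})

test_that("recovery degrades gracefully as contamination grows", {
  err_at <- function(frac, seed = 11) {
    sc <- make_correspondence_scene(200, gain = c(2, 1, 0.5), offset = c(0.1, 0, -0.1),
                                    outlier_fraction = frac, noise_sigma = 0.005,
                                    seed = seed)
    fit <- ransac_fit(sc, thre = 0.05, seed = seed)
    max(abs(fit$gain - sc$true_gain), abs(fit$offset - sc$true_offset))
  }
  e10 <- err_at(0.1)
  e40 <- err_at(0.4)
  expect_lt(e40, 0.02)        # still a good fit at 40% contamination
  expect_lte(e40, 10 * e10)   # and no cliff between 10% and 40%
})

test_that("the fit is deterministic given the seed and errors cleanly", {
  sc <- make_correspondence_scene(100, gain = c(1.5, 1, 0.8), offset = c(0, 0.05, -0.05),
                                  outlier_fraction = 0.2, noise_sigma = 0.005, seed = 7)
  f1 <- ransac_fit(sc, seed = 7)
  f2 <- ransac_fit(sc, seed = 7)
  expect_identical(f1[c("gain", "offset", "inlier_mask", "E_trajectory")],
                   f2[c("gain", "offset", "inlier_mask", "E_trajectory")])
  expect_error(ransac_fit(list(a = matrix(runif(9), 3, 3),
                               b = matrix(runif(9), 3, 3))), "at least 4")
  withr::with_seed(1, {
    junk <- list(a = matrix(runif(60), 20, 3), b = matrix(runif(60), 20, 3))
  })
  expect_error(ransac_fit(junk, thre = 1e-12, seed = 1), "fewer than 2 inliers")
})

test_that("grayscale correspondences run through the same machinery", {
  sc <- make_correspondence_scene(100, gain = 1.3, offset = 0.05,
                                  outlier_fraction = 0.2, noise_sigma = 0.003, seed = 8)
  fit <- ransac_fit(sc, thre = 0.03, seed = 8)
  expect_equal(fit$n_channels, 1)
  expect_lt(abs(fit$gain - 1.3), 0.02)
  expect_lt(abs(fit$offset - 0.05), 0.02)
})
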