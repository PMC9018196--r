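test_that("a constant image has identically zero corner response", {
  expect_true(all(corner_response(matrix(0.7, 16, 16)) == 0))
})

test_that("response peaks at an L-corner vertex and is negative on edge interiors", {
  img <- matrix(0, 32, 32)
  img[10:32, 10:32] <- 1  # single L-shaped corner with vertex at (10, 10)
  r <- corner_response(img, k = 0.04)
  peak <- which(r == max(r), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(peak - c(10, 10))), 2)
  # far from the vertex, along the vertical edge: one dominant eigenvalue
  expect_lt(r[24, 10], 0)
  expect_lt(r[10, 24], 0)
})

test_that("the response equals the explicit per-pixel structure-tensor oracle", {
  withr::with_seed(3, {
    for (rep in 1:3) {
      img <- matrix(runif(24 * 24), 24, 24)
      got <- corner_response(img, k = 0.04, window_sigma = 1.0)
      want <- naive_corner_response(img, k = 0.04, sigma = 1.0)
      expect_lt(max(abs(got - want)), 1e-9)
    }
  })
})

test_that("response is strictly decreasing in k wherever trace(M)^2 > 0", {
  sc <- make_corner_scene(1, c(48, 48), seed = 5)
  r1 <- corner_response(sc$image, k = 0.04)
  r2 <- corner_response(sc$image, k = 0.06)
  active <- r1 != r2  # trace(M)^2 > 0 exactly where k matters
  expect_true(any(active))
  expect_true(all(r2[active] < r1[active]))
})

test_that("parameter validation warns outside the conventional k interval", {
  img <- matrix(runif(64), 8, 8)
  expect_warning(corner_response(img, k = 0.3), "0.04")
  expect_error(corner_response(img, window_sigma = 0), "window_sigma")
})

test_that("corner selection applies threshold and non-maximum suppression", {
  expect_equal(nrow(detect_corners(matrix(0, 16, 16), threshold = 0.1)), 0)
  # two candidates one pixel apart: only the stronger survives NMS
  resp <- matrix(0, 16, 16)
  resp[8, 8] <- 1.0
  resp[8, 9] <- 0.9
  cs <- detect_corners(resp, threshold = 0.5, nms_radius = 3)
  expect_equal(nrow(cs), 1)
  expect_equal(c(cs$row, cs$col), c(8, 8))
  # retained corners respect the Chebyshev spacing and the threshold
  withr::with_seed(8, {
    resp <- matrix(runif(900), 30, 30)
    cs <- detect_corners(resp, threshold = 0.7, nms_radius = 2)
    expect_true(all(cs$response >= 0.7))
    if (nrow(cs) > 1) {
      d <- as.matrix(dist(cbind(cs$row, cs$col), method = "maximum"))
      expect_true(all(d[upper.tri(d)] > 2))
    }
  })
})

test_that("all planted vertices of noise-free squares are recovered within 2 px", {
  for (seed in 1:5) {
    sc <- make_corner_scene(3, c(96, 96), noise_sigma = 0, seed = seed)
    cs <- find_corners(sc$image)
    pr <- corner_pr(cs, sc$corner_truth, tol = 2)
    expect_equal(pr$precision, 1.0)
    expect_equal(pr$recall, 1.0)
  }
})

test_that("NCC is bounded, symmetric, and invariant to affine intensity maps", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      p <- matrix(runif(81), 9, 9)
      q <- matrix(runif(81), 9, 9)
      s <- ncc(p, q)
      expect_gte(s, -1); expect_lte(s, 1)
      expect_equal(s, ncc(q, p), tolerance = 1e-12)
    }
    p <- matrix(runif(81), 9, 9)
    expect_equal(ncc(p, p), 1)
    expect_equal(ncc(p, 2 * p + 0.1), 1, tolerance = 1e-9)
    expect_equal(ncc(p, -p), -1, tolerance = 1e-12)
  })
  expect_true(is.na(ncc(matrix(0.5, 5, 5), matrix(runif(25), 5, 5))))
})

test_that("corners of a translated copy are matched correctly one-to-one", {
  sc <- make_corner_scene(5, c(128, 128), noise_sigma = 0.01, seed = 6,
                          margin = 10)
  dr <- 4; dc <- 6
  img_b <- matrix(0.1, 128, 128)
  img_b[(1 + dr):128, (1 + dc):128] <- sc$image[1:(128 - dr), 1:(128 - dc)]
  ca <- find_corners(sc$image)
  cb <- find_corners(img_b)
  expect_gte(nrow(ca), 20)
  ms <- ncc_match(sc$image, img_b, ca, cb, patch_radius = 4, min_ncc = 0.8)
  correct <- sum(ms$row_b - ms$row_a == dr & ms$col_b - ms$col_a == dc)
  expect_gte(correct, 18)
  expect_true(all(ms$ncc >= 0.8 & ms$ncc <= 1))
  # one-to-one: no endpoint is reused
  expect_equal(anyDuplicated(ms[, c("row_a", "col_a")]), 0)
  expect_equal(anyDuplicated(ms[, c("row_b", "col_b")]), 0)
})

test_that("self-matching identical corner sets gives ncc = 1 everywhere", {
  sc <- make_corner_scene(2, c(64, 64), noise_sigma = 0.005, seed = 12)
  cs <- find_corners(sc$image)
  ms <- ncc_match(sc$image, sc$image, cs, cs)
  expect_equal(nrow(ms), nrow(cs))
  expect_true(all(abs(ms$ncc - 1) < 1e-12))
  expect_true(all(ms$row_a == ms$row_b & ms$col_a == ms$col_b))
})
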