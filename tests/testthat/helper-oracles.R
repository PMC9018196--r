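# Independent brute-force oracles. Everything here is a deliberately naive
# nested-loop computation, kept free of the package's fast paths so the two
# routes can disagree.

# Valid-mode cross-correlation by explicit loops.
naive_correlate <- function(img, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  oh <- nrow(img) - kh + 1; ow <- ncol(img) - kw + 1
  out <- matrix(0, oh, ow)
  for (y in seq_len(oh)) for (x in seq_len(ow)) {
    s <- 0
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      s <- s + kern[i, j] * img[y + i - 1, x + j - 1]
    }
    out[y, x] <- s
  }
  out
}

clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

# Full-size correlation with clamped (replicate) indexing, centred 3x3 kernel.
naive_correlate_clamped <- function(img, kern) {
  r <- (nrow(kern) - 1) %/% 2
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    s <- 0
    for (i in -r:r) for (j in -r:r) {
      s <- s + kern[i + r + 1, j + r + 1] *
        img[clamp_idx(y + i, H), clamp_idx(x + j, W)]
    }
    out[y, x] <- s
  }
  out
}

# Explicit per-pixel structure tensor and corner response, from scratch:
# Sobel derivatives and Gaussian accumulation both by clamped-index loops.
naive_corner_response <- function(img, k = 0.04, sigma = 1.0) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  sy <- matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3, byrow = TRUE)
  ix <- naive_correlate_clamped(img, sx)
  iy <- naive_correlate_clamped(img, sy)
  r <- ceiling(3 * sigma)
  u <- (-r):r
  w <- outer(exp(-u^2 / (2 * sigma^2)), exp(-u^2 / (2 * sigma^2)))
  w <- w / sum(w)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    m11 <- 0; m12 <- 0; m22 <- 0
    for (i in -r:r) for (j in -r:r) {
      yy <- clamp_idx(y + i, H); xx <- clamp_idx(x + j, W)
      wt <- w[i + r + 1, j + r + 1]
      m11 <- m11 + wt * ix[yy, xx]^2
      m12 <- m12 + wt * ix[yy, xx] * iy[yy, xx]
      m22 <- m22 + wt * iy[yy, xx]^2
    }
    M <- matrix(c(m11, m12, m12, m22), 2, 2)
    out[y, x] <- det(M) - k * sum(diag(M))^2
  }
  out
}

# Exhaustive SSD by explicit window loops.
naive_ssd <- function(img, tpl) {
  th <- nrow(tpl); tw <- ncol(tpl)
  oh <- nrow(img) - th + 1; ow <- ncol(img) - tw + 1
  out <- matrix(0, oh, ow)
  for (y in seq_len(oh)) for (x in seq_len(ow)) {
    s <- 0
    for (i in seq_len(th)) for (j in seq_len(tw)) {
      s <- s + (img[y + i - 1, x + j - 1] - tpl[i, j])^2
    }
    out[y, x] <- s
  }
  out
}

# Principal eigenvalue by power iteration (positive matrix).
power_lambda_max <- function(m, iters = 2000) {
  v <- rep(1, nrow(m))
  for (i in seq_len(iters)) {
    v2 <- as.vector(m %*% v)
    v <- v2 / sqrt(sum(v2^2))
  }
  as.numeric(crossprod(v, m %*% v) / crossprod(v))
}

rotate90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Greedy 1-1 assignment of detected to true corners within a pixel tolerance.
corner_pr <- function(detected, truth, tol = 2) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0
  for (i in seq_len(nrow(detected))) {
    d <- pmax(abs(truth$row - detected$row[i]), abs(truth$col - detected$col[i]))
    j <- which(!used & d <= tol)
    if (length(j) > 0) { used[j[1]] <- TRUE; tp <- tp + 1 }
  }
  list(precision = if (nrow(detected) > 0) tp / nrow(detected) else NA_real_,
       recall = tp / nrow(truth))
}
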