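# Independent oracles used across the suite. Each is a deliberately naive
# reference implementation (explicit loops / closed forms), kept separate
# from the code paths it checks.

# Direct-summation 2D convolution with reflected boundary.
oracle_conv2 <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  hr <- (kr - 1L) / 2L; hc <- (kc - 1L) / 2L
  k <- max(hr, hc)
  ri <- c(seq(k + 1, 2, by = -1L), seq_len(nrow(m)), seq(nrow(m) - 1L, nrow(m) - k))
  ci <- c(seq(k + 1, 2, by = -1L), seq_len(ncol(m)), seq(ncol(m) - 1L, ncol(m) - k))
  P <- m[ri, ci, drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      s <- 0
      for (u in -hr:hr) {
        for (v in -hc:hc) {
          s <- s + kernel[u + hr + 1L, v + hc + 1L] * P[i + k - u, j + k - v]
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# Explicit per-tile double-loop summation.
oracle_tile_sum <- function(m, w) {
  nt_r <- nrow(m) %/% w
  nt_c <- ncol(m) %/% w
  out <- matrix(0, nt_r, nt_c)
  for (a in seq_len(nt_r)) {
    for (b in seq_len(nt_c)) {
      s <- 0
      for (i in seq_len(w)) {
        for (j in seq_len(w)) {
          s <- s + m[(a - 1L) * w + i, (b - 1L) * w + j]
        }
      }
      out[a, b] <- s
    }
  }
  out
}

# Equivalent-ellipse full major/minor axis lengths from second-order
# central moments of a pixel set.
oracle_ellipse_axes <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  mu <- colMeans(idx)
  C <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx)  # population covariance
  e <- eigen(C, symmetric = TRUE)$values
  list(major = 4 * sqrt(max(e)), minor = 4 * sqrt(min(e)),
       centroid = unname(mu))
}

# Brute-force Benjamini-Hochberg step-up by definition:
# q(i) = min_{j: p(j) >= p(i)} m * p(j) / rank(j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / seq(i, m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Closed-form pooled-variance two-sample t.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Normal-equations OLS with intercept: coefficients, t statistics,
# adjusted R^2 and model F.
oracle_ols <- function(y, X) {
  Xi <- cbind(1, X)
  XtX <- t(Xi) %*% Xi
  beta <- solve(XtX, t(Xi) %*% y)
  res <- y - Xi %*% beta
  n <- length(y); p <- ncol(Xi)
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(solve(XtX)) * s2)
  tstat <- beta / se
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / tss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  F <- (r2 / (p - 1)) / ((1 - r2) / (n - p))
  list(beta = drop(beta), t = drop(tstat), r2 = r2, r2_adj = r2_adj, F = F)
}

# Closed-form DTI scalars for one sorted eigenvalue triple.
oracle_dti_scalars <- function(l) {
  md <- mean(l)
  fa <- sqrt(1.5 * sum((l - md)^2) / sum(l^2))
  list(FA = fa, MD = md, AD = l[1], RD = (l[2] + l[3]) / 2,
       CL = (l[1] - l[2]) / l[1], CP = (l[2] - l[3]) / l[1], CS = l[3] / l[1])
}

# Draw a filled ellipse mask (used to build triage fixtures).
draw_ellipse_mask <- function(nr, nc, cx, cy, a, b, theta = 0) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dy <- rows - cx; dx <- cols - cy
  ((dx * cos(theta) + dy * sin(theta))^2 / a^2 +
     (-dx * sin(theta) + dy * cos(theta))^2 / b^2) <= 1
}

# Gaussian intensity bump field (markers fixtures).
bump_field <- function(nr, nc, centers, heights, sigma = 12) {
  f <- matrix(0, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(nrow(centers))) {
    d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
    f <- pmax(f, heights[i] * exp(-d2 / (2 * sigma^2)))
  }
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a
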