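# Internal helpers shared across modules.

#' @useDynLib histotensor, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Reflect-pad a matrix
#'
#' Pads `m` by `k` pixels on every side, mirroring the image about its
#' border (boundary handling used by all convolutions in the package).
#' @noRd
reflect_pad <- function(m, k) {
  stopifnot(k >= 1, nrow(m) > k, ncol(m) > k)
  ri <- c(seq(k + 1, 2, by = -1L), seq_len(nrow(m)), seq(nrow(m) - 1L, nrow(m) - k))
  ci <- c(seq(k + 1, 2, by = -1L), seq_len(ncol(m)), seq(ncol(m) - 1L, ncol(m) - k))
  m[ri, ci, drop = FALSE]
}

#' 2D convolution with reflected boundary
#'
#' True convolution (kernel flipped) with reflection at the borders.
#' Uses EBImage's FFT filter on a reflect-padded copy so interior values
#' match direct summation.
#' @noRd
conv2_reflect <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  k <- max((kr - 1L) / 2L, (kc - 1L) / 2L)
  padded <- reflect_pad(m, k)
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out <- as.matrix(out)
  out[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m)), drop = FALSE]
}

#' Non-overlapping tile sums
#'
#' Sums `m` over non-overlapping `w x w` tiles; border tiles smaller than
#' the window are dropped.
#' @noRd
tile_sum <- function(m, w) {
  nt_r <- nrow(m) %/% w
  nt_c <- ncol(m) %/% w
  if (nt_r < 1 || nt_c < 1) {
    stop("image (", nrow(m), "x", ncol(m), ") smaller than one ", w, "x", w, " tile")
  }
  mc <- m[seq_len(nt_r * w), seq_len(nt_c * w), drop = FALSE]
  s1 <- colSums(array(mc, c(w, nt_r, nt_c * w)))        # nt_r x (nt_c*w)
  s2 <- colSums(array(t(s1), c(w, nt_c, nt_r)))         # nt_c x nt_r
  t(s2)
}

#' Centred sliding box sums via an integral image
#'
#' Per-pixel sum over a centred `w x w` window, truncated at the image
#' borders (the window is clipped, not padded).
#' @noRd
box_sum <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  P <- matrix(0, nr + 1L, nc + 1L)
  P[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  lo <- (w - 1L) %/% 2L
  hi <- w - 1L - lo
  r1 <- pmax(seq_len(nr) - lo, 1L); r2 <- pmin(seq_len(nr) + hi, nr)
  c1 <- pmax(seq_len(nc) - lo, 1L); c2 <- pmin(seq_len(nc) + hi, nc)
  P[r2 + 1L, c2 + 1L] - P[r1, c2 + 1L] - P[r2 + 1L, c1] + P[r1, c1]
}

#' Label connected foreground components
#'
#' 8-connected labelling: EBImage's 4-connected labelling followed by a
#' union-find merge of labels that touch diagonally.
#' @noRd
label_components <- function(mask, connectivity = 8L) {
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  storage.mode(lab) <- "integer"
  if (connectivity == 4L || max(lab) <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]   # down-right diagonal pairs
  a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]   # down-left diagonal pairs
  pairs <- rbind(
    cbind(a1[a1 > 0L & b1 > 0L & a1 != b1], b1[a1 > 0L & b1 > 0L & a1 != b1]),
    cbind(a2[a2 > 0L & b2 > 0L & a2 != b2], b2[a2 > 0L & b2 > 0L & a2 != b2])
  )
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1L]); rb <- find(pairs[i, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Run an expression with a fixed RNG state
#' @noRd
with_seed <- function(seed, expr) withr::with_seed(as.integer(seed), expr)

#' Derive a per-stage seed from a global seed
#'
#' Named substreams keep stage randomness stable under reordering.
#' @noRd
stage_seed <- function(seed, stage) {
  stages <- c("fibers", "nissl", "dwi", "cohort", "chanvese", "stats", "misc")
  k <- match(stage, stages)
  if (is.na(k)) k <- 7L + (sum(utf8ToInt(stage)) %% 1000L)
  (as.integer(seed) * 37L + k * 1009L) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
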