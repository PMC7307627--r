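# Diffusion-tensor scalar metrics and the log-linear tensor fit.
#
# All scalars derive from the sorted eigenvalues l1 >= l2 >= l3 (mm^2/s)
# of the 3x3 diffusion tensor:
#   MD = (l1 + l2 + l3) / 3         AD = l1        RD = (l2 + l3) / 2
#   FA = sqrt(3/2) * ||l - MD|| / ||l||
# and the Westin shape indices in the l1-normalized convention
#   CL = (l1 - l2)/l1,  CP = (l2 - l3)/l1,  CS = l3/l1   (CL+CP+CS = 1),
# with the sum-normalized variant available behind a switch.

#' DTI scalars from sorted eigenvalues
#'
#' @param evals Numeric vector `c(l1, l2, l3)` with `l1 >= l2 >= l3`, or an
#'   `n x 3` matrix of sorted rows. Negative values (tensor-fit artifacts)
#'   are accepted and flagged.
#' @param westin `"l1"` (default; indices normalized by l1 so that
#'   CL + CP + CS = 1) or `"sum"` (normalized by l1 + l2 + l3).
#' @return A tibble with columns `FA`, `MD`, `AD`, `RD`, `CL`, `CP`, `CS`
#'   and `negative_eigenvalues`.
#' @export
scalars_from_eigenvalues <- function(evals, westin = c("l1", "sum")) {
  westin <- match.arg(westin)
  ev <- if (is.matrix(evals)) evals else matrix(evals, nrow = 1)
  stopifnot(ncol(ev) == 3, all(is.finite(ev)))
  if (any(ev[, 1] < ev[, 2] - 1e-15) || any(ev[, 2] < ev[, 3] - 1e-15)) {
    stop("eigenvalues must be sorted l1 >= l2 >= l3")
  }
  l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
  md <- (l1 + l2 + l3) / 3
  nrm2 <- l1^2 + l2^2 + l3^2
  dev2 <- (l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2
  fa <- ifelse(nrm2 > 0, sqrt(1.5 * dev2 / nrm2), 0)
  if (westin == "l1") {
    den <- l1
    cl <- ifelse(den != 0, (l1 - l2) / den, 0)
    cp <- ifelse(den != 0, (l2 - l3) / den, 0)
    cs <- ifelse(den != 0, l3 / den, 1)
  } else {
    den <- l1 + l2 + l3
    cl <- ifelse(den != 0, (l1 - l2) / den, 0)
    cp <- ifelse(den != 0, 2 * (l2 - l3) / den, 0)
    cs <- ifelse(den != 0, 3 * l3 / den, 1)
  }
  tibble::tibble(FA = fa, MD = md, AD = l1, RD = (l2 + l3) / 2,
                 CL = cl, CP = cp, CS = cs,
                 negative_eigenvalues = l3 < 0)
}

#' Diffusion-weighted acquisition protocol
#'
#' Default geometry: 4 b0 volumes plus 60 directions at b = 2000 s/mm^2,
#' with directions spread quasi-uniformly on the sphere (spherical
#' Fibonacci lattice). `delta` and `Delta` (ms) are metadata only.
#'
#' @param n_dirs Number of diffusion-weighted directions (default 60).
#' @param bval b-value of the weighted volumes, s/mm^2 (default 2000).
#' @param n_b0 Number of b = 0 volumes (default 4).
#' @param bvecs Optional `3 x n` matrix of unit directions overriding the
#'   Fibonacci set (b0 columns may be zero).
#' @param delta,Delta Gradient timing metadata, ms.
#' @return A `dwi_protocol` list with `bvals` (length n) and `bvecs`
#'   (`3 x n`, zero columns for b0).
#' @export
dwi_protocol <- function(n_dirs = 60L, bval = 2000, n_b0 = 4L,
                         bvecs = NULL, delta = 4, Delta = 11) {
  if (is.null(bvecs)) {
    i <- seq_len(n_dirs)
    z <- (2 * i - 1) / n_dirs - 1
    phi <- i * pi * (3 - sqrt(5))
    r <- sqrt(pmax(1 - z^2, 0))
    dirs <- rbind(r * cos(phi), r * sin(phi), z)
  } else {
    dirs <- bvecs
    stopifnot(nrow(dirs) == 3)
    n_dirs <- ncol(dirs)
  }
  nn <- sqrt(colSums(dirs^2))
  dirs <- sweep(dirs, 2, ifelse(nn > 0, nn, 1), "/")
  bvals <- c(rep(0, n_b0), rep(bval, n_dirs))
  bv <- unname(cbind(matrix(0, 3, n_b0), dirs))
  dimnames(bv) <- NULL
  structure(list(bvals = bvals, bvecs = bv, delta = delta, Delta = Delta),
            class = "dwi_protocol")
}

# Design matrix of the log-linear tensor model:
# log S = log S0 - b (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz
#                     + 2 gx gy Dxy + 2 gx gz Dxz + 2 gy gz Dyz)
dti_design <- function(protocol) {
  g <- protocol$bvecs; b <- protocol$bvals
  cbind(1,
        -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
        -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
        -2 * b * g[2, ] * g[3, ])
}

#' Ordinary least-squares diffusion-tensor fit
#'
#' Fits log-signal against the six unique tensor elements plus log S0 and
#' eigen-decomposes the tensor. Non-positive signals are excluded with a
#' warning. Negative fitted eigenvalues are kept (flagged, not clamped).
#'
#' @param signals Numeric vector of measurements, one per protocol volume.
#' @param protocol A [dwi_protocol].
#' @return List with sorted `evals` (l1 >= l2 >= l3), `evecs` (columns
#'   matching `evals`), `S0`, the tensor matrix `D`, `n_used` and
#'   `negative_eigenvalues`.
#' @export
fit_tensor <- function(signals, protocol) {
  stopifnot(length(signals) == length(protocol$bvals))
  ok <- signals > 0
  if (!all(ok)) {
    warning(sum(!ok), " non-positive signal(s) excluded from the tensor fit")
  }
  if (sum(ok) < 7) stop("need >= 7 positive measurements (6 directions + b0)")
  X <- dti_design(protocol)[ok, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < 7) stop("rank-deficient design: directions do not span the tensor space")
  beta <- qr.coef(qrX, log(signals[ok]))
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  e <- eigen(D, symmetric = TRUE)   # values in decreasing order
  list(evals = e$values, evecs = e$vectors, S0 = exp(beta[1]), D = D,
       n_used = sum(ok), negative_eigenvalues = any(e$values < 0))
}

#' ROI mean of a scalar map
#'
#' Mean of the map over the mask voxels; NaN/NA voxels are excluded and
#' counted.
#'
#' @param map Numeric array (any dimensionality).
#' @param mask Logical array of the same shape.
#' @return List with `mean`, `n_voxels` (finite voxels used) and
#'   `n_excluded`.
#' @export
roi_scalar_summary <- function(map, mask) {
  if (!identical(dim(map), dim(mask))) stop("map and mask grids differ")
  v <- map[mask > 0]
  if (length(v) == 0) stop("empty ROI mask")
  bad <- !is.finite(v)
  list(mean = mean(v[!bad]), n_voxels = sum(!bad), n_excluded = sum(bad))
}

#' Read / write FSL-style b-vectors and b-values
#'
#' `bvecs` is a 3 x N whitespace table, `bvals` a single row.
#' @param path File path.
#' @return `read_bvecs`: a 3 x N matrix; `read_bvals`: a numeric vector.
#' @export
read_bvecs <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (nrow(m) != 3 && ncol(m) == 3) m <- t(m)
  stopifnot(nrow(m) == 3)
  unname(m)
}

#' @rdname read_bvecs
#' @export
read_bvals <- function(path) as.numeric(unlist(utils::read.table(path)))

#' @rdname read_bvecs
#' @param bvecs 3 x N matrix; `bvals` numeric vector.
#' @param bvals Numeric vector.
#' @export
write_bvecs <- function(bvecs, path) {
  utils::write.table(format(bvecs, digits = 17), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_bvecs
#' @export
write_bvals <- function(bvals, path) {
  utils::write.table(t(bvals), path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Compute DTI scalar maps from an eigenvalue volume
#'
#' Convenience wrapper for NIfTI eigenvalue volumes: the last array
#' dimension must hold the three sorted eigenvalues.
#'
#' @param evals_path Path to a NIfTI volume with eigenvalues stacked on
#'   the last dimension.
#' @param out_dir Output directory for `FA/MD/AD/RD/CL/CP/CS.nii.gz`.
#' @param westin Westin convention, see [scalars_from_eigenvalues()].
#' @return Named list of output paths, invisibly.
#' @export
dti_scalar_maps <- function(evals_path, out_dir, westin = "l1") {
  vol <- RNifti::readNifti(evals_path)
  d <- dim(vol)
  stopifnot(d[length(d)] == 3)
  flat <- matrix(vol, ncol = 3)
  flat <- t(apply(flat, 1, sort, decreasing = TRUE))
  sc <- scalars_from_eigenvalues(flat, westin = westin)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- d[-length(d)]
  paths <- list()
  for (nm in c("FA", "MD", "AD", "RD", "CL", "CP", "CS")) {
    arr <- array(sc[[nm]], dim = sp)
    p <- file.path(out_dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(arr), p)
    paths[[nm]] <- p
  }
  invisible(paths)
}
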