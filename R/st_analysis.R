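# Structure-tensor (ST) analysis of myelin-stained sections.
#
# The local orientation statistics of a stained section are summarized by
# the 2x2 structure tensor J = sum_w [Ix^2, IxIy; IxIy, Iy^2], where Ix and
# Iy are Gaussian-derivative images and the sum runs over a 128x128-pixel
# window. The eigenvalues l1 >= l2 >= 0 of J give the anisotropy index
# AI = (l1 - l2) / (l1 + l2): 0 for isotropic texture, 1 for perfectly
# coherent fibers. Orientation is reported as the fiber direction (the
# eigenvector of l2, i.e. the direction of least intensity change), in
# radians in [0, pi) measured from the image x (column) axis.

#' Structure-tensor configuration
#'
#' @param deriv_kernel_size Odd Gaussian-derivative kernel size in pixels
#'   (default 11).
#' @param deriv_sigma Gaussian sigma in pixels (default 3).
#' @param window Aggregation window in pixels (default 128).
#' @param aggregation `"tiled"` (non-overlapping windows; default) or
#'   `"sliding"` (per-pixel box sum).
#' @return An `st_config` list.
#' @export
st_config <- function(deriv_kernel_size = 11L, deriv_sigma = 3,
                      window = 128L, aggregation = c("tiled", "sliding")) {
  aggregation <- match.arg(aggregation)
  deriv_kernel_size <- as.integer(deriv_kernel_size)
  if (deriv_kernel_size < 3L || deriv_kernel_size %% 2L == 0L) {
    stop("deriv_kernel_size must be odd and >= 3")
  }
  deriv_sigma <- as.numeric(deriv_sigma)
  if (deriv_sigma <= 0) stop("deriv_sigma must be > 0")
  window <- as.integer(window)
  if (window < deriv_kernel_size) stop("window must be >= kernel size")
  structure(list(deriv_kernel_size = deriv_kernel_size,
                 deriv_sigma = deriv_sigma,
                 window = window,
                 aggregation = aggregation),
            class = "st_config")
}

#' Analytic Gaussian-derivative kernels
#'
#' Returns the x- and y-derivative-of-Gaussian kernels on a
#' `size x size` grid. The Gaussian is normalized to unit sum so the
#' filters are gradient-calibrated: convolving a linear ramp of unit slope
#' yields a response of (approximately) 1.
#'
#' x is the column axis, y the row axis; the y kernel is the transpose of
#' the x kernel.
#'
#' @param size Odd kernel size in pixels.
#' @param sigma Gaussian sigma in pixels.
#' @return List with matrices `kx`, `ky`.
#' @export
gaussian_derivative_kernels <- function(size = 11L, sigma = 3) {
  h <- (size - 1) / 2
  u <- seq(-h, h)
  g <- exp(-u^2 / (2 * sigma^2))
  G <- outer(g, g)          # rows = y offsets, cols = x offsets
  G <- G / sum(G)
  X <- matrix(u, size, size, byrow = TRUE)   # x (column) offset
  Y <- matrix(u, size, size)                 # y (row) offset
  kx <- -X / sigma^2 * G
  # first-moment calibration: truncation shrinks the ramp response below
  # 1; rescale so a unit-slope ramp yields exactly 1
  kx <- kx / sum(-X * kx)
  list(kx = kx, ky = t(kx))
}

#' Gaussian-derivative images
#'
#' Convolves a grayscale image with the directional derivatives of a 2D
#' Gaussian (reflected boundary), producing the derivative fields from
#' which structure tensors are formed.
#'
#' @param img A [histo_image] (RGB is converted to luminance) or a matrix.
#' @param cfg An [st_config].
#' @return List with matrices `Ix` (column direction) and `Iy`
#'   (row direction), the same size as the image.
#' @export
gaussian_derivatives <- function(img, cfg = st_config()) {
  m <- if (inherits(img, "histo_image")) as_gray(img) else img
  stopifnot(is.matrix(m))
  if (min(dim(m)) < cfg$deriv_kernel_size) {
    stop("image (", nrow(m), "x", ncol(m), ") smaller than the ",
         cfg$deriv_kernel_size, "-pixel derivative kernel")
  }
  k <- gaussian_derivative_kernels(cfg$deriv_kernel_size, cfg$deriv_sigma)
  list(Ix = conv2_reflect(m, k$kx), Iy = conv2_reflect(m, k$ky))
}

#' Structure-tensor field
#'
#' Forms the pixelwise tensor `[Ix^2, IxIy; IxIy, Iy^2]` and aggregates it
#' over the configured window: `tiled` sums over non-overlapping
#' `window x window` tiles (border remainders dropped), `sliding` box-sums
#' per pixel. Each aggregated tensor is eigen-decomposed in closed form.
#'
#' @param Ix,Iy Derivative fields from [gaussian_derivatives()].
#' @param cfg An [st_config].
#' @return An `st_field` list with matrices `Jxx`, `Jxy`, `Jyy`, `l1`,
#'   `l2`, `orientation` (fiber direction, radians in `[0, pi)`) and
#'   `ai_map`, plus the aggregation metadata.
#' @export
structure_tensor_field <- function(Ix, Iy, cfg = st_config()) {
  if (!identical(dim(Ix), dim(Iy))) stop("Ix and Iy must have the same shape")
  w <- cfg$window
  if (cfg$aggregation == "tiled") {
    Jxx <- tile_sum(Ix * Ix, w)
    Jxy <- tile_sum(Ix * Iy, w)
    Jyy <- tile_sum(Iy * Iy, w)
  } else {
    Jxx <- box_sum(Ix * Ix, w)
    Jxy <- box_sum(Ix * Iy, w)
    Jyy <- box_sum(Iy * Iy, w)
  }
  eig <- st_eigen(Jxx, Jxy, Jyy)
  structure(list(Jxx = Jxx, Jxy = Jxy, Jyy = Jyy,
                 l1 = eig$l1, l2 = eig$l2,
                 orientation = eig$orientation,
                 ai_map = anisotropy_index(eig$l1, eig$l2),
                 aggregation = cfg$aggregation, window = w),
            class = "st_field")
}

# Closed-form eigen-decomposition of symmetric 2x2 tensor fields.
# Orientation is the fiber direction: the minor eigenvector, perpendicular
# to the dominant gradient direction.
st_eigen <- function(Jxx, Jxy, Jyy) {
  tr <- Jxx + Jyy
  disc <- sqrt(((Jxx - Jyy) / 2)^2 + Jxy^2)
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  l2[l2 < 0 & l2 > -1e-12 * pmax(l1, 1)] <- 0  # clamp roundoff
  grad_dir <- 0.5 * atan2(2 * Jxy, Jxx - Jyy)  # major eigenvector angle
  orientation <- (grad_dir + pi / 2) %% pi
  list(l1 = l1, l2 = l2, orientation = orientation)
}

#' Anisotropy index from structure-tensor eigenvalues
#'
#' `AI = (l1 - l2) / (l1 + l2)`, defined as 0 where the tensor is zero
#' (flat, gradient-free texture).
#'
#' @param l1,l2 Eigenvalue arrays with `l1 >= l2 >= 0`.
#' @return AI values in `[0, 1]`, same shape as the input.
#' @export
anisotropy_index <- function(l1, l2) {
  if (any(l2 < -1e-9 * pmax(abs(l1), 1))) stop("eigenvalues must be non-negative")
  if (any(l1 - l2 < -1e-9 * pmax(abs(l1), 1))) stop("l1 must be >= l2")
  s <- l1 + l2
  ai <- (l1 - l2) / ifelse(s > 0, s, 1)
  ai[s <= 0] <- 0
  ai
}

#' ROI summary of a structure-tensor field
#'
#' Sums the aggregated tensors of all locations covered by the mask and
#' reports the AI of the summed tensor (`ai_tensor`), together with the
#' mean of the per-location AI values (`ai_mean`) as an alternative
#' summary. The two differ when the ROI mixes orientations: orthogonal
#' coherent tiles cancel in the tensor sum but not in the mean.
#'
#' @param field An `st_field`.
#' @param mask Logical matrix, either on the aggregated grid (tile grid for
#'   tiled fields) or on the full image grid; image-grid masks cover a tile
#'   when at least half of the tile's pixels are inside the mask.
#' @return List with `ai_tensor`, `ai_mean`, `orientation` (of the summed
#'   tensor) and `n_locations`.
#' @export
roi_ai <- function(field, mask) {
  stopifnot(inherits(field, "st_field"))
  mask <- mask > 0
  if (identical(dim(mask), dim(field$Jxx))) {
    sel <- mask
  } else if (field$aggregation == "tiled") {
    w <- field$window
    cover <- tile_sum(mask * 1, w) / w^2
    if (!identical(dim(cover), dim(field$Jxx))) {
      stop("mask shape matches neither the tile grid nor the image grid")
    }
    sel <- cover >= 0.5
  } else {
    stop("mask shape does not match the field grid")
  }
  if (!any(sel)) stop("empty ROI: mask covers no aggregated tensor location")
  Jxx <- sum(field$Jxx[sel]); Jxy <- sum(field$Jxy[sel]); Jyy <- sum(field$Jyy[sel])
  eig <- st_eigen(Jxx, Jxy, Jyy)
  list(ai_tensor = as.numeric(anisotropy_index(eig$l1, eig$l2)),
       ai_mean = mean(field$ai_map[sel]),
       orientation = as.numeric(eig$orientation),
       n_locations = sum(sel))
}

#' Structure-tensor analysis of one photomicrograph
#'
#' End-to-end ST stage: Gaussian derivatives, windowed tensor aggregation,
#' eigen-decomposition and AI, with an optional ROI summary.
#'
#' @param img A [histo_image].
#' @param cfg An [st_config].
#' @param roi Optional logical ROI mask (see [roi_ai()]).
#' @return List with the `st_field`, a tidy per-location `tiles` tibble
#'   (row, col, Jxx, Jxy, Jyy, l1, l2, orientation, ai) and, when `roi` is
#'   given, the `roi` summary.
#' @export
st_analyze <- function(img, cfg = st_config(), roi = NULL) {
  d <- gaussian_derivatives(img, cfg)
  field <- structure_tensor_field(d$Ix, d$Iy, cfg)
  idx <- which(!is.na(field$ai_map), arr.ind = TRUE)
  tiles <- tibble::tibble(
    row = idx[, 1], col = idx[, 2],
    Jxx = field$Jxx[idx], Jxy = field$Jxy[idx], Jyy = field$Jyy[idx],
    l1 = field$l1[idx], l2 = field$l2[idx],
    orientation = field$orientation[idx], ai = field$ai_map[idx]
  )
  out <- list(field = field, tiles = tiles)
  if (!is.null(roi)) out$roi <- roi_ai(field, roi)
  out
}
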