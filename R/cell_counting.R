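# Automated cell counting on Nissl-stained sections.
#
# Pipeline: (1) preliminary foreground segmentation with Chan-Vese active
# contours evolved on the speed image (gradient magnitude of the green
# channel); (2) ellipse-fit triage of the connected components -- major
# axis < S -> noise, > B -> under-segmented, in [S, B] -> accepted;
# (3) for under-segmented components, markers from the regional maxima of
# the H-maxima transform of the Gaussian-filtered (inverted) HSV value
# image, filtered by the intensity threshold I and the pairwise spatial
# (D_s) and intensity (D_i) separation rules; (4) marker-based watershed
# to split each under-segmented component. Cell density is rho = N / A.

#' Cell-counting configuration
#'
#' Thresholds are in pixels on the acquisition grid and intensities on the
#' `[0, 1]` scale. `D_i` is expressed in 8-bit-equivalent units and is
#' multiplied by `d_i_scale` (default 1/255) before comparison against
#' `[0, 1]` intensities.
#'
#' @param cv_smooth Chan-Vese smoothing weight (default 0.2).
#' @param cv_max_iter Maximum Chan-Vese iterations (default 300).
#' @param cv_tol Convergence tolerance: stop when the fraction of pixels
#'   changing phase in one iteration is at most this (default 0: run to a
#'   fixed point of the contour evolution, within the iteration budget).
#' @param S Noise threshold on the ellipse major axis, pixels (default 30).
#' @param B Under-segmentation threshold on the major axis, pixels
#'   (default 140).
#' @param I Marker intensity threshold in `[0, 1]` (default 0.5).
#' @param D_s Minimum marker spatial separation, pixels (default 70).
#' @param D_i Minimum marker intensity separation in 8-bit-equivalent
#'   units (default 1).
#' @param d_i_scale Scale mapping `D_i` onto `[0, 1]` (default 1/255).
#' @param h H-maxima depth (default 0.1).
#' @param marker_sigma Gaussian sigma of the marker pre-filter, pixels
#'   (default 3).
#' @param min_gradient Minimum raw gradient magnitude (intensity units
#'   per pixel) for an image to be considered to contain stained
#'   structure; below it the segmentation is empty (default 0.05).
#' @param speckle_min_area Foreground speckles smaller than this many
#'   pixels are removed before the closing step (default 100; well below
#'   the area of any component passing the S threshold).
#' @param init Chan-Vese initialization: `"random"` binary mask (default)
#'   or deterministic `"checkerboard"`.
#' @param rng_seed Seed for the random initialization (default 1).
#' @return A `cell_count_config` list.
#' @export
cell_count_config <- function(cv_smooth = 0.2, cv_max_iter = 300L,
                              cv_tol = 0,
                              S = 30, B = 140, I = 0.5,
                              D_s = 70, D_i = 1, d_i_scale = 1 / 255,
                              h = 0.1, marker_sigma = 3,
                              min_gradient = 0.05,
                              speckle_min_area = 100L,
                              init = c("random", "checkerboard"),
                              rng_seed = 1L) {
  init <- match.arg(init)
  for (nm in c("cv_smooth", "cv_tol", "S", "B", "I", "D_s", "D_i",
               "d_i_scale", "h", "marker_sigma", "min_gradient")) {
    assign(nm, as.numeric(get(nm)))
  }
  if (!(S > 0 && B > S)) stop("need 0 < S < B")
  if (cv_smooth < 0) stop("cv_smooth must be >= 0")
  if (I < 0 || I > 1) stop("I must lie in [0, 1]")
  if (D_s <= 0) stop("D_s must be > 0")
  if (h <= 0) stop("h must be > 0")
  structure(list(cv_smooth = cv_smooth, cv_max_iter = as.integer(cv_max_iter),
                 cv_tol = cv_tol, S = S, B = B, I = I,
                 D_s = D_s, D_i = D_i, d_i_scale = d_i_scale,
                 h = h, marker_sigma = marker_sigma,
                 min_gradient = min_gradient,
                 speckle_min_area = as.integer(speckle_min_area),
                 init = init, rng_seed = as.integer(rng_seed)),
            class = "cell_count_config")
}

#' Speed image: green-channel gradient magnitude
#'
#' Sobel gradient magnitude of the green channel (cell membranes are
#' sharpest there), rescaled to `[0, 1]`. This is the field the Chan-Vese
#' contour evolves on.
#'
#' @param img An RGB [histo_image].
#' @param channel Channel to use; grayscale input requires an explicit
#'   `channel = "gray"` override.
#' @return A matrix in `[0, 1]`.
#' @export
speed_image <- function(img, channel = c("green", "red", "blue", "gray")) {
  channel <- match.arg(channel)
  if (!is_rgb(img)) {
    if (channel != "gray") {
      stop("grayscale input: pass channel = \"gray\" explicitly")
    }
    g <- img$pixels
  } else {
    g <- switch(channel,
                red = img$pixels[, , 1], green = img$pixels[, , 2],
                blue = img$pixels[, , 3], gray = as_gray(img))
  }
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dx (columns)
  gx <- conv2_reflect(g, sx)
  gy <- conv2_reflect(g, t(sx))
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  out <- if (mx > 1e-9) mag / mx else mag * 0   # flat channel: no edges
  attr(out, "raw_max") <- mx
  out
}

#' Chan-Vese segmentation of a scalar field
#'
#' Two-phase piecewise-constant active-contour (Chan-Vese) segmentation,
#' minimized with a threshold-dynamics scheme: each iteration recomputes
#' the two region means, diffuses the current region indicator with a
#' small Gaussian, and rethresholds it against the data term, with the
#' smoothing weight `mu` scaling the diffusion-threshold length
#' regularizer. The indicator is initialized with a seeded random binary
#' mask; iteration stops at a fixed point (no pixel changes phase) or
#' after `max_iter` iterations. The foreground is the phase with the
#' higher field mean.
#'
#' @param m Numeric matrix in `[0, 1]`.
#' @param mu Smoothing weight.
#' @param max_iter Iteration budget.
#' @param tol Stop when the fraction of pixels changing phase in one
#'   iteration is at most this (default 0: run to a fixed point).
#' @param init `"random"` or `"checkerboard"`.
#' @param seed RNG seed for the random initialization.
#' @param sigma Gaussian diffusion scale of the contour regularizer,
#'   pixels (default 2).
#' @return List with logical `foreground` and `iterations`.
#' @export
chan_vese <- function(m, mu = 0.2, max_iter = 300L, tol = 0,
                      init = c("random", "checkerboard"), seed = 1L,
                      sigma = 2) {
  init <- match.arg(init)
  stopifnot(is.matrix(m))
  u <- if (init == "random") {
    with_seed(seed, matrix(sample(c(TRUE, FALSE), length(m), replace = TRUE),
                           nrow(m), ncol(m)))
  } else {
    (outer(seq_len(nrow(m)), seq_len(ncol(m)),
           function(i, j) sin(pi * i / 5) * sin(pi * j / 5))) > 0
  }
  K <- gaussian_kernel_2d(sigma)
  it <- 0L
  repeat {
    it <- it + 1L
    n1 <- sum(u)
    if (n1 == 0L || n1 == length(u)) break   # one phase vanished
    c1 <- mean(m[u]); c2 <- mean(m[!u])
    # before phases exist the regularizer only echoes the init pattern;
    # the first sweep is a pure data-term threshold
    v <- if (it == 1L) 0.5 else conv2_reflect(u * 1, K)
    un <- ((m - c2)^2 - (m - c1)^2 + mu * (v - 0.5)) > 0
    changed <- sum(un != u)
    u <- un
    if (changed <= tol * length(u) || it >= max_iter) break
  }
  n1 <- sum(u)
  c1 <- if (n1 > 0) mean(m[u]) else -Inf
  c2 <- if (n1 < length(u)) mean(m[!u]) else -Inf
  fg <- if (c1 >= c2) u else !u
  list(foreground = fg, iterations = it)
}

#' Preliminary segmentation of a Nissl image
#'
#' Chan-Vese on the speed image, removal of speckle components smaller
#' than `speckle_min_area`, a small morphological closing (the level-set
#' boundary is ragged at the pixel scale and the detected cell outlines
#' must close before hole filling), hole filling, and 8-connected
#' component labelling.
#'
#' @param img An RGB [histo_image].
#' @param cfg A [cell_count_config].
#' @return Integer label matrix (0 = background).
#' @export
preliminary_segmentation <- function(img, cfg = cell_count_config()) {
  sp <- speed_image(img)
  if ((attr(sp, "raw_max") %||% Inf) < cfg$min_gradient) {
    warning("no image contrast: maximum gradient below min_gradient; ",
            "empty segmentation")
    return(matrix(0L, nrow(sp), ncol(sp)))
  }
  cv <- chan_vese(sp, mu = cfg$cv_smooth, max_iter = cfg$cv_max_iter,
                  tol = cfg$cv_tol, init = cfg$init, seed = cfg$rng_seed)
  fg <- cv$foreground
  if (all(fg) || !any(fg)) {
    warning("Chan-Vese produced an all-foreground or all-background result")
    return(matrix(0L, nrow(fg), ncol(fg)))
  }
  lab0 <- label_components(fg, connectivity = 8L)
  sizes <- tabulate(lab0[lab0 > 0L], nbins = max(lab0))
  fg[lab0 > 0L & sizes[pmax(lab0, 1L)] < cfg$speckle_min_area] <- FALSE
  closed <- as.matrix(EBImage::closing(fg * 1, EBImage::makeBrush(5, "disc"))) > 0
  filled <- as.matrix(EBImage::fillHull(closed * 1)) > 0
  label_components(filled, connectivity = 8L)
}

#' Ellipse-fit triage of preliminary components
#'
#' Fits the second-order-moment equivalent ellipse to every component and
#' classifies it: major axis < `S` -> `noise`, > `B` -> `under_segmented`,
#' otherwise `accepted`.
#'
#' @param labels Integer label matrix.
#' @param cfg A [cell_count_config].
#' @return Tibble with one row per component: `id`, `area`, `cx`, `cy`
#'   (centroid, matrix row/col coordinates), `major`, `minor`, `theta`,
#'   `status`.
#' @export
triage_components <- function(labels, cfg = cell_count_config()) {
  n <- max(labels)
  if (n == 0) {
    return(tibble::tibble(id = integer(), area = integer(),
                          cx = numeric(), cy = numeric(),
                          major = numeric(), minor = numeric(),
                          theta = numeric(), status = character()))
  }
  feats <- EBImage::computeFeatures.moment(labels)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  area <- tabulate(lab, nbins = n)
  cx <- as.numeric(tapply(idx[, 1], lab, mean))  # row coordinate
  cy <- as.numeric(tapply(idx[, 2], lab, mean))  # col coordinate
  major <- as.numeric(feats[, "m.majoraxis"])
  minor <- major * sqrt(1 - pmin(as.numeric(feats[, "m.eccentricity"]), 1)^2)
  status <- ifelse(major < cfg$S, "noise",
                   ifelse(major > cfg$B, "under_segmented", "accepted"))
  tibble::tibble(id = seq_len(n), area = area, cx = cx, cy = cy,
                 major = as.numeric(major), minor = as.numeric(minor),
                 theta = as.numeric(feats[, "m.theta"]), status = status)
}

#' Marker intensity image
#'
#' HSV value channel of the RGB image, Gaussian-filtered with
#' `marker_sigma` and inverted so that (dark) cell bodies become maxima.
#' The result stays on the absolute `[0, 1]` scale -- no contrast stretch
#' -- because the marker thresholds `I` and `D_i` are absolute.
#'
#' @param img An RGB [histo_image].
#' @param cfg A [cell_count_config].
#' @return Matrix in `[0, 1]`.
#' @export
marker_intensity_image <- function(img, cfg = cell_count_config()) {
  v <- hsv_value(img)
  sz <- 2L * ceiling(3 * cfg$marker_sigma) + 1L
  u <- seq(-(sz - 1) / 2, (sz - 1) / 2)
  g1 <- exp(-u^2 / (2 * cfg$marker_sigma^2))
  K <- outer(g1, g1); K <- K / sum(K)
  f <- conv2_reflect(v, K)
  pmin(pmax(1 - f, 0), 1)
}

# H-maxima transform: grayscale reconstruction of (f - h) under f.
hmaxima <- function(f, h) .grayrec_dilate(f - h, f)

#' Extract watershed markers for an under-segmented component
#'
#' Markers are the regional maxima of the H-maxima transform (depth `h`)
#' of the filtered intensity image, restricted to the component domain,
#' then filtered by the three marker conditions: (1) marker intensity
#' must exceed `I`; (2) the distance between two markers must exceed
#' `D_s`; (3) the intensity difference between two markers must exceed
#' `D_i` (on the `d_i_scale`). Pairs violating (2) or (3) keep the
#' brighter marker; processing order is deterministic (decreasing
#' intensity, then row, then column).
#'
#' @param intensity Matrix from [marker_intensity_image()].
#' @param comp_mask Logical matrix of the component domain.
#' @param cfg A [cell_count_config].
#' @return Tibble of surviving markers: `row`, `col`, `intensity`.
#' @export
extract_markers <- function(intensity, comp_mask, cfg = cell_count_config()) {
  stopifnot(identical(dim(intensity), dim(comp_mask)))
  idx <- which(comp_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty component domain")
  r0 <- max(min(idx[, 1]) - 2L, 1L); r1 <- min(max(idx[, 1]) + 2L, nrow(intensity))
  c0 <- max(min(idx[, 2]) - 2L, 1L); c1 <- min(max(idx[, 2]) + 2L, ncol(intensity))
  f <- intensity[r0:r1, c0:c1]
  dom <- comp_mask[r0:r1, c0:c1]
  f[!dom] <- 0                     # outside-domain floor
  rec <- hmaxima(f, cfg$h)
  dil <- as.matrix(EBImage::dilate(rec, EBImage::makeBrush(3, "box")))
  cand <- dom & (rec >= dil - 1e-12)
  if (!any(cand)) return(empty_markers())
  plat <- label_components(cand, connectivity = 8L)
  pk <- which(plat > 0, arr.ind = TRUE)
  pl <- plat[plat > 0]
  markers <- do.call(rbind, lapply(seq_len(max(plat)), function(k) {
    px <- pk[pl == k, , drop = FALSE]
    ctr <- colMeans(px)
    d2 <- (px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2
    px[which.min(d2), ]
  }))
  mi <- f[cbind(markers[, 1], markers[, 2])]
  m <- tibble::tibble(row = markers[, 1] + r0 - 1L,
                      col = markers[, 2] + c0 - 1L,
                      intensity = mi)
  # condition (1): absolute intensity
  m <- m[m$intensity > cfg$I, , drop = FALSE]
  if (nrow(m) == 0) return(empty_markers())
  # conditions (2)-(3): greedy pairwise suppression, brighter marker wins
  m <- m[order(-m$intensity, m$row, m$col), , drop = FALSE]
  d_i <- cfg$D_i * cfg$d_i_scale
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    ok <- TRUE
    for (j in which(keep)) {
      dist <- sqrt((m$row[i] - m$row[j])^2 + (m$col[i] - m$col[j])^2)
      if (dist <= cfg$D_s || abs(m$intensity[i] - m$intensity[j]) <= d_i) {
        ok <- FALSE; break
      }
    }
    keep[i] <- ok
  }
  m[keep, , drop = FALSE]
}

empty_markers <- function() {
  tibble::tibble(row = integer(), col = integer(), intensity = numeric())
}

#' Marker-based watershed correction of one component
#'
#' Splits the component domain into one region per marker by seeded
#' region growing on the (inverted) intensity landscape.
#'
#' @param comp_mask Logical component domain.
#' @param markers Marker tibble from [extract_markers()]; every marker
#'   must lie inside the domain.
#' @param intensity Matrix from [marker_intensity_image()].
#' @return Integer matrix of sub-labels `1..nrow(markers)` partitioning
#'   the component (0 outside).
#' @export
watershed_correct <- function(comp_mask, markers, intensity) {
  stopifnot(nrow(markers) >= 1)
  inside <- comp_mask[cbind(markers$row, markers$col)]
  if (!all(inside)) stop("marker outside the component domain")
  if (nrow(markers) == 1) return(comp_mask * 1L)
  seeds <- matrix(0L, nrow(comp_mask), ncol(comp_mask))
  seeds[cbind(markers$row, markers$col)] <- seq_len(nrow(markers))
  lab <- EBImage::propagate(1 - intensity, seeds, mask = comp_mask)
  out <- as.matrix(lab)
  storage.mode(out) <- "integer"
  out
}

#' Count cells in a Nissl image
#'
#' Runs the full counting pipeline and returns a segmentation result:
#' preliminary and final label images, the per-component triage table
#' (with the number of watershed sub-labels for corrected components) and
#' the cell count. Under-segmented components with fewer than two
#' surviving markers are kept as a single cell.
#'
#' @param img An RGB [histo_image].
#' @param cfg A [cell_count_config].
#' @param roi_mask Optional logical ROI mask; cells are counted by
#'   centroid inclusion.
#' @return A `segmentation_result` list with `preliminary`, `final`,
#'   `components`, `cells` (tibble of per-cell centroids) and `N`.
#' @export
count_cells <- function(img, cfg = cell_count_config(), roi_mask = NULL) {
  labels <- preliminary_segmentation(img, cfg)
  comps <- triage_components(labels, cfg)
  final <- matrix(0L, nrow(labels), ncol(labels))
  cells <- list()
  next_id <- 0L
  n_sub <- integer(nrow(comps))
  if (nrow(comps) > 0) {
    intens <- marker_intensity_image(img, cfg)
    for (i in seq_len(nrow(comps))) {
      if (comps$status[i] == "noise") next
      comp_mask <- labels == comps$id[i]
      if (comps$status[i] == "accepted") {
        next_id <- next_id + 1L
        final[comp_mask] <- next_id
        n_sub[i] <- 1L
        cells[[length(cells) + 1L]] <-
          data.frame(cell = next_id, component = comps$id[i],
                     cx = comps$cx[i], cy = comps$cy[i])
        next
      }
      mk <- extract_markers(intens, comp_mask, cfg)
      if (nrow(mk) < 2) {
        # zero or one marker: keep as a single cell
        next_id <- next_id + 1L
        final[comp_mask] <- next_id
        n_sub[i] <- 1L
        cells[[length(cells) + 1L]] <-
          data.frame(cell = next_id, component = comps$id[i],
                     cx = comps$cx[i], cy = comps$cy[i])
      } else {
        sub <- watershed_correct(comp_mask, mk, intens)
        n_sub[i] <- nrow(mk)
        for (s in seq_len(nrow(mk))) {
          px <- which(sub == s, arr.ind = TRUE)
          next_id <- next_id + 1L
          final[sub == s] <- next_id
          cells[[length(cells) + 1L]] <-
            data.frame(cell = next_id, component = comps$id[i],
                       cx = mean(px[, 1]), cy = mean(px[, 2]))
        }
      }
    }
  }
  cells <- if (length(cells)) tibble::as_tibble(do.call(rbind, cells)) else
    tibble::tibble(cell = integer(), component = integer(),
                   cx = numeric(), cy = numeric())
  comps$n_sublabels <- n_sub
  if (!is.null(roi_mask)) {
    inroi <- roi_mask[cbind(pmin(pmax(round(cells$cx), 1), nrow(final)),
                            pmin(pmax(round(cells$cy), 1), ncol(final)))]
    cells <- cells[inroi, , drop = FALSE]
  }
  structure(list(preliminary = labels, final = final, components = comps,
                 cells = cells, N = nrow(cells),
                 config = cfg),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> N = %d cells (%d accepted, %d corrected, %d noise components)\n",
              x$N, sum(x$components$status == "accepted"),
              sum(x$components$status == "under_segmented"),
              sum(x$components$status == "noise")))
  invisible(x)
}

#' Cell count and density in an ROI
#'
#' `rho = N / A`: `N` cells with centroid inside the ROI, `A` the ROI area
#' in um^2 (mask pixel count times the pixel area).
#'
#' @param img An RGB [histo_image].
#' @param roi_mask Optional logical ROI mask (default: whole image).
#' @param cfg A [cell_count_config].
#' @return A `cell_density` list: `N`, `A_um2`, `rho` (cells/um^2),
#'   `rho_x1e2` (the x 1e-2 cells/um^2 reporting scale) and the
#'   `segmentation`.
#' @export
count_and_density <- function(img, roi_mask = NULL, cfg = cell_count_config()) {
  if (is.null(roi_mask)) {
    roi_mask <- matrix(TRUE, dim(img$pixels)[1], dim(img$pixels)[2])
  }
  if (!any(roi_mask)) stop("empty ROI mask")
  seg <- count_cells(img, cfg, roi_mask = roi_mask)
  A <- sum(roi_mask) * img$pixel_area
  structure(list(N = seg$N, A_um2 = A, rho = seg$N / A,
                 rho_x1e2 = 100 * seg$N / A, segmentation = seg),
            class = "cell_density")
}

#' @export
print.cell_density <- function(x, ...) {
  cat(sprintf("<cell_density> N = %d cells, A = %.1f um^2, rho = %.3f x 1e-2 cells/um^2\n",
              x$N, x$A_um2, x$rho_x1e2))
  invisible(x)
}
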