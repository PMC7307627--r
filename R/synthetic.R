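# Synthetic fixtures: oriented fiber textures for the ST stage, Nissl-like
# cell images with ground truth for the counting stage, diffusion-weighted
# signals for the tensor fit, and sham/mTBI ROI cohorts on the scale of
# the study's histology table. All generators are deterministic given
# (spec, seed).

#' Fiber image specification
#'
#' @param size Image side in pixels (>= 256 so tiled ST analysis has
#'   tiles; default 512).
#' @param orientation Fiber orientation in radians in `[0, pi)`, measured
#'   from the x (column) axis (default pi/6).
#' @param coherence Fraction of texture energy aligned with the fiber
#'   direction, in `[0, 1]` (default 0.8).
#' @param fiber_width Across-fiber correlation length in pixels
#'   (default 4).
#' @param noise_sd Additive white-noise SD (default 0.01).
#' @param contrast Texture amplitude around mid-gray (default 0.18).
#' @param seed RNG seed.
#' @return A `fiber_image_spec` list.
#' @export
fiber_image_spec <- function(size = 512L, orientation = pi / 6,
                             coherence = 0.8, fiber_width = 4,
                             noise_sd = 0.01, contrast = 0.18, seed = 1L) {
  stopifnot(coherence >= 0, coherence <= 1, size >= 64)
  for (nm in c("orientation", "coherence", "fiber_width", "noise_sd", "contrast")) {
    assign(nm, as.numeric(get(nm)))
  }
  structure(list(size = as.integer(size), orientation = orientation %% pi,
                 coherence = coherence, fiber_width = fiber_width,
                 noise_sd = noise_sd, contrast = contrast,
                 seed = as.integer(seed)),
            class = "fiber_image_spec")
}

#' Generate an oriented fiber texture
#'
#' The image is a coherence-weighted mixture of an aligned texture
#' (a smooth 1D profile constant along the fiber direction, so all its
#' gradient energy is perpendicular to the fibers) and an isotropic
#' smoothed-noise texture, plus white noise. At coherence 1 the structure
#' tensor of the texture is (up to noise) rank one with orientation equal
#' to the fiber direction; at coherence 0 it is isotropic.
#'
#' @param spec A [fiber_image_spec].
#' @return List with the [histo_image] `image` and the `true_orientation`.
#' @export
gen_fiber_image <- function(spec = fiber_image_spec()) {
  n <- spec$size
  with_seed(spec$seed, {
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    # across-fiber coordinate; y axis points down (rows) so use -sin
    th <- spec$orientation
    u <- -(cols - n / 2) * sin(th) + (rows - n / 2) * cos(th)
    L <- ceiling(2 * n) + 10L
    prof <- stats::filter(stats::rnorm(L), gaussian_taps(spec$fiber_width),
                          sides = 2, circular = TRUE)
    prof <- as.numeric(prof)
    prof <- (prof - mean(prof)) / stats::sd(prof)
    coh <- matrix(stats::approx(seq_len(L), prof, xout = u + L / 2,
                                rule = 2)$y, n, n)
    iso <- matrix(stats::rnorm(n * n), n, n)
    iso <- conv2_reflect(iso, gaussian_kernel_2d(spec$fiber_width))
    iso <- (iso - mean(iso)) / stats::sd(iso)
    tex <- spec$coherence * coh + (1 - spec$coherence) * iso
    img <- 0.5 + spec$contrast * tex + spec$noise_sd * matrix(stats::rnorm(n * n), n, n)
    img <- pmin(pmax(img, 0), 1)
    list(image = histo_image(img, stain = "myelin"),
         true_orientation = th)
  })
}

gaussian_taps <- function(sigma) {
  h <- ceiling(3 * sigma)
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  g / sum(g)
}

gaussian_kernel_2d <- function(sigma) {
  g <- gaussian_taps(sigma)
  K <- outer(g, g)
  K / sum(K)
}

#' Nissl image specification
#'
#' Cell sizes default to the accepted ellipse-axis regime of the counting
#' algorithm (major axis within [S, B] = [30, 140] px, sized so that
#' touching pairs exceed B and marker separations exceed D_s = 70 px).
#' At the 0.013 um^2/px acquisition scale the defaults correspond to
#' 9-12.5 um somata at about 0.3 x 1e-2 cells/um^2.
#'
#' @param size Image side in pixels (default 768).
#' @param n_cells Number of planted cells (default 24).
#' @param major_range Major-axis range in pixels (default c(85, 110)).
#' @param minor_range Minor-axis range in pixels (default c(55, 85)).
#' @param fraction_touching Fraction of cells placed as touching pairs
#'   (default 0.1; pairs fuse into components whose fitted major axis
#'   exceeds B).
#' @param contrast Staining depth multiplier (default 1).
#' @param seed RNG seed.
#' @return A `nissl_image_spec` list.
#' @export
nissl_image_spec <- function(size = 768L, n_cells = 24L,
                             major_range = c(85, 110),
                             minor_range = c(55, 85),
                             fraction_touching = 0.1,
                             contrast = 1, seed = 1L) {
  stopifnot(n_cells >= 0, fraction_touching >= 0, fraction_touching <= 1,
            all(major_range > 0), all(minor_range > 0),
            diff(major_range) >= 0, diff(minor_range) >= 0)
  structure(list(size = as.integer(size), n_cells = as.integer(n_cells),
                 major_range = as.numeric(major_range),
                 minor_range = as.numeric(minor_range),
                 fraction_touching = as.numeric(fraction_touching),
                 contrast = as.numeric(contrast), seed = as.integer(seed)),
            class = "nissl_image_spec")
}

# Nissl rendering palette: light background, blue-violet somata
# (B > R > G at full staining depth).
NISSL_BG <- c(0.93, 0.91, 0.96)
NISSL_DEPTH <- c(0.60, 0.73, 0.62)

#' Generate a Nissl-like cell image with ground truth
#'
#' Dark elliptical somata with smooth super-Gaussian edge profiles on a
#' light background, colored with a Nissl-like blue-violet hue. Cells are
#' placed on a jittered grid (guaranteeing feasibility at the default
#' density); `fraction_touching` of the cells are planted as overlapping
#' pairs offset along their shared major axis so that the fused component
#' exceeds the under-segmentation threshold while the two intensity peaks
#' stay separated by more than the marker distance rule. Cells in a pair
#' are given distinct staining depths (natural staining variability, and
#' it keeps their markers distinguishable on the intensity scale).
#'
#' @param spec A [nissl_image_spec].
#' @return List with the RGB [histo_image] `image`, the ground-truth
#'   `cells` tibble (id, cx, cy, major, minor, theta, depth, pair) and
#'   `count`.
#' @export
gen_nissl_image <- function(spec = nissl_image_spec()) {
  n <- spec$size
  with_seed(spec$seed, {
    n_pairs <- round(spec$fraction_touching * spec$n_cells / 2)
    n_single <- spec$n_cells - 2L * n_pairs
    n_sites <- n_single + n_pairs
    if (spec$n_cells == 0) {
      img <- array(rep(NISSL_BG, each = n * n), dim = c(n, n, 3))
      img <- img + array(stats::rnorm(length(img), 0, 0.004), dim = dim(img))
      return(list(image = histo_image(pmin(pmax(img, 0), 1), stain = "nissl"),
                  cells = tibble::tibble(id = integer(), cx = numeric(),
                                         cy = numeric(), major = numeric(),
                                         minor = numeric(), theta = numeric(),
                                         depth = numeric(), pair = integer()),
                  count = 0L))
    }
    g <- ceiling(sqrt(n_sites))
    while (n_pairs > 0 && ceiling((g - 2)^2 / 2) < n_pairs) g <- g + 1L  # pairs need checkerboard interior sites
    pitch <- n / g
    if (pitch < 1.25 * max(spec$major_range)) {
      stop("infeasible packing: ", spec$n_cells, " cells of major axis up to ",
           max(spec$major_range), " px do not fit a ", n, "x", n, " frame")
    }
    centers <- expand.grid(r = (seq_len(g) - 0.5) * pitch,
                           c = (seq_len(g) - 0.5) * pitch)
    grid_rc <- expand.grid(r = seq_len(g), c = seq_len(g))
    interior <- grid_rc$r > 1 & grid_rc$r < g & grid_rc$c > 1 & grid_rc$c < g
    # pairs go on a checkerboard of interior sites so no two pairs are
    # grid-adjacent (their fused footprints would merge)
    pairable <- interior & (grid_rc$r + grid_rc$c) %% 2 == 0
    if (n_pairs > sum(pairable)) stop("infeasible packing: too many touching pairs")
    pair_sites <- if (n_pairs > 0) sample(which(pairable), n_pairs) else integer(0)
    single_sites <- sample(setdiff(seq_len(g^2), pair_sites), n_single)

    cells <- list()
    add_cell <- function(cx, cy, major, minor, theta, depth, pair) {
      cells[[length(cells) + 1L]] <<- data.frame(
        cx = cx, cy = cy, major = major, minor = minor,
        theta = theta, depth = depth, pair = pair)
    }
    for (s in single_sites) {
      jr <- stats::runif(1, -0.1, 0.1) * pitch
      jc <- stats::runif(1, -0.1, 0.1) * pitch
      major <- stats::runif(1, spec$major_range[1], spec$major_range[2])
      minor <- min(stats::runif(1, spec$minor_range[1], spec$minor_range[2]),
                   0.9 * major)
      add_cell(centers$r[s] + jr, centers$c[s] + jc, major, minor,
               stats::runif(1, 0, pi), stats::runif(1, 0.92, 1.08), NA_integer_)
    }
    for (k in seq_along(pair_sites)) {
      s <- pair_sites[k]
      # diagonal pair axis keeps the pair clear of axis-aligned neighbors
      axis <- sample(c(pi / 4, 3 * pi / 4), 1) + stats::runif(1, -pi / 18, pi / 18)
      m1 <- stats::runif(1, spec$major_range[1], spec$major_range[2])
      m2 <- stats::runif(1, spec$major_range[1], spec$major_range[2])
      b1 <- min(stats::runif(1, spec$minor_range[1], spec$minor_range[2]), 0.9 * m1)
      b2 <- min(stats::runif(1, spec$minor_range[1], spec$minor_range[2]), 0.9 * m2)
      sep <- 0.95 * (m1 + m2) / 2         # > D_s = 70, overlapping, fused major > B
      dr <- sin(axis) * sep / 2; dc <- cos(axis) * sep / 2
      t1 <- stats::runif(1, 0.92, 1.08)
      t2 <- pmin(pmax(t1 + sample(c(-1, 1), 1) * stats::runif(1, 0.03, 0.08),
                      0.88), 1.12)
      add_cell(centers$r[s] - dr, centers$c[s] - dc, m1, b1, axis, t1, k)
      add_cell(centers$r[s] + dr, centers$c[s] + dc, m2, b2, axis, t2, k)
    }
    cells <- do.call(rbind, cells)
    cells <- cells[order(cells$cx, cells$cy), ]
    cells$id <- seq_len(nrow(cells))

    # staining-depth field: per-pixel max over super-Gaussian cell profiles
    D <- matrix(0, n, n)
    for (i in seq_len(nrow(cells))) {
      a <- cells$major[i] / 2; b <- cells$minor[i] / 2; th <- cells$theta[i]
      ext <- ceiling(1.6 * a)
      r0 <- max(1, floor(cells$cx[i] - ext)); r1 <- min(n, ceiling(cells$cx[i] + ext))
      c0 <- max(1, floor(cells$cy[i] - ext)); c1 <- min(n, ceiling(cells$cy[i] + ext))
      rr <- r0:r1; cc <- c0:c1
      dy <- matrix(rr - cells$cx[i], length(rr), length(cc))
      dx <- matrix(cc - cells$cy[i], length(rr), length(cc), byrow = TRUE)
      ua <- (dx * cos(th) + dy * sin(th)) / a
      ub <- (-dx * sin(th) + dy * cos(th)) / b
      u2 <- ua^2 + ub^2
      prof <- cells$depth[i] * spec$contrast * exp(-u2^2)
      D[rr, cc] <- pmax(D[rr, cc], prof)
    }
    img <- array(0, dim = c(n, n, 3))
    for (ch in 1:3) {
      img[, , ch] <- NISSL_BG[ch] - NISSL_DEPTH[ch] * D +
        stats::rnorm(n * n, 0, 0.004)
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = histo_image(img, stain = "nissl"),
         cells = tibble::as_tibble(cells[, c("id", "cx", "cy", "major",
                                             "minor", "theta", "depth", "pair")]),
         count = nrow(cells))
  })
}

#' Generate diffusion-weighted signals from a known tensor
#'
#' `S = S0 exp(-b g' D g)` with `D = R diag(evals) R'`, plus optional
#' Gaussian noise at the given SNR (relative to S0). Gaussian noise (not
#' Rician) is the default: the generator validates fitting algebra, not
#' scanner noise physics.
#'
#' @param evals Sorted eigenvalues (mm^2/s).
#' @param rotation 3x3 rotation matrix applied to the tensor frame
#'   (default identity).
#' @param protocol A [dwi_protocol].
#' @param snr Signal-to-noise ratio (`Inf` = noiseless).
#' @param s0 b0 signal amplitude (default 1).
#' @param seed RNG seed used when `snr` is finite.
#' @param rician Use Rician instead of Gaussian noise (default FALSE).
#' @return Numeric vector of signals, one per protocol volume.
#' @export
gen_dwi <- function(evals, rotation = diag(3), protocol = dwi_protocol(),
                    snr = Inf, s0 = 1, seed = 1L, rician = FALSE) {
  stopifnot(length(evals) == 3, all(dim(rotation) == c(3, 3)))
  if (snr <= 0) stop("snr must be > 0")
  D <- rotation %*% diag(evals) %*% t(rotation)
  g <- protocol$bvecs
  att <- colSums((D %*% g) * g)          # g' D g per volume
  s <- s0 * exp(-protocol$bvals * att)
  if (is.finite(snr)) {
    s <- with_seed(seed, {
      sigma <- s0 / snr
      if (rician) {
        sqrt((s + stats::rnorm(length(s), 0, sigma))^2 +
               stats::rnorm(length(s), 0, sigma)^2)
      } else {
        s + stats::rnorm(length(s), 0, sigma)
      }
    })
  }
  s
}

#' Default cohort parameterization
#'
#' Region-wise AI and CD group means and SDs for both hemispheres at the
#' three bregma levels, on the scale of the study's histology table
#' (CD on the x 1e-2 cells/um^2 scale), together with synthetic FA/AD
#' parameters: ROI-level DTI summary statistics are not part of the
#' printed tables, so FA and AD means are derived from the AI means
#' (FA = 0.8 AI, SD 0.06; AD = (0.8 + 0.6 AI) x 1e-3 mm^2/s, SD 0.08e-3)
#' -- synthetic values documented as such.
#'
#' @param n_sham,n_mtbi Group sizes (defaults 6 and 8).
#' @param seed RNG seed for [gen_cohort()].
#' @return A `cohort_spec` list with the `params` tibble (one row per
#'   group/hemisphere/level/region with AI/CD/FA/AD means and SDs).
#' @export
cohort_spec <- function(n_sham = 6L, n_mtbi = 8L, seed = 1L) {
  stopifnot(n_sham >= 2, n_mtbi >= 2)
  p <- table1_params()
  p$FA_mean <- 0.8 * p$AI_mean
  p$FA_sd <- 0.06
  p$AD_mean <- (0.8 + 0.6 * p$AI_mean) * 1e-3
  p$AD_sd <- 0.08e-3
  structure(list(n_sham = as.integer(n_sham), n_mtbi = as.integer(n_mtbi),
                 params = p, seed = as.integer(seed)),
            class = "cohort_spec")
}

# AI and CD group means/SDs per hemisphere, level and region (CD on the
# x 1e-2 cells/um^2 scale). One row per (level, region, hemisphere, group).
table1_params <- function() {
  txt <- "level,region,hemisphere,group,AI_mean,AI_sd,CD_mean,CD_sd
1.08,cc,ipsilateral,sham,0.81,0.05,0.53,0.03
1.08,cc,ipsilateral,mTBI,0.83,0.03,0.52,0.04
1.08,cc,contralateral,sham,0.80,0.04,0.52,0.04
1.08,cc,contralateral,mTBI,0.81,0.03,0.52,0.02
1.08,ec,ipsilateral,sham,0.73,0.04,0.43,0.03
1.08,ec,ipsilateral,mTBI,0.71,0.04,0.44,0.04
1.08,ec,contralateral,sham,0.75,0.03,0.44,0.05
1.08,ec,contralateral,mTBI,0.75,0.03,0.46,0.05
1.08,S1,ipsilateral,sham,0.43,0.06,0.39,0.02
1.08,S1,ipsilateral,mTBI,0.47,0.06,0.40,0.06
1.08,S1,contralateral,sham,0.47,0.04,0.39,0.01
1.08,S1,contralateral,mTBI,0.47,0.01,0.38,0.03
-1.60,cc,ipsilateral,sham,0.85,0.02,0.51,0.05
-1.60,cc,ipsilateral,mTBI,0.82,0.04,0.55,0.04
-1.60,cc,contralateral,sham,0.84,0.04,0.50,0.02
-1.60,cc,contralateral,mTBI,0.82,0.03,0.53,0.03
-1.60,ec,ipsilateral,sham,0.71,0.06,0.43,0.04
-1.60,ec,ipsilateral,mTBI,0.66,0.03,0.50,0.05
-1.60,ec,contralateral,sham,0.73,0.02,0.42,0.03
-1.60,ec,contralateral,mTBI,0.72,0.05,0.44,0.04
-1.60,S1,ipsilateral,sham,0.38,0.05,0.39,0.02
-1.60,S1,ipsilateral,mTBI,0.38,0.06,0.41,0.03
-1.60,S1,contralateral,sham,0.45,0.05,0.39,0.02
-1.60,S1,contralateral,mTBI,0.44,0.05,0.39,0.02
-3.60,cc,ipsilateral,sham,0.83,0.04,0.50,0.06
-3.60,cc,ipsilateral,mTBI,0.78,0.05,0.52,0.06
-3.60,cc,contralateral,sham,0.80,0.06,0.49,0.03
-3.60,cc,contralateral,mTBI,0.75,0.07,0.50,0.06
-3.60,ec,ipsilateral,sham,0.76,0.03,0.44,0.03
-3.60,ec,ipsilateral,mTBI,0.60,0.08,0.56,0.06
-3.60,ec,contralateral,sham,0.73,0.04,0.43,0.03
-3.60,ec,contralateral,mTBI,0.78,0.03,0.42,0.03
-3.60,S1,ipsilateral,sham,0.34,0.07,0.39,0.02
-3.60,S1,ipsilateral,mTBI,0.30,0.05,0.46,0.05
-3.60,S1,contralateral,sham,0.35,0.09,0.39,0.03
-3.60,S1,contralateral,mTBI,0.33,0.04,0.38,0.01
-3.60,ic,ipsilateral,sham,0.53,0.09,0.38,0.03
-3.60,ic,ipsilateral,mTBI,0.47,0.04,0.45,0.02
-3.60,ic,contralateral,sham,0.56,0.08,0.38,0.02
-3.60,ic,contralateral,mTBI,0.57,0.04,0.35,0.04
-3.60,VPL,ipsilateral,sham,0.43,0.03,0.33,0.03
-3.60,VPL,ipsilateral,mTBI,0.43,0.03,0.38,0.04
-3.60,VPL,contralateral,sham,0.45,0.05,0.33,0.03
-3.60,VPL,contralateral,mTBI,0.44,0.04,0.34,0.03"
  tibble::as_tibble(utils::read.csv(text = txt, stringsAsFactors = FALSE))
}

#' Generate a synthetic sham/mTBI ROI cohort
#'
#' Independent Gaussian draws per record from the spec's group means and
#' SDs; one record per (animal, hemisphere, level, region). Draws are
#' independent across regions (no within-animal covariance), a documented
#' simplification relative to real data.
#'
#' @param spec A [cohort_spec].
#' @return An ROI-table tibble with columns `animal_id`, `group`,
#'   `hemisphere`, `level`, `region`, `AI`, `CD`, `FA`, `AD`.
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  p <- spec$params
  animals <- c(paste0("sham_", seq_len(spec$n_sham)),
               paste0("mTBI_", seq_len(spec$n_mtbi)))
  groups <- c(rep("sham", spec$n_sham), rep("mTBI", spec$n_mtbi))
  with_seed(spec$seed, {
    rows <- vector("list", nrow(p))
    for (i in seq_len(nrow(p))) {
      sel <- groups == p$group[i]
      k <- sum(sel)
      rows[[i]] <- tibble::tibble(
        animal_id = animals[sel], group = p$group[i],
        hemisphere = p$hemisphere[i], level = p$level[i], region = p$region[i],
        AI = stats::rnorm(k, p$AI_mean[i], p$AI_sd[i]),
        CD = stats::rnorm(k, p$CD_mean[i], p$CD_sd[i]),
        FA = stats::rnorm(k, p$FA_mean[i], p$FA_sd[i]),
        AD = stats::rnorm(k, p$AD_mean[i], p$AD_sd[i]))
    }
    out <- dplyr::bind_rows(rows)
    out[order(out$level, out$region, out$hemisphere, out$animal_id,
              method = "radix", decreasing = c(TRUE, FALSE, FALSE, FALSE)), ]
  })
}
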