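# Cell-counting stage: speed image, Chan-Vese segmentation, triage,
# markers, watershed correction and density.

rgb_image <- function(r, g, b) {
  histo_image(array(c(r, g, b), dim = c(nrow(r), ncol(r), 3)))
}

test_that("speed image responds to green-channel structure only", {
  flat <- matrix(0.5, 32, 32)
  img <- rgb_image(matrix(runif(32 * 32), 32), flat, flat)
  expect_equal(max(speed_image(img)), 0)   # constant green, busy red

  g <- matrix(0.2, 64, 64); g[, 33:64] <- 0.8
  img <- rgb_image(flat_m <- matrix(0.5, 64, 64), g, flat_m)
  sp <- speed_image(img)
  expect_equal(which.max(colSums(sp)), 32L, tolerance = 1)
  expect_true(all(sp >= 0 & sp <= 1))

  expect_error(speed_image(histo_image(matrix(0.5, 16, 16))), "channel")
  expect_silent(speed_image(histo_image(matrix(0.5, 16, 16)), channel = "gray"))
})

test_that("speed image matches a direct Sobel convolution oracle", {
  set.seed(9)
  r <- matrix(runif(24 * 24), 24); g <- matrix(runif(24 * 24), 24)
  img <- rgb_image(r, g, r)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- oracle_conv2(g, sx); gy <- oracle_conv2(g, t(sx))
  mag <- sqrt(gx^2 + gy^2); mag <- mag / max(mag)
  expect_lt(max(abs(speed_image(img) - mag)), 1e-10)
})

test_that("Chan-Vese recovers a two-phase blob from random and fixed inits", {
  m <- matrix(0.1, 96, 96)
  m[30:66, 30:66] <- 0.9
  m <- m + matrix(rnorm(96 * 96, 0, 0.01), 96, 96)
  truth <- matrix(FALSE, 96, 96); truth[30:66, 30:66] <- TRUE
  for (init in c("random", "checkerboard")) {
    cv <- chan_vese(m, mu = 0.2, max_iter = 300, init = init, seed = 4)
    agree <- mean(cv$foreground == truth)
    expect_gt(agree, 0.99)
  }
})

test_that("blank images segment to zero components", {
  g <- gen_nissl_image(nissl_image_spec(n_cells = 0, size = 256))
  lab <- suppressWarnings(preliminary_segmentation(g$image))
  expect_equal(max(lab), 0)
  expect_equal(nrow(triage_components(lab)), 0)
})

test_that("ellipse triage classifies by major axis against S and B", {
  lab <- matrix(0L, 300, 600)
  lab[draw_ellipse_mask(300, 600, 80, 100, 10, 8)] <- 1L    # major 20 < S
  lab[draw_ellipse_mask(300, 600, 80, 300, 30, 20)] <- 2L   # major 60 in [S, B]
  lab[draw_ellipse_mask(300, 600, 200, 150, 74, 25)] <- 3L  # major ~150 > B
  tri <- triage_components(lab)
  expect_equal(tri$status, c("noise", "accepted", "under_segmented"))
  # fitted axes agree with the second-order moments oracle
  for (i in 1:3) {
    o <- oracle_ellipse_axes(lab == i)
    expect_equal(tri$major[i], o$major, tolerance = 0.02)
    expect_equal(tri$minor[i], o$minor, tolerance = 0.02)
    expect_equal(tri$cx[i], o$centroid[1], tolerance = 1e-6)
    expect_equal(tri$cy[i], o$centroid[2], tolerance = 1e-6)
  }
})

test_that("a dumbbell of two fused cells triages as under-segmented", {
  lab <- matrix(0L, 260, 260)
  mask <- draw_ellipse_mask(260, 260, 130, 90, 30, 28) |
    draw_ellipse_mask(260, 260, 130, 175, 30, 28)
  lab[mask] <- 1L
  tri <- triage_components(lab)
  expect_equal(tri$status, "under_segmented")
  expect_equal(tri$major, oracle_ellipse_axes(mask)$major, tolerance = 0.02)
})

test_that("marker intensity image is the inverted filtered value channel", {
  c0 <- matrix(0.6, 32, 32)
  gray_img <- rgb_image(c0, c0, c0)
  mi <- marker_intensity_image(gray_img)
  expect_equal(mi, matrix(0.4, 32, 32), tolerance = 1e-9)

  set.seed(2)
  r <- matrix(runif(40 * 40), 40); g <- matrix(runif(40 * 40), 40)
  b <- matrix(runif(40 * 40), 40)
  img <- rgb_image(r, g, b)
  cfg <- cell_count_config()
  v <- pmax(r, g, b)
  sz <- 2 * ceiling(3 * cfg$marker_sigma) + 1
  u <- seq(-(sz - 1) / 2, (sz - 1) / 2)
  g1 <- exp(-u^2 / (2 * cfg$marker_sigma^2))
  K <- outer(g1, g1); K <- K / sum(K)
  expect_lt(max(abs(marker_intensity_image(img) - (1 - oracle_conv2(v, K)))),
            1e-10)
})

test_that("marker extraction applies the intensity and separation rules", {
  cfg <- cell_count_config()
  dom <- matrix(TRUE, 200, 300)

  # one interior maximum -> one marker at the bump
  f1 <- bump_field(200, 300, rbind(c(100, 150)), 0.9)
  m1 <- extract_markers(f1, dom, cfg)
  expect_equal(nrow(m1), 1L)
  expect_equal(c(m1$row, m1$col), c(100, 150), tolerance = 1.5)

  # condition (1): a 0.4 peak is below I = 0.5 and is dropped
  f2 <- bump_field(200, 300, rbind(c(100, 80), c(100, 220)), c(0.9, 0.4))
  m2 <- extract_markers(f2, dom, cfg)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$intensity, 0.9, tolerance = 1e-6)

  # condition (2): peaks 40 px apart (< D_s = 70) keep only the brighter
  f3 <- bump_field(200, 300, rbind(c(100, 130), c(100, 170)), c(0.9, 0.8))
  m3 <- extract_markers(f3, dom, cfg)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$col, 130, tolerance = 1.5)

  # condition (3): far-apart peaks with equal intensity collapse to one
  f4 <- bump_field(200, 300, rbind(c(100, 80), c(100, 220)), c(0.9, 0.9))
  m4 <- extract_markers(f4, dom, cfg)
  expect_equal(nrow(m4), 1L)

  # all markers below I -> empty marker set (component kept as one cell)
  f5 <- bump_field(200, 300, rbind(c(100, 150)), 0.3)
  expect_equal(nrow(extract_markers(f5, dom, cfg)), 0L)
})

test_that("watershed correction partitions a component into one region per marker", {
  dom <- draw_ellipse_mask(200, 300, 100, 110, 80, 40) |
    draw_ellipse_mask(200, 300, 100, 190, 80, 40)
  f <- bump_field(200, 300, rbind(c(100, 110), c(100, 190)), c(0.9, 0.85), sigma = 25)
  mk <- tibble::tibble(row = c(100L, 100L), col = c(110L, 190L),
                       intensity = c(0.9, 0.85))
  sub <- watershed_correct(dom, mk, f)
  expect_equal(sort(unique(sub[sub > 0])), c(1L, 2L))
  expect_equal(sum(sub > 0), sum(dom))   # partition
  areas <- tabulate(sub[sub > 0])
  expect_lt(abs(areas[1] / areas[2] - 1), 0.2)   # symmetric split

  # one marker leaves the component whole
  one <- watershed_correct(dom, mk[1, ], f)
  expect_equal(sum(one == 1), sum(dom))
  # marker outside the domain violates the contract
  bad <- tibble::tibble(row = 5L, col = 5L, intensity = 0.9)
  expect_error(watershed_correct(dom, bad, f), "outside")
})

test_that("counting recovers planted cells and is stable across init seeds", {
  g <- gen_nissl_image(nissl_image_spec(seed = 101))
  d <- count_and_density(g$image)
  expect_equal(d$N, g$count)
  expect_equal(d$A_um2, 768^2 * 0.013)
  expect_equal(d$rho, d$N / d$A_um2)
  expect_equal(d$rho_x1e2, 100 * d$rho)
  counts <- vapply(1:3, function(s)
    count_and_density(g$image, cfg = cell_count_config(rng_seed = s))$N,
    integer(1))
  expect_true(all(counts == counts[1]))
})

test_that("count is invariant to whole-pixel translation on an interior ROI", {
  g <- gen_nissl_image(nissl_image_spec(seed = 55))
  p <- g$image$pixels
  shifted <- p
  shifted[9:768, 9:768, ] <- p[1:760, 1:760, ]
  roi <- matrix(FALSE, 768, 768); roi[60:700, 60:700] <- TRUE
  roi_shift <- matrix(FALSE, 768, 768); roi_shift[68:708, 68:708] <- TRUE
  n1 <- count_and_density(g$image, roi_mask = roi)$N
  n2 <- count_and_density(histo_image(shifted), roi_mask = roi_shift)$N
  expect_equal(n1, n2)
})

test_that("density follows rho = N / A exactly and rejects empty masks", {
  g <- gen_nissl_image(nissl_image_spec(n_cells = 4, size = 512, seed = 9))
  roi <- matrix(TRUE, 512, 512)
  half <- roi; half[, 1:256] <- FALSE
  d_full <- count_and_density(g$image, roi_mask = roi)
  expect_equal(d_full$rho * d_full$A_um2, d_full$N)
  expect_error(count_and_density(g$image, roi_mask = roi & FALSE), "empty")
})
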