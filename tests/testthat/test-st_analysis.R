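# Structure-tensor stage: derivative filters, windowed tensors, AI, ROI
# summaries.

test_that("gaussian derivatives vanish on constants and reproduce ramps", {
  cfg <- st_config()
  flat <- gaussian_derivatives(matrix(0.7, 64, 64), cfg)
  expect_lt(max(abs(flat$Ix)), 1e-12)
  expect_lt(max(abs(flat$Iy)), 1e-12)

  ramp_x <- matrix(rep(seq_len(64), times = 64), 64, 64, byrow = TRUE)
  d <- gaussian_derivatives(ramp_x, cfg)
  interior <- 10:55
  expect_equal(max(abs(d$Ix[interior, interior] - 1)), 0, tolerance = 1e-9)
  expect_lt(max(abs(d$Iy[interior, interior])), 1e-9)
})

test_that("derivative fields equal the explicit-kernel convolution oracle", {
  set.seed(42)
  m <- matrix(runif(64 * 64), 64, 64)
  cfg <- st_config()
  d <- gaussian_derivatives(m, cfg)
  k <- gaussian_derivative_kernels(cfg$deriv_kernel_size, cfg$deriv_sigma)
  expect_lt(max(abs(d$Ix - oracle_conv2(m, k$kx))), 1e-10)
  expect_lt(max(abs(d$Iy - oracle_conv2(m, k$ky))), 1e-10)
})

test_that("images smaller than the kernel are rejected", {
  expect_error(gaussian_derivatives(matrix(0, 8, 8), st_config()),
               "smaller than")
})

test_that("tiled tensors match brute-force per-tile summation exactly", {
  set.seed(7)
  Ix <- matrix(rnorm(96 * 96), 96, 96)
  Iy <- matrix(rnorm(96 * 96), 96, 96)
  cfg <- st_config(window = 32)
  f <- structure_tensor_field(Ix, Iy, cfg)
  expect_lt(max(abs(f$Jxx - oracle_tile_sum(Ix * Ix, 32))), 1e-10)
  expect_lt(max(abs(f$Jxy - oracle_tile_sum(Ix * Iy, 32))), 1e-10)
  expect_lt(max(abs(f$Jyy - oracle_tile_sum(Iy * Iy, 32))), 1e-10)
})

test_that("uniform unit x-gradient gives rank-one tile tensors", {
  w <- 32
  Ix <- matrix(1, 64, 64); Iy <- matrix(0, 64, 64)
  f <- structure_tensor_field(Ix, Iy, st_config(window = w))
  expect_equal(unname(f$l1), matrix(w^2, 2, 2))
  expect_equal(unname(f$l2), matrix(0, 2, 2))
  expect_equal(unname(f$ai_map), matrix(1, 2, 2))
})

test_that("tiled mode drops partial border tiles and rejects tiny images", {
  f <- structure_tensor_field(matrix(1, 100, 70), matrix(0, 100, 70),
                              st_config(window = 32))
  expect_equal(dim(f$Jxx), c(3L, 2L))
  expect_error(structure_tensor_field(matrix(1, 20, 20), matrix(0, 20, 20),
                                      st_config(window = 32)), "tile")
  expect_error(structure_tensor_field(matrix(1, 4, 4), matrix(0, 5, 5),
                                      st_config(window = 4)), "shape")
})

test_that("sliding aggregation equals clipped box sums", {
  set.seed(3)
  Ix <- matrix(rnorm(20 * 20), 20, 20)
  cfg5 <- st_config(deriv_kernel_size = 5, deriv_sigma = 1, window = 5,
                    aggregation = "sliding")
  f <- structure_tensor_field(Ix, Ix, cfg5)
  # interior pixel: full 5x5 window
  expect_equal(f$Jxx[10, 10], sum(Ix[8:12, 8:12]^2), tolerance = 1e-12)
  # corner pixel: clipped window
  expect_equal(f$Jxx[1, 1], sum(Ix[1:3, 1:3]^2), tolerance = 1e-12)
})

test_that("anisotropy index follows the eigenvalue contract", {
  expect_equal(anisotropy_index(5, 5), 0)
  expect_equal(anisotropy_index(7, 0), 1)
  expect_equal(anisotropy_index(3, 1), 0.5)
  expect_equal(anisotropy_index(0, 0), 0)   # zero-tensor convention
  expect_error(anisotropy_index(-1, -2), "non-negative")
  expect_error(anisotropy_index(1, 2), "l1")
})

test_that("white-noise texture is isotropic at the 128-pixel window", {
  set.seed(11)
  m <- matrix(runif(512 * 512), 512, 512)
  d <- gaussian_derivatives(m, st_config())
  f <- structure_tensor_field(d$Ix, d$Iy, st_config())
  expect_lt(median(f$ai_map), 0.1)
})

test_that("AI is invariant to intensity scaling and 90-degree rotation", {
  fib <- gen_fiber_image(fiber_image_spec(size = 256, coherence = 0.7, seed = 5))
  m <- fib$image$pixels
  cfg <- st_config()
  ai_of <- function(mm) {
    d <- gaussian_derivatives(mm, cfg)
    structure_tensor_field(d$Ix, d$Iy, cfg)
  }
  f1 <- ai_of(m)
  f2 <- ai_of(0.35 * m)
  expect_equal(f1$ai_map, f2$ai_map, tolerance = 1e-9)

  rot <- t(m)[, rev(seq_len(nrow(m)))]   # 90-degree rotation
  f3 <- ai_of(rot)
  expect_equal(sort(as.numeric(f3$ai_map)), sort(as.numeric(f1$ai_map)),
               tolerance = 1e-6)
  # orientation of the summed tensor rotates by pi/2 (mod pi)
  r1 <- roi_ai(f1, matrix(TRUE, nrow(f1$Jxx), ncol(f1$Jxx)))
  r3 <- roi_ai(f3, matrix(TRUE, nrow(f3$Jxx), ncol(f3$Jxx)))
  dtheta <- abs((r1$orientation - r3$orientation) %% pi)
  expect_lt(min(abs(dtheta - pi / 2), abs(dtheta - pi / 2) %% pi), 0.05)
})

test_that("ROI summary separates tensor-sum AI from mean AI", {
  # two orthogonal perfectly coherent tiles with equal energy
  field <- structure(list(
    Jxx = matrix(c(3, 0), 1, 2), Jxy = matrix(0, 1, 2),
    Jyy = matrix(c(0, 3), 1, 2),
    l1 = matrix(3, 1, 2), l2 = matrix(0, 1, 2),
    orientation = matrix(c(pi / 2, 0), 1, 2),
    ai_map = matrix(1, 1, 2), aggregation = "tiled", window = 128L
  ), class = "st_field")
  both <- roi_ai(field, matrix(TRUE, 1, 2))
  expect_equal(both$ai_tensor, 0)
  expect_equal(both$ai_mean, 1)
  one <- roi_ai(field, matrix(c(TRUE, FALSE), 1, 2))
  expect_equal(one$ai_tensor, 1)
  # identical tensors: same AI as either tile (scale invariance)
  twin <- field
  twin$Jyy <- matrix(0, 1, 2); twin$Jxx <- matrix(3, 1, 2)
  expect_equal(roi_ai(twin, matrix(TRUE, 1, 2))$ai_tensor, 1)
  expect_error(roi_ai(field, matrix(FALSE, 1, 2)), "empty ROI")
})

test_that("st_analyze summarizes an image-grid ROI mask", {
  fib <- gen_fiber_image(fiber_image_spec(size = 256, coherence = 1, seed = 2))
  mask <- matrix(FALSE, 256, 256)
  mask[1:128, 1:128] <- TRUE
  res <- st_analyze(fib$image, st_config(), roi = mask)
  expect_equal(res$roi$n_locations, 1L)
  expect_equal(res$roi$ai_tensor, res$field$ai_map[1, 1])
  expect_equal(nrow(res$tiles), 4L)
})
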