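test_that("sigma = FWHM / sqrt(8 ln 2) and kernels are normalized", {
  psf <- psf_model(c(8.8, 11.0, 9.2))
  expect_equal(psf$sigma, c(8.8, 11.0, 9.2) / sqrt(8 * log(2)))
  expect_equal(psf$sigma[1], 3.737, tolerance = 1e-3)
  k <- gaussian_kernel(psf, 2.21)
  expect_equal(sum(k$array), 1, tolerance = 1e-6)
  expect_true(all(k$array >= 0))
  # zero FWHM is the identity along every axis
  d <- gaussian_kernel(psf_model(c(0, 0, 0)), 2.21)
  expect_identical(dim(d$array), c(1L, 1L, 1L))
  expect_equal(d$array[1, 1, 1], 1)
})

test_that("a kernel wider than the image is rejected with advice", {
  g <- voxel_grid(c(4, 4, 4), 1)
  img <- activity_image(array(1, g$dim), g)
  expect_error(convolve_psf(img, psf_model(c(30, 30, 30))), "zero-pad")
})

test_that("separable convolution matches the direct triple-sum oracle", {
  set.seed(42)
  g <- voxel_grid(c(16, 16, 16), 2.21)
  x <- array(stats::runif(prod(g$dim)), g$dim)
  psf <- psf_model(c(8.8, 11.0, 9.2), truncation_radius = 3)
  fast <- convolve_psf(x, psf, g$spacing)
  slow <- direct_convolve(x, psf, g$spacing)
  expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-10)
})

test_that("convolution is linear and preserves interior DC level", {
  set.seed(7)
  g <- voxel_grid(c(20, 20, 20), 2.21)
  psf <- psf_model(c(6, 6, 6))
  f <- array(stats::runif(prod(g$dim)), g$dim)
  h <- array(stats::runif(prod(g$dim)), g$dim)
  lin <- convolve_psf(2 * f + 3 * h, psf, g$spacing)
  sep <- 2 * convolve_psf(f, psf, g$spacing) + 3 * convolve_psf(h, psf, g$spacing)
  expect_lt(max(abs(lin - sep)) / max(abs(sep)), 1e-10)
  const <- convolve_psf(array(5, g$dim), psf, g$spacing)
  expect_equal(const[10, 10, 10], 5, tolerance = 1e-9)
})

test_that("impulse response replicates the kernel; mass is conserved", {
  g <- voxel_grid(c(24, 24, 24), 2.21)
  psf <- psf_model(c(8.8, 11.0, 9.2))
  x <- array(0, g$dim); x[12, 12, 12] <- 1
  y <- convolve_psf(x, psf, g$spacing)
  k <- gaussian_kernel(psf, g$spacing)$array
  r <- (dim(k) - 1L) %/% 2L
  sub <- y[12 + (-r[1]:r[1]), 12 + (-r[2]:r[2]), 12 + (-r[3]:r[3])]
  expect_equal(sub, k, tolerance = 1e-12)
  # support >= 4 sigma from the boundary: total mass conserved
  expect_lt(abs(sum(y) - sum(x)) / sum(x), 1e-6)
})

test_that("noise-free observation equals the convolution; seeds reproduce", {
  g <- voxel_grid(c(20, 20, 20), 2.21)
  truth <- activity_image(array(33800, g$dim), g)
  psf <- psf_model(c(8.8, 11.0, 9.2))
  clean <- simulate_observation(truth, psf)
  expect_equal(clean$values, convolve_psf(truth$values, psf, g$spacing),
               tolerance = 1e-12)
  n1 <- simulate_observation(truth, psf, noise = list(kappa = 0.04, seed = 11))
  n2 <- simulate_observation(truth, psf, noise = list(kappa = 0.04, seed = 11))
  n3 <- simulate_observation(truth, psf, noise = list(kappa = 0.04, seed = 12))
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
  expect_error(simulate_observation(truth, psf, noise = list(kappa = -1, seed = 1)),
               "kappa")
})

test_that("Poisson noise has the 1/sqrt(mean) coefficient of variation", {
  g <- voxel_grid(c(22, 22, 22), 2.21)  # ~1e4 voxels
  conc <- 33800
  kappa <- 100 / (conc * voxel_volume(g, "mL"))  # mean 100 counts/voxel
  truth <- activity_image(array(conc, g$dim), g)
  psf <- psf_model(c(0, 0, 0))  # no blur: every voxel iid
  noisy <- simulate_observation(truth, psf, noise = list(kappa = kappa, seed = 5))
  cv <- stats::sd(noisy$values) / mean(noisy$values)
  expect_equal(cv, 0.1, tolerance = 0.01)
})

test_that("label shifts are rigid, fill with background, and clip at the body", {
  lm <- tiny_phantom_labels()
  expect_identical(shift_labels(lm, c(0, 0, 0), "kidney_R")$labels, lm$labels)
  sh <- shift_labels(lm, c(3, 0, 0), "kidney_R")
  com <- function(l, lab) unname(colMeans(which(l$labels == lab, arr.ind = TRUE)))
  expect_equal(com(sh, 1) - com(lm, 1), c(3, 0, 0), tolerance = 1e-12)
  # physical displacement = 3 voxels * spacing
  expect_equal((com(sh, 1) - com(lm, 1)) * lm$grid$spacing,
               c(3 * 4.42, 0, 0), tolerance = 1e-12)
  # vacated voxels are background now
  vac <- lm$labels == 1L & sh$labels != 1L
  expect_true(all(sh$labels[vac] == 11L))
  # shifting out and back is not the identity where labels were overwritten
  back <- shift_labels(shift_labels(lm, c(1, 0, 0), "kidney_R"),
                       c(-1, 0, 0), "kidney_R")
  expect_identical(back$labels == 1L, lm$labels == 1L)
  # a huge shift pushes the kidney against the body support: warns and clips
  expect_warning(shift_labels(lm, c(14, 0, 0), "kidney_R"), "clipped")
})
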