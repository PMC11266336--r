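test_that("recovery coefficients are exact on constant and truth images", {
  g <- voxel_grid(c(8, 8, 8), 2.21)
  img <- activity_image(array(50, g$dim), g)
  m <- array(TRUE, g$dim)
  rc <- recovery_coefficient(img, m, 50)
  expect_equal(rc$RC, 1)
  expect_error(recovery_coefficient(img, array(FALSE, g$dim), 50), "empty")
  expect_error(recovery_coefficient(img, m, 0), "C_cal")
  # piecewise-constant truth: kidney RC is exactly 1 over the crisp mask
  p <- iec1_phantom()
  bin <- iec1_binary_observation()
  for (k in c("kidney_R", "kidney_L")) {
    rck <- recovery_coefficient(bin$truth, region_mask(p$asm$labels, k),
                                378.7 * 1000)
    expect_equal(rck$RC, 1, tolerance = 1e-9)
  }
  # fractional truth over structure interiors (occupancy 1): exactly 1
  interior <- p$asm$occupancy$structures$kidney_R >= 1 - 1e-12
  rci <- recovery_coefficient(p$asm$truth, interior, 378.7 * 1000)
  expect_equal(rci$RC, 1, tolerance = 1e-6)
  # fractional truth over the 0.5-threshold mask: a few percent low, a
  # segmentation-vs-object boundary effect, not an error
  rcm <- recovery_coefficient(p$asm$truth, region_mask(p$asm$labels, "kidney_R"),
                              378.7 * 1000)
  expect_lt(rcm$RC, 1)
  expect_gt(rcm$RC, 0.9)
})

test_that("background RC is 1 on truth and within 1% on the blurred image", {
  p <- iec1_phantom()
  bg_cal <- 33.8 * 1000
  expect_equal(background_rc(p$asm$truth, p$asm$labels, bg_cal)$RC, 1,
               tolerance = 1e-6)
  expect_equal(background_rc(p$obs, p$asm$labels, bg_cal)$RC, 1,
               tolerance = 0.01)
})

test_that("peripheral shell of the truth sits at the background level", {
  p <- iec1_phantom()
  bin <- iec1_binary_observation()
  # piecewise-constant truth: the 3-voxel shell lies in background exactly
  rc <- peripheral_shell_rc(bin$truth, p$asm$labels, "kidney_R",
                            C_cal = 378.7 * 1000)
  expect_equal(rc$RC, 33.8 / 378.7, tolerance = 1e-9)
  # fractional truth carries part of the boundary mass into the shell
  rcf <- peripheral_shell_rc(p$asm$truth, p$asm$labels, "kidney_R",
                             C_cal = 378.7 * 1000)
  expect_gte(rcf$RC, rc$RC)
  expect_lt(rcf$RC, 2 * rc$RC)
})

test_that("calibration-factor arithmetic and stability summary", {
  g <- voxel_grid(c(90, 90, 80), 2.21)
  img <- activity_image(array(100, g$dim), g, unit = "counts")
  cal <- calibration_factor(img, C_cal = 50)
  expect_equal(cal$CF, 2)
  expect_equal(cal$N_ave, 100)
  expect_equal(cf_decrease_pct(18.40, 17.95), 2.45, tolerance = 0.01)
  tiny <- activity_image(array(1, c(4, 4, 4)), voxel_grid(c(4, 4, 4), 2.21),
                         unit = "counts")
  expect_error(calibration_factor(tiny, 50), "outside the grid")
})

test_that("a uniform cylinder at the nominal sensitivity recovers its CF", {
  g <- voxel_grid(c(100, 100, 90), 2.21)
  cc <- kidneypvc:::grid_coords_matrix(g)
  inside <- cc[, 1]^2 + cc[, 2]^2 <= 105^2 & abs(cc[, 3]) <= 183 / 2
  C_cal <- 848.3  # MBq in the calibration cylinder
  cf_true <- 18.26
  counts <- array(0, g$dim)
  counts[array(inside, g$dim)] <- cf_true * C_cal
  img <- activity_image(counts, g, unit = "counts")
  cal <- calibration_factor(img, C_cal)
  expect_equal(cal$CF, cf_true, tolerance = 1e-10)
})

test_that("FWHM estimation recovers the simulation input from a capillary", {
  # fine grid: the procedure's own sampling bias is negligible and the
  # simulation inputs come back within 0.3 mm
  g <- voxel_grid(c(70, 70, 40), 1.5)
  cap <- rasterize_shape(shape_cylinder(c(0, 0), 0.75,
                                        c(g$origin[3], -g$origin[3])), g, 5)
  psf <- psf_model(c(8.8, 11.0, 9.2))
  img <- activity_image(convolve_psf(cap * 1000, psf, g$spacing), g)
  for (ax in 1:2) {
    est <- estimate_fwhm(img, axis = ax)
    expect_equal(est$fwhm_mm, psf$fwhm[ax], tolerance = 0.3 / psf$fwhm[ax])
    expect_false(est$resolution_limited)
  }
  # working-grid sampling (2.21 mm): half-maximum interpolation and voxel
  # binning widen the profile by a known ~0.5 mm; the estimate stays within
  # a quarter voxel of that
  g2 <- voxel_grid(c(50, 50, 30), 2.21)
  cap2 <- rasterize_shape(shape_cylinder(c(0, 0), 0.75,
                                         c(g2$origin[3], -g2$origin[3])), g2, 5)
  img2 <- activity_image(convolve_psf(cap2 * 1000, psf, g2$spacing), g2)
  est2 <- estimate_fwhm(img2, axis = 2)
  expect_equal(est2$fwhm_mm, 11.0, tolerance = 0.06)
  # unblurred single-voxel-wide line: resolution-limited flag
  raw <- array(0, g2$dim); raw[25, 25, 10:20] <- 1
  est0 <- estimate_fwhm(activity_image(raw, g2), axis = 1)
  expect_true(est0$resolution_limited)
  # a profile that never falls below half maximum is rejected
  flat <- array(100, g2$dim); flat[25, 25, 15] <- 101
  expect_error(estimate_fwhm(activity_image(flat, g2), axis = 1),
               "half-maximum")
})

test_that("bias-vs-S:V regression handles exact lines and degenerate input", {
  sv <- c(1.5, 1.8, 2.3, 2.8)
  fit <- bias_vs_sv_regression(3 - 2 * sv, sv)
  expect_equal(fit$slope, -2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  flat <- bias_vs_sv_regression(rep(1, 4) + c(1e-9, 0, 0, 0), sv)
  expect_equal(flat$slope, 0, tolerance = 1e-6)
  expect_error(bias_vs_sv_regression(c(1, 2), c(1, 2)), "3 distinct")
})

test_that("all three sweeps report zero bias at the null perturbation", {
  tc <- tiny_ideal_case()
  Ct <- tc$C_true[["kidney_R"]]
  methods <- c("gtm", "labbe", "iy")
  ps <- psf_mismatch_sweep(tc$obs, tc$labels, tc$psf, Ct, deltas = 0,
                           methods = methods)
  expect_true(all(abs(ps$bias_pct) < 0.1))
  rs <- registration_sweep(tc$obs, tc$labels, tc$psf, Ct, offsets_voxels = 0L,
                           methods = methods)
  expect_true(all(abs(rs$bias_pct) < 0.1))
  hs <- heterogeneity_sweep(tc$obs, tc$labels, tc$psf, Ct, ratios = 1,
                            methods = methods)
  expect_true(all(abs(hs$bias_pct) < 0.1))
})

test_that("heterogeneity injection is confined to the lung and hits the ratio", {
  tc <- tiny_ideal_case()
  lung <- region_mask(tc$labels, "lung")
  merged_bg <- region_mask(tc$labels, "background") | lung
  v <- tc$obs$values
  target_ratio <- 2.5
  add <- (target_ratio - 1) * sum(v[merged_bg]) / sum(lung)
  v2 <- v
  v2[lung] <- v2[lung] + add
  expect_equal(mean(v2[merged_bg]) / mean(v[merged_bg]), target_ratio,
               tolerance = 1e-12)
  expect_identical(v2[!lung], v[!lung])
  expect_error(heterogeneity_sweep(tc$obs, tc$labels, tc$psf, 340,
                                   ratios = 0.5), "unattainable")
})

test_that("negative-FWHM deltas are skipped with a record", {
  tc <- tiny_ideal_case()
  expect_warning(
    sw <- psf_mismatch_sweep(tc$obs, tc$labels, tc$psf, 340,
                             deltas = c(-20, 0), methods = "gtm"),
    "negative FWHM")
  expect_true(all(sw$delta_mm == 0))
})
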