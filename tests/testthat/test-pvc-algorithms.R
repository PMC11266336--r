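test_that("GTM region means equal brute-force masked averages", {
  lm <- tiny_phantom_labels()
  g <- lm$grid
  const <- activity_image(array(7.5, g$dim), g)
  A <- region_means_gtm(const, lm)
  expect_equal(as.numeric(A), rep(7.5, 4), tolerance = 1e-12)
  ind <- array(0, g$dim); ind[lm$labels == 1L] <- 1
  A2 <- region_means_gtm(activity_image(ind, g), lm)
  expect_equal(as.numeric(A2[c("kidney_R", "lung")]), c(1, 0))
  set.seed(3)
  v <- array(stats::runif(prod(g$dim)), g$dim)
  A3 <- region_means_gtm(v, lm)
  for (nm in names(lm$names)) {
    expect_equal(A3[[nm]], sum(v[lm$labels == lm$names[[nm]]]) /
                   sum(lm$labels == lm$names[[nm]]), tolerance = 1e-12)
  }
})

test_that("Labbe means collapse to GTM for a delta PSF and match the oracle", {
  lm <- tiny_phantom_labels()
  set.seed(4)
  v <- array(stats::runif(prod(lm$grid$dim)), lm$grid$dim)
  delta <- psf_model(c(0, 0, 0))
  expect_equal(as.numeric(region_means_labbe(v, lm, delta)),
               as.numeric(region_means_gtm(v, lm)), tolerance = 1e-12)
  # constant image, interior region: blurred-mask mass is conserved
  psf <- psf_model(c(8.8, 11.0, 9.2))
  Ac <- region_means_labbe(array(3, lm$grid$dim), lm, psf)
  expect_equal(Ac[["kidney_R"]], 3, tolerance = 1e-6)
  # brute-force oracle: direct convolution of the mask, then the printed sum
  A <- region_means_labbe(v, lm, psf)
  for (nm in c("kidney_R", "background")) {
    m <- region_mask(lm, nm)
    bm <- direct_convolve(m + 0, psf, lm$grid$spacing)
    expect_equal(A[[nm]], sum(bm * v) / sum(m), tolerance = 1e-10)
  }
})

test_that("Labbe blurred-normalization switch coincides for interior regions", {
  lm <- tiny_phantom_labels()
  psf <- psf_model(c(8.8, 11.0, 9.2))
  set.seed(8)
  v <- array(stats::runif(prod(lm$grid$dim)), lm$grid$dim)
  crisp <- region_means_labbe(v, lm, psf)
  blurred <- region_means_labbe(v, lm, psf, normalization = "blurred")
  # kidney_R sits >4 sigma inside the grid: both normalizations agree
  expect_equal(crisp[["kidney_R"]], blurred[["kidney_R"]], tolerance = 1e-6)
})

test_that("spill-over matrix: delta identity, symmetry, and direct oracle", {
  lm <- tiny_phantom_labels()
  sp0 <- build_spillover_matrix(lm, psf_model(c(0, 0, 0)), mode = "gtm")
  expect_equal(sp0$G, diag(4), ignore_attr = TRUE, tolerance = 1e-12)
  # congruent mirror-image regions couple symmetrically
  g <- voxel_grid(c(20, 20, 12), 2.21)
  lab <- array(0L, g$dim)
  lab[5:8, 8:13, 4:9] <- 1L
  lab[13:16, 8:13, 4:9] <- 2L
  lm2 <- label_map(lab, g, c(a = 1L, b = 2L))
  psf <- psf_model(c(6, 6, 6))
  sp <- build_spillover_matrix(lm2, psf, mode = "gtm")
  expect_equal(sp$G[1, 2], sp$G[2, 1], tolerance = 1e-12)
  expect_true(is.finite(sp$condition_number))
  # every entry against the triple-loop convolution oracle, both modes
  for (mode in c("gtm", "labbe")) {
    spx <- build_spillover_matrix(lm2, psf, mode = mode)
    bms <- lapply(1:2, function(l) direct_convolve((lab == l) + 0, psf, g$spacing))
    for (i in 1:2) for (j in 1:2) {
      num <- if (mode == "gtm") sum(bms[[i]][lab == j])
             else sum(bms[[i]] * bms[[j]])
      expect_equal(spx$G[i, j], num / sum(lab == j), tolerance = 1e-10)
    }
  }
})

test_that("GTM rows conserve mass over a partition with interior kernel", {
  # labels partition the WHOLE grid; the inner regions sit further from the
  # grid edge than the kernel support, so their blurred mass stays inside
  # the partition and the weighted row sum returns the region size
  g <- voxel_grid(c(26, 26, 26), 2.21)
  lab <- array(3L, g$dim)
  lab[10:13, 10:17, 10:17] <- 1L
  lab[15:17, 10:17, 10:17] <- 2L
  lm <- label_map(lab, g, c(a = 1L, b = 2L, c = 3L))
  sp <- build_spillover_matrix(lm, psf_model(c(5, 5, 5)), mode = "gtm")
  sizes <- sp$region_sizes
  for (i in 1:2) {
    landed <- sum(sp$G[i, ] * sizes)
    expect_lt(abs(landed - sizes[i]) / sizes[i], 1e-4)
  }
  # the outer region touches the zero-padded grid edge and loses exactly the
  # off-grid kernel mass
  landed3 <- sum(sp$G[3, ] * sizes)
  offgrid <- sizes[3] - sum(convolve_psf((lab == 3) + 0, psf_model(c(5, 5, 5)),
                                         g$spacing))
  expect_equal(landed3, sizes[3] - offgrid, tolerance = 1e-10)
})

test_that("solving the spill-over system recovers truth in the ideal limit", {
  tc <- tiny_ideal_case()
  for (mode in c("gtm", "labbe")) {
    A <- if (mode == "gtm") region_means_gtm(tc$obs, tc$sys)
         else region_means_labbe(tc$obs, tc$sys)
    sp <- build_spillover_matrix(tc$sys, mode = mode)
    C <- solve_corrected_means(sp, A)
    expect_equal(as.numeric(C), as.numeric(tc$C_true), tolerance = 1e-3)
    err <- abs(as.numeric(C) - tc$C_true)[tc$C_true > 0] /
      tc$C_true[tc$C_true > 0]
    expect_lt(max(err), 0.001)
  }
  # G = identity passes A through unchanged
  spI <- structure(list(G = diag(3), region_sizes = c(10, 10, 10),
                        mode = "gtm", condition_number = 1,
                        names = c("a", "b", "c")),
                   class = "spillover_matrix")
  A <- structure(c(a = 1, b = 2, c = 3), kind = "uncorrected_A",
                 estimator = "gtm", class = "region_means")
  expect_equal(as.numeric(solve_corrected_means(spI, A)), c(1, 2, 3))
})

test_that("a duplicated region makes the system singular and is reported", {
  spDup <- structure(list(G = matrix(c(1, 1, 1, 1), 2), region_sizes = c(5, 5),
                          mode = "gtm", condition_number = Inf,
                          names = c("dup1", "dup2")),
                     class = "spillover_matrix")
  A <- structure(c(dup1 = 1, dup2 = 1), class = "region_means")
  expect_error(solve_corrected_means(spDup, A), "ill-conditioned")
})

test_that("MTC: delta-PSF identity, closed-form exactness, independent oracle", {
  tc <- tiny_ideal_case()
  lm <- tc$labels
  # delta PSF: both terms collapse and I_c = I
  sys0 <- pvc_system(lm, psf_model(c(0, 0, 0)))
  set.seed(5)
  v <- array(stats::runif(prod(lm$grid$dim)), lm$grid$dim)
  img <- activity_image(v, lm$grid)
  C <- structure(stats::setNames(c(2, 3, 0.5, 1), names(lm$names)),
                 class = "region_means")
  out0 <- mtc_correct(img, sys0, C)
  expect_equal(out0$values[lm$labels > 0], v[lm$labels > 0], tolerance = 1e-12)
  # ideal input with exact C: the bracket reduces to C_j s_j voxel-exactly
  Ct <- tc$C_true
  out <- mtc_correct(tc$obs, tc$sys, Ct)
  inr <- lm$labels > 0
  expect_lt(max(abs(out$values[inr] - tc$S[inr]) / max(tc$S)), 1e-6)
  expect_true(out$corrected)
  # independent second implementation, different loop order (sum over region
  # terms assembled as full-image arrays)
  Crand <- stats::setNames(c(5, 2, 0.3, 1.2), names(lm$names))
  ref <- array(0, lm$grid$dim)
  for (j in seq_along(lm$names)) {
    sj <- region_mask(lm, names(lm$names)[j])
    bj <- convolve_psf(sj + 0, tc$psf, lm$grid$spacing)
    spill <- array(0, lm$grid$dim)
    for (i in seq_along(lm$names)) if (i != j)
      spill <- spill + Crand[i] *
        convolve_psf(region_mask(lm, names(lm$names)[i]) + 0, tc$psf,
                     lm$grid$spacing)
    term <- (sj * v - sj * spill) / bj
    guardok <- sj & (bj > 1e-3 * max(bj[sj]))
    ref[guardok] <- term[guardok]
    ref[sj & !guardok] <- v[sj & !guardok]
  }
  mine <- mtc_correct(img, tc$sys, structure(Crand, class = "region_means"))
  expect_equal(mine$values[inr], ref[inr], tolerance = 1e-10)
})

test_that("RBV: delta-PSF identity and closed-form exactness on ideal input", {
  tc <- tiny_ideal_case()
  lm <- tc$labels
  sys0 <- pvc_system(lm, psf_model(c(0, 0, 0)))
  set.seed(6)
  v <- array(stats::runif(prod(lm$grid$dim)) + 0.5, lm$grid$dim)
  img <- activity_image(v, lm$grid)
  C <- structure(stats::setNames(c(2, 3, 0.5, 1), names(lm$names)),
                 class = "region_means")
  out0 <- rbv_correct(img, sys0, C)
  expect_equal(out0$values[lm$labels > 0], v[lm$labels > 0], tolerance = 1e-12)
  out <- rbv_correct(tc$obs, tc$sys, tc$C_true)
  inr <- lm$labels > 0
  expect_lt(max(abs(out$values[inr] - tc$S[inr]) / max(tc$S)), 1e-6)
  # region means of the RBV-corrected ideal input equal C exactly
  mu <- region_means_gtm(out, lm)
  nz <- tc$C_true > 0
  expect_equal(as.numeric(mu)[nz], unname(tc$C_true[nz]), tolerance = 1e-6)
  zero <- structure(stats::setNames(rep(0, 4), names(lm$names)),
                    class = "region_means")
  expect_error(rbv_correct(img, tc$sys, zero), "identically zero")
})

test_that("IY: delta-PSF one-shot, monotone convergence, tol = Inf contract", {
  tc <- tiny_ideal_case()
  lm <- tc$labels
  sys0 <- pvc_system(lm, psf_model(c(0, 0, 0)))
  set.seed(9)
  v <- array(stats::runif(prod(lm$grid$dim)), lm$grid$dim)
  img <- activity_image(v, lm$grid)
  r0 <- iy_correct(img, sys0)
  expect_equal(r0$image$values[lm$labels > 0], v[lm$labels > 0],
               tolerance = 1e-12)
  expect_lte(nrow(r0$trace), 3)  # converges immediately
  # ideal input: means within 1% of truth after 10 iterations, error monotone
  r <- iy_correct(tc$obs, tc$sys, n_iter = 10)
  nz <- tc$C_true > 0
  expect_lt(max(abs(as.numeric(r$means)[nz] - tc$C_true[nz]) / tc$C_true[nz]),
            0.01)
  err <- apply(r$trace[, nz, drop = FALSE], 1,
               function(m) max(abs(m - tc$C_true[nz]) / tc$C_true[nz]))
  expect_true(all(diff(err) <= 1e-12))
  # tol = Inf reproduces non-iterated Yang: exactly one iteration
  r1 <- iy_correct(tc$obs, tc$sys, n_iter = 10, tol = Inf)
  expect_identical(nrow(r1$trace), 2L)
})

test_that("run_pvc dispatches all seven methods with consistent seeds", {
  tc <- tiny_ideal_case()
  expect_error(run_pvc(tc$obs, tc$sys, method = "nope"))
  rb <- run_pvc(tc$obs, tc$sys, method = "gtm+rbv")
  rg <- run_pvc(tc$obs, tc$sys, method = "gtm")
  expect_equal(as.numeric(rb$means), as.numeric(rg$means), tolerance = 1e-12)
  expect_null(rg$image)
  expect_false(is.null(rb$image))
  # Labbe and GTM agree in the ideal limit
  rl <- run_pvc(tc$obs, tc$sys, method = "labbe")
  nz <- tc$C_true > 0
  expect_lt(max(abs((as.numeric(rl$means) - as.numeric(rg$means))[nz]) /
                  tc$C_true[nz]), 0.001)
  # IY and GTM+RBV images agree within 1% RMS over the body
  ry <- run_pvc(tc$obs, tc$sys, method = "iy")
  body <- tc$labels$labels > 0
  rms <- sqrt(mean((ry$image$values[body] - rb$image$values[body])^2))
  expect_lt(rms / max(tc$S), 0.01)
})
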