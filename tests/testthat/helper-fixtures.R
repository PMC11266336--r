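# Shared fixtures. Heavy objects (kidney surrogate fits, the full IEC-1
# phantom) are built once per test session and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small phantom-like partition on a coarse grid: two hot "kidneys" (spheres),
# a cold "lung" cylinder, and background inside an ellipsoidal body.
# Region names match the full phantom so the sweep functions run on it.
tiny_phantom_labels <- function() {
  cached("tiny_labels", function() {
    g <- voxel_grid(c(36, 36, 36), 4.42)
    cc <- kidneypvc:::grid_coords_matrix(g)
    lab <- integer(nrow(cc))
    body <- (cc[, 1] / 72)^2 + (cc[, 2] / 72)^2 + (cc[, 3] / 72)^2 <= 1
    k1 <- (cc[, 1] - 32)^2 + cc[, 2]^2 + cc[, 3]^2 <= 16^2
    k2 <- (cc[, 1] + 32)^2 + (cc[, 2] - 8)^2 + cc[, 3]^2 <= 13^2
    lung <- cc[, 1]^2 + (cc[, 2] + 34)^2 <= 12^2 & abs(cc[, 3]) <= 40 & body
    lab[body] <- 11L
    lab[k1] <- 1L
    lab[k2] <- 2L
    lab[lung] <- 9L
    label_map(array(lab, g$dim), g,
              c(kidney_R = 1L, kidney_L = 2L, lung = 9L, background = 11L))
  })
}

tiny_truth_means <- function() c(kidney_R = 340, kidney_L = 320, lung = 0,
                                 background = 30)

# piecewise-constant truth + PSF-blurred observation on the tiny partition
tiny_ideal_case <- function() {
  cached("tiny_ideal", function() {
    lm <- tiny_phantom_labels()
    psf <- psf_model(c(8.8, 11.0, 9.2))
    sys <- pvc_system(lm, psf)
    Ct <- tiny_truth_means()
    S <- piecewise_constant_image(sys, Ct)
    obs <- activity_image(convolve_psf(S, psf, lm$grid$spacing), lm$grid)
    list(labels = lm, psf = psf, sys = sys, C_true = Ct, S = S, obs = obs)
  })
}

# all six kidney surrogates fitted to the printed geometry table (1 mm grid)
fitted_surrogates <- function() {
  cached("surrogates", function() fit_all_kidney_surrogates())
}

# IEC-1 analogue (small kidney pair) at the first-row concentrations,
# fractional truth, assembled with clearance validation on
iec1_phantom <- function() {
  cached("iec1", function() {
    surr <- fitted_surrogates()
    spec <- phantom_spec(kidneys = surr[c("Small-R", "Small-L")],
                         background_conc = 33.8, target_conc = 378.7)
    asm <- assemble_phantom(spec)
    psf <- psf_model(c(8.8, 11.0, 9.2))
    obs <- simulate_observation(asm$truth, psf)
    list(spec = spec, asm = asm, psf = psf, obs = obs)
  })
}

# the same phantom with piecewise-constant (binary-label) truth
iec1_binary_observation <- function() {
  cached("iec1_binary", function() {
    p <- iec1_phantom()
    spec <- p$spec
    spec$truth_mode <- "binary"
    truth <- kidneypvc:::phantom_truth(spec, p$asm$occupancy, p$asm$labels)
    list(truth = truth, obs = simulate_observation(truth, p$psf))
  })
}

iec1_system <- function() {
  cached("iec1_sys", function() {
    p <- iec1_phantom()
    pvc_system(p$asm$labels, p$psf)
  })
}

# direct (non-separable, triple-loop over kernel taps) zero-padded
# convolution: the brute-force oracle for all convolution-built quantities
direct_convolve <- function(x, psf, spacing) {
  k <- gaussian_kernel(psf, spacing)$array
  d <- dim(x)
  dk <- dim(k)
  r <- (dk - 1L) %/% 2L
  out <- array(0, d)
  for (ox in seq_len(dk[1])) for (oy in seq_len(dk[2])) for (oz in seq_len(dk[3])) {
    w <- k[ox, oy, oz]
    if (w == 0) next
    sx <- ox - r[1] - 1L; sy <- oy - r[2] - 1L; sz <- oz - r[3] - 1L
    xi <- seq_len(d[1]) - sx; yi <- seq_len(d[2]) - sy; zi <- seq_len(d[3]) - sz
    okx <- xi >= 1L & xi <= d[1]; oky <- yi >= 1L & yi <= d[2]
    okz <- zi >= 1L & zi <= d[3]
    out[okx, oky, okz] <- out[okx, oky, okz] +
      w * x[xi[okx], yi[oky], zi[okz]]
  }
  out
}
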