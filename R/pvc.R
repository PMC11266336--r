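# Anatomy-based partial volume correction.
#
# All seven methods are built from one cached primitive: the PSF-blurred
# indicator of each segmented region (one convolution per region). The
# spill-over matrix, the Labbe means, and the MTC/RBV/IY denominators are all
# inner products or sums over these cached fields, so a full method
# comparison costs N convolutions, not N per method.

#' Precompute the blurred region masks shared by all PVC methods
#'
#' @param labels a [label_map()]; label 0 (air) is excluded.
#' @param psf a [psf_model()].
#' @return object of class `pvc_system`: region labels/names/sizes, the crisp
#'   logical masks, and the PSF-blurred mask fields.
#' @export
pvc_system <- function(labels, psf) {
  stopifnot(inherits(labels, "label_map"), inherits(psf, "psf_model"))
  labs <- region_labels(labels)
  if (!length(labs)) stop("pvc_system: label map has no regions")
  nm <- names(labels$names)[match(labs, labels$names)]
  masks <- lapply(labs, function(l) labels$labels == l)
  sizes <- vapply(masks, sum, 1)
  if (any(sizes == 0)) stop("pvc_system: empty region")
  blurred <- lapply(masks, function(m)
    convolve_psf(m + 0, psf, labels$grid$spacing))
  structure(list(labels = labs, names = nm, sizes = sizes,
                 masks = masks, blurred = blurred,
                 grid = labels$grid, psf = psf, label_map = labels),
            class = "pvc_system")
}

#' Uncorrected region means (GTM estimator)
#'
#' `A_i` is the mean of the observed image over the crisp segmentation mask
#' `s_i`.
#'
#' @param image an [activity_image()] (or 3-D array on the same grid).
#' @param labels a [label_map()] or a prebuilt [pvc_system()].
#' @return named numeric vector (class `region_means`, estimator "gtm").
#' @export
region_means_gtm <- function(image, labels) {
  v <- image_values(image)
  sys <- as_pvc_system_for_means(labels)
  A <- vapply(seq_along(sys$labels), function(i) mean(v[sys$masks[[i]]]), 1)
  region_means(A, sys$names, kind = "uncorrected_A", estimator = "gtm")
}

#' Uncorrected region means (Labbe estimator)
#'
#' `A_i = sum((s_i (*) h) * I) / sum(s_i)`: a blurred-mask-weighted sum
#' normalized by the crisp mask size. With `normalization = "blurred"` the
#' sum is normalized by `sum(s_i (*) h)` instead; the two coincide when the
#' blurred mask loses no mass off the grid (interior regions).
#'
#' @param image an [activity_image()] or 3-D array.
#' @param labels a [label_map()] or [pvc_system()].
#' @param psf a [psf_model()] (ignored when `labels` is a `pvc_system`).
#' @param normalization `"crisp"` (as printed) or `"blurred"`.
#' @return named numeric vector (class `region_means`, estimator "labbe").
#' @export
region_means_labbe <- function(image, labels, psf = NULL,
                               normalization = c("crisp", "blurred")) {
  normalization <- match.arg(normalization)
  v <- image_values(image)
  sys <- as_pvc_system_for_means(labels, psf)
  A <- vapply(seq_along(sys$labels), function(i) {
    num <- sum(sys$blurred[[i]] * v)
    den <- if (normalization == "crisp") sys$sizes[i] else sum(sys$blurred[[i]])
    num / den
  }, 1)
  region_means(A, sys$names, kind = "uncorrected_A", estimator = "labbe")
}

region_means <- function(values, names, kind, estimator) {
  if (any(!is.finite(values))) stop("region means must be finite")
  structure(stats::setNames(values, names),
            kind = kind, estimator = estimator, class = "region_means")
}

image_values <- function(image) {
  if (inherits(image, "activity_image")) image$values else image
}

as_pvc_system_for_means <- function(labels, psf = NULL) {
  if (inherits(labels, "pvc_system")) return(labels)
  if (is.null(psf)) {
    # GTM means need no blurred masks; build a light system
    labs <- region_labels(labels)
    masks <- lapply(labs, function(l) labels$labels == l)
    sizes <- vapply(masks, sum, 1)
    if (any(sizes == 0)) stop("empty region")
    nm <- names(labels$names)[match(labs, labels$names)]
    return(list(labels = labs, names = nm, masks = masks, sizes = sizes))
  }
  pvc_system(labels, psf)
}

#' Build the spill-over matrix G
#'
#' `G[i, j]` is the fraction of region i's blurred indicator landing in
#' region j, normalized by the receiving region size: GTM mode
#' `sum((s_i (*) h) * s_j) / sum(s_j)`; Labbe mode
#' `sum((s_i (*) h) * (s_j (*) h)) / sum(s_j)`. With this source-to-target
#' orientation the observed means of a piecewise-constant object satisfy
#' `A = t(G) C`, which is what [solve_corrected_means()] solves.
#'
#' @param labels a [label_map()] or prebuilt [pvc_system()].
#' @param psf a [psf_model()] (ignored for a `pvc_system`).
#' @param mode `"gtm"` or `"labbe"`.
#' @return object of class `spillover_matrix`: `G`, `region_sizes`, `mode`,
#'   `condition_number`, `names`.
#' @export
build_spillover_matrix <- function(labels, psf = NULL,
                                   mode = c("gtm", "labbe")) {
  mode <- match.arg(mode)
  sys <- if (inherits(labels, "pvc_system")) labels else pvc_system(labels, psf)
  n <- length(sys$labels)
  G <- matrix(0, n, n, dimnames = list(sys$names, sys$names))
  for (i in seq_len(n)) {
    bi <- sys$blurred[[i]]
    for (j in seq_len(n)) {
      num <- if (mode == "gtm") sum(bi[sys$masks[[j]]])
             else sum(bi * sys$blurred[[j]])
      G[i, j] <- num / sys$sizes[j]
    }
  }
  structure(list(G = G, region_sizes = sys$sizes, mode = mode,
                 condition_number = kappa(G, exact = FALSE),
                 names = sys$names),
            class = "spillover_matrix")
}

#' Solve the spill-over system for the corrected region means
#'
#' Solves `t(G) C = A` by LU factorization (never an explicit inverse) and
#' verifies the residual. The transpose arises from the source-to-target
#' orientation of [build_spillover_matrix()]: observed means of a
#' piecewise-constant object are `A = t(G) C`, so this solve recovers the
#' true means exactly in the noise-free matched-PSF limit.
#'
#' @param spill a `spillover_matrix`.
#' @param A a `region_means` vector (uncorrected).
#' @return `region_means` vector of corrected values C.
#' @export
solve_corrected_means <- function(spill, A) {
  stopifnot(inherits(spill, "spillover_matrix"))
  G <- spill$G
  if (!is.finite(spill$condition_number) || spill$condition_number >= 1e8) {
    off <- abs(G); diag(off) <- 0
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("solve_corrected_means: ill-conditioned spill-over ",
                        "matrix (condition number %.3g); strongest coupling ",
                        "between regions '%s' and '%s'"),
                 spill$condition_number,
                 spill$names[worst[1]], spill$names[worst[2]]))
  }
  C <- solve(t(G), as.numeric(A))
  resid <- sqrt(sum((t(G) %*% C - as.numeric(A))^2)) /
    max(sqrt(sum(as.numeric(A)^2)), .Machine$double.eps)
  if (resid >= 1e-8)
    stop("solve_corrected_means: linear-solve residual ", signif(resid, 3),
         " exceeds 1e-8")
  region_means(as.numeric(C), spill$names, kind = "corrected_C",
               estimator = attr(A, "estimator") %||% "gtm")
}

#' Piecewise-constant image of region means
#'
#' `S = sum_j C_j * s_j`: every voxel takes the mean of its region exactly
#' (0 outside all regions).
#'
#' @param sys a [pvc_system()] (or [label_map()]).
#' @param C `region_means` (corrected values).
#' @return 3-D array.
#' @export
piecewise_constant_image <- function(sys, C) {
  if (inherits(sys, "label_map")) {
    labs <- region_labels(sys)
    S <- array(0, sys$grid$dim)
    for (i in seq_along(labs)) S[sys$labels == labs[i]] <- C[i]
    return(S)
  }
  S <- array(0, sys$grid$dim)
  for (i in seq_along(sys$labels)) S[sys$masks[[i]]] <- C[i]
  S
}

# blurred piecewise-constant image from cached blurred masks (linearity)
blur_piecewise <- function(sys, C) {
  Sh <- array(0, sys$grid$dim)
  for (i in seq_along(sys$labels)) Sh <- Sh + C[i] * sys$blurred[[i]]
  Sh
}

#' Multi-target correction (MTC)
#'
#' Sequential target-neighbor correction: within each region j the observed
#' image is divided by the blurred mask `s_j (*) h` (spill-out) after
#' removing the blurred contribution of all other regions computed from the
#' precomputed corrected means C (spill-in). Voxels where the denominator
#' falls below `guard` times its within-region maximum are left uncorrected
#' and flagged (attribute `guarded`); voxels outside all regions are left
#' uncorrected.
#'
#' @param image observed [activity_image()].
#' @param sys a [pvc_system()] (or a [label_map()] plus `psf`).
#' @param C `region_means` of corrected values (from GTM or Labbe).
#' @param psf required when `sys` is a label map.
#' @param guard relative denominator guard (default 1e-3).
#' @return corrected [activity_image()] (flag `corrected = TRUE`).
#' @export
mtc_correct <- function(image, sys, C, psf = NULL, guard = 1e-3) {
  sys <- ensure_system(sys, psf)
  v <- image_values(image)
  out <- v
  Sh_all <- blur_piecewise(sys, C)
  guarded <- 0L
  for (j in seq_along(sys$labels)) {
    mj <- sys$masks[[j]]
    bj <- sys$blurred[[j]]
    ok <- mj & (bj > guard * max(bj[mj]))
    if (!any(ok))
      stop("mtc_correct: all voxels of region '", sys$names[j],
           "' fall under the denominator guard")
    spill_in <- Sh_all - C[j] * bj
    out[ok] <- (v[ok] - spill_in[ok]) / bj[ok]
    guarded <- guarded + sum(mj & !ok)
  }
  res <- as_corrected_image(out, image, sys)
  attr(res, "guarded") <- guarded
  res
}

#' Region-based voxel-wise correction (RBV)
#'
#' `I_c = I * S / (S (*) h)` with `S` the piecewise-constant image of the
#' precomputed corrected means. Voxels where `S (*) h` falls below `guard`
#' times its within-region maximum are left uncorrected; outside all regions
#' the image is untouched.
#'
#' @inheritParams mtc_correct
#' @return corrected [activity_image()].
#' @export
rbv_correct <- function(image, sys, C, psf = NULL, guard = 1e-3) {
  sys <- ensure_system(sys, psf)
  v <- image_values(image)
  S <- piecewise_constant_image(sys, C)
  if (all(S == 0)) stop("rbv_correct: piecewise-constant image is identically zero")
  Sh <- blur_piecewise(sys, C)
  out <- v
  body <- Reduce(`|`, sys$masks)
  ok <- body & (Sh > guard * max(Sh[body]))
  out[ok] <- v[ok] * S[ok] / Sh[ok]
  res <- as_corrected_image(out, image, sys)
  attr(res, "guarded") <- sum(body & !ok)
  res
}

#' Iterative Yang correction (IY)
#'
#' Needs no prior corrected means: iteration 1 applies the RBV voxel-wise
#' ratio with region means taken directly from the observed image; each
#' subsequent iteration re-estimates the means from the corrected image and
#' reapplies the ratio to the ORIGINAL observed image. Stops after `n_iter`
#' iterations or when the maximum relative change of any region mean drops
#' below `tol`.
#'
#' @inheritParams mtc_correct
#' @param n_iter maximum iterations (default 10).
#' @param tol relative mean-change stopping tolerance (default 1e-5);
#'   `tol = Inf` reproduces non-iterated Yang (exactly one iteration).
#' @return list: `image` (corrected [activity_image()]), `means`
#'   (`region_means` at convergence), `trace` (iterations x regions matrix).
#' @export
iy_correct <- function(image, sys, psf = NULL, n_iter = 10, tol = 1e-5,
                       guard = 1e-3) {
  sys <- ensure_system(sys, psf)
  v <- image_values(image)
  means_of <- function(x) vapply(sys$masks, function(m) mean(x[m]), 1)
  body <- Reduce(`|`, sys$masks)
  Ck <- means_of(v)
  trace <- matrix(Ck, nrow = 1, dimnames = list(NULL, sys$names))
  out <- v
  for (it in seq_len(n_iter)) {
    S <- piecewise_constant_image(sys, Ck)
    Sh <- blur_piecewise(sys, Ck)
    ok <- body & (Sh > guard * max(Sh[body]))
    out <- v
    out[ok] <- v[ok] * S[ok] / Sh[ok]
    C_new <- means_of(out)
    if (any(!is.finite(C_new)))
      stop("iy_correct: non-finite region mean at iteration ", it)
    delta <- max(abs(C_new - Ck) / pmax(abs(Ck), .Machine$double.eps))
    Ck <- C_new
    trace <- rbind(trace, Ck)
    if (delta < tol) break
  }
  list(image = as_corrected_image(out, image, sys),
       means = region_means(Ck, sys$names, kind = "corrected_C",
                            estimator = "iy"),
       trace = trace)
}

ensure_system <- function(sys, psf) {
  if (inherits(sys, "pvc_system")) sys
  else if (inherits(sys, "label_map")) {
    if (is.null(psf)) stop("a psf_model is required with a raw label map")
    pvc_system(sys, psf)
  } else stop("expected a pvc_system or label_map")
}

as_corrected_image <- function(values, image, sys) {
  if (inherits(image, "activity_image"))
    activity_image(array(values, image$grid$dim), image$grid,
                   unit = image$unit, corrected = TRUE)
  else activity_image(array(values, sys$grid$dim), sys$grid,
                      corrected = TRUE)
}

#' PVC method names
#' @export
pvc_methods <- function() {
  c("gtm", "labbe", "gtm+mtc", "labbe+mtc", "gtm+rbv", "labbe+rbv", "iy")
}

#' Run one anatomy-based PVC method end to end
#'
#' Region-based methods ("gtm", "labbe") return corrected means only;
#' voxel-based methods ("gtm+mtc", "labbe+mtc", "gtm+rbv", "labbe+rbv",
#' "iy") also return the corrected image. The seeding estimator before the
#' "+" provides the corrected means for MTC/RBV.
#'
#' @param image observed [activity_image()].
#' @param labels a [label_map()] or prebuilt [pvc_system()] (reuse one
#'   system to compare several methods cheaply).
#' @param psf a [psf_model()] (ignored for a prebuilt system).
#' @param method one of [pvc_methods()].
#' @param n_iter,tol IY controls.
#' @return list: `method`, `means` (corrected `region_means` C), `image`
#'   (corrected [activity_image()] or NULL), `A` (uncorrected means),
#'   `condition_number` (region-based seeds), `provenance`.
#' @export
run_pvc <- function(image, labels, psf = NULL, method = pvc_methods(),
                    n_iter = 10, tol = 1e-5) {
  method <- match.arg(method)
  sys <- ensure_system(labels, psf)
  seed <- if (startsWith(method, "labbe")) "labbe" else "gtm"
  prov <- list(method = method, fwhm_mm = sys$psf$fwhm,
               n_regions = length(sys$labels),
               mask_checksum = sum(vapply(sys$masks, sum, 1) *
                                     seq_along(sys$masks)))
  if (method == "iy") {
    r <- iy_correct(image, sys, n_iter = n_iter, tol = tol)
    return(list(method = method, means = r$means, image = r$image,
                A = region_means(r$trace[1, ], sys$names,
                                 kind = "uncorrected_A", estimator = "iy"),
                trace = r$trace, condition_number = NA_real_,
                provenance = prov))
  }
  A <- if (seed == "gtm") region_means_gtm(image, sys)
       else region_means_labbe(image, sys)
  spill <- build_spillover_matrix(sys, mode = seed)
  C <- solve_corrected_means(spill, A)
  img <- NULL
  if (endsWith(method, "+mtc")) img <- mtc_correct(image, sys, C)
  if (endsWith(method, "+rbv")) img <- rbv_correct(image, sys, C)
  list(method = method, means = C, image = img, A = A,
       condition_number = spill$condition_number, provenance = prov)
}
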