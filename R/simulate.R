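#' Simulate an observed SPECT image from a ground-truth activity image
#'
#' Degrades the truth by the stationary anisotropic Gaussian PSF and,
#' optionally, Poisson count noise: the expected counts in a voxel are
#' `concentration [Bq/mL] * voxel volume [mL] * kappa [counts/Bq]`, sampled
#' with a fixed seed and converted back to concentration. Noise is off by
#' default; noise-free simulation is exactly `convolve_psf(truth, psf)`.
#'
#' The default `kappa` anchors the count density to a measured tomographic
#' sensitivity of 18.26 counts/s/MBq over a 60 x 40 s projection acquisition:
#' 18.26 * 2400 / 1e6 = 0.043824 counts per Bq of voxel activity.
#'
#' @param truth non-negative [activity_image()] in Bq/mL.
#' @param psf a [psf_model()].
#' @param noise NULL (default, noise-free) or a list with elements
#'   `kappa` (counts per Bq, > 0) and `seed` (integer).
#' @return an [activity_image()] (the observed image).
#' @export
simulate_observation <- function(truth, psf, noise = NULL) {
  stopifnot(inherits(truth, "activity_image"))
  if (any(truth$values < 0)) stop("simulate_observation: truth must be non-negative")
  observed <- convolve_psf(truth, psf)
  # separable Gaussian taps are non-negative; tiny negatives can only come
  # from floating-point cancellation
  observed$values[observed$values < 0] <- 0
  if (is.null(noise)) return(observed)
  kappa <- noise$kappa %||% 0.043824
  if (!is.numeric(kappa) || kappa <= 0)
    stop("simulate_observation: noise$kappa must be > 0")
  if (is.null(noise$seed)) stop("simulate_observation: noise runs require a seed")
  vol_mL <- voxel_volume(truth$grid, "mL")
  lambda <- observed$values * vol_mL * kappa
  counts <- withr_seed(noise$seed, stats::rpois(length(lambda), as.vector(lambda)))
  observed$values <- array(counts / (vol_mL * kappa), truth$grid$dim)
  observed
}

# evaluate expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Rigidly translate selected labels of a label map (misregistration model)
#'
#' Translates the listed labels by an integer voxel offset. Voxels vacated by
#' a moved label become `fill_label` (the background); voxels entered
#' overwrite their previous label; all other labels are untouched except where
#' overwritten. Translation is not invertible where labels were overwritten.
#'
#' @param labels a [label_map()].
#' @param offset integer triple, voxels.
#' @param labels_to_shift integer labels (or region names) to translate.
#' @param fill_label label assigned to vacated voxels (default: the region
#'   named "background" if present, else 0).
#' @return a [label_map()]; a warning is raised (and recorded in the
#'   `clipped` attribute) if the shift pushes label voxels outside the grid.
#' @export
shift_labels <- function(labels, offset, labels_to_shift, fill_label = NULL) {
  stopifnot(inherits(labels, "label_map"))
  offset <- as.integer(round(offset))
  if (length(offset) != 3L) stop("shift_labels: offset must be an integer triple")
  d <- labels$grid$dim
  if (any(abs(offset) > d)) stop("shift_labels: offset exceeds the grid extent")
  if (is.character(labels_to_shift))
    labels_to_shift <- unname(labels$names[labels_to_shift])
  labels_to_shift <- as.integer(labels_to_shift)
  if (is.null(fill_label)) {
    fill_label <- if ("background" %in% names(labels$names))
      labels$names[["background"]] else 0L
  }
  lab <- labels$labels
  moving <- lab %in% labels_to_shift
  dim(moving) <- d
  out <- lab
  out[moving] <- fill_label
  src <- which(moving, arr.ind = TRUE)
  if (nrow(src)) {
    dst <- sweep(src, 2, offset, "+")
    inside <- dst[, 1] >= 1L & dst[, 1] <= d[1] &
              dst[, 2] >= 1L & dst[, 2] <= d[2] &
              dst[, 3] >= 1L & dst[, 3] <= d[3]
    src <- src[inside, , drop = FALSE]
    dst <- dst[inside, , drop = FALSE]
    # clip at the body support: never move a label into air (label 0)
    in_body <- lab[dst] != 0L
    clipped <- sum(!inside) + sum(!in_body)
    if (clipped > 0)
      warning("shift_labels: ", clipped,
              " voxels shifted outside the body support were clipped")
    out[dst[in_body, , drop = FALSE]] <- lab[src[in_body, , drop = FALSE]]
  } else clipped <- 0L
  res <- label_map(out, labels$grid, labels$names)
  attr(res, "clipped") <- clipped
  res
}
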