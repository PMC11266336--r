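# Binary-mask morphology with exact Euclidean balls.
#
# Erosion by a physical distance keeps the voxels whose Euclidean distance to
# the mask complement exceeds that distance; dilation adds every voxel within
# the ball. Both are computed by counting, for each voxel, the neighbours
# inside an exact Euclidean-ball indicator via zero-padded FFT convolution —
# equivalent to thresholding the exact Euclidean distance transform, with no
# chamfer/structuring-element approximation of the physical distance.

ball_offsets <- function(radius_mm, spacing) {
  r_vox <- floor(radius_mm / spacing)
  if (any(r_vox < 0)) stop("negative radius")
  k <- lapply(1:3, function(a) (-r_vox[a]):(r_vox[a]) * spacing[a])
  d2 <- outer(outer(k[[1]]^2, k[[2]]^2, "+"), k[[3]]^2, "+")
  array(d2 <= radius_mm^2 + 1e-9, dim = vapply(k, length, 1L))
}

# zero-padded FFT convolution of a (small) kernel with a full-size array;
# kernel center at its middle voxel. Returns same-size array.
fft_convolve_kernel <- function(x, kernel) {
  dx <- dim(x); dk <- dim(kernel)
  dp <- dx + dk - 1L
  xp <- array(0, dp); xp[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  kp <- array(0, dp); kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  y <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / prod(dp)
  ctr <- (dk + 1L) %/% 2L  # kernel center index (odd-sized kernels)
  y[ctr[1] - 1L + seq_len(dx[1]),
    ctr[2] - 1L + seq_len(dx[2]),
    ctr[3] - 1L + seq_len(dx[3])]
}

#' Erode a binary mask by a physical distance
#'
#' Keeps the voxels of `mask` whose Euclidean distance (mm, voxel centers) to
#' the mask complement exceeds `distance_mm`. An erosion that empties the mask
#' raises an explicit "empty result" error rather than returning a silent
#' empty mask.
#'
#' @param mask logical 3-D array.
#' @param distance_mm erosion distance in mm, >= 0.
#' @param spacing per-axis voxel spacing in mm (scalar recycled).
#' @return logical 3-D array.
#' @export
erode_mask <- function(mask, distance_mm, spacing) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- array(as.logical(mask), dim(mask))
  if (distance_mm < 0) stop("erode_mask: distance_mm must be >= 0")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (distance_mm == 0) return(mask)
  bg <- !mask
  # voxels outside the grid count as background (objects truncated by the
  # field of view erode from the boundary too): pad is implicit because the
  # zero-padded convolution treats out-of-grid as 0, so add the boundary term
  # by counting interior background + missing ball mass near edges.
  kern <- ball_offsets(distance_mm, spacing)
  nb_bg <- fft_convolve_kernel(bg + 0, kern)
  nb_all <- fft_convolve_kernel(array(1, dim(mask)), kern)
  outside <- sum(kern) - nb_all          # ball mass falling outside the grid
  eroded <- mask & (nb_bg + outside < 0.5)
  if (!any(eroded))
    stop("erode_mask: empty result (erosion by ", distance_mm,
         " mm removed the whole mask)")
  eroded
}

#' Euclidean shell around a binary mask
#'
#' `shell_mask(mask, k)` is the mask dilated by a Euclidean ball of radius `k`
#' voxels minus the mask itself; it is disjoint from the mask by construction.
#'
#' @param mask logical 3-D array.
#' @param thickness_voxels shell thickness in voxels, >= 1.
#' @param spacing per-axis voxel spacing in mm (scalar recycled). The ball
#'   radius is `thickness_voxels * min(spacing)` so an isotropic grid gets an
#'   exact k-voxel Euclidean shell.
#' @return logical 3-D array.
#' @export
shell_mask <- function(mask, thickness_voxels, spacing) {
  if (thickness_voxels < 1) stop("shell_mask: thickness_voxels must be >= 1")
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("shell_mask: empty input mask")
  spacing <- rep_len(as.numeric(spacing), 3L)
  radius <- thickness_voxels * min(spacing)
  kern <- ball_offsets(radius, spacing)
  nb <- fft_convolve_kernel(mask + 0, kern)
  dilated <- nb > 0.5
  dilated & !mask
}
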