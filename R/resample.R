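#' Nearest-neighbor resampling to a target spacing
#'
#' Resamples an activity image or label map to an isotropic (or per-axis)
#' target spacing by nearest-neighbor assignment in physical coordinates: each
#' target voxel center takes the value of the source voxel whose cell contains
#' it. The target grid tiles the same physical extent as the source (cell edges
#' aligned), so resampling to the source spacing is the identity, and an
#' integer split (e.g. 4.42 mm to 2.21 mm) maps each source voxel to an exact
#' block. Label maps never acquire new label values.
#'
#' @param x an [activity_image()] or [label_map()].
#' @param target_spacing numeric scalar or triple, mm; all > 0.
#' @return object of the same class as `x` on the resampled grid.
#' @export
resample_nearest <- function(x, target_spacing) {
  UseMethod("resample_nearest")
}

resample_grid_indices <- function(grid, target_spacing) {
  ts <- rep_len(as.numeric(target_spacing), 3L)
  if (any(!is.finite(ts)) || any(ts <= 0))
    stop("resample_nearest: target_spacing must be > 0")
  s <- grid$spacing
  # physical extent covered by the source cells
  lo <- grid$origin - s / 2
  n_t <- as.integer(pmax(1, round(grid$dim * s / ts)))
  origin_t <- lo + ts / 2
  tgt <- voxel_grid(n_t, ts, origin_t)
  idx <- lapply(1:3, function(a) {
    centers <- grid_axis_coords(tgt, a)
    i <- floor((centers - lo[a]) / s[a]) + 1
    pmin(pmax(as.integer(i), 1L), grid$dim[a])
  })
  list(grid = tgt, idx = idx)
}

#' @export
resample_nearest.activity_image <- function(x, target_spacing) {
  r <- resample_grid_indices(x$grid, target_spacing)
  vals <- x$values[r$idx[[1]], r$idx[[2]], r$idx[[3]], drop = FALSE]
  activity_image(array(vals, r$grid$dim), r$grid, unit = x$unit,
                 corrected = x$corrected)
}

#' @export
resample_nearest.label_map <- function(x, target_spacing) {
  r <- resample_grid_indices(x$grid, target_spacing)
  labs <- x$labels[r$idx[[1]], r$idx[[2]], r$idx[[3]], drop = FALSE]
  label_map(array(labs, r$grid$dim), r$grid, x$names)
}
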