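#' Activity image on a voxel grid
#'
#' A 3-D array of activity concentration (canonically Bq/mL) or counts on a
#' [voxel_grid()]. Ground-truth and simulated images must be non-negative;
#' PVC-corrected images may contain negative voxels and carry
#' `corrected = TRUE` as provenance.
#'
#' @param values 3-D numeric array matching `grid$dim`; all values finite.
#' @param grid a [voxel_grid()].
#' @param unit `"Bq_per_mL"` or `"counts"`.
#' @param corrected logical; TRUE marks a PVC-corrected image (negative voxels
#'   allowed).
#' @return an object of class `activity_image`.
#' @export
activity_image <- function(values, grid, unit = c("Bq_per_mL", "counts"),
                           corrected = FALSE) {
  unit <- match.arg(unit)
  values <- as.array(values)
  if (!identical(dim(values), NULL) && length(dim(values)) != 3L)
    stop("activity_image: 'values' must be a 3-D array")
  if (!identical(as.integer(dim(values)), grid$dim))
    stop("activity_image: array dimensions do not match the grid")
  if (any(!is.finite(values)))
    stop("activity_image: non-finite voxel values")
  if (!corrected && any(values < 0))
    stop("activity_image: negative voxels in a non-corrected image")
  structure(list(values = values, grid = grid, unit = unit,
                 corrected = isTRUE(corrected)),
            class = "activity_image")
}

#' @export
print.activity_image <- function(x, ...) {
  cat(sprintf("activity_image [%s%s]: range [%.4g, %.4g]\n",
              x$unit, if (x$corrected) ", corrected" else "",
              min(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' Label map on a voxel grid
#'
#' Integer region assignment per voxel. Label 0 is reserved for
#' "outside body / uncorrected"; every nonzero label present in the array must
#' appear in the `names` table. Regions are mutually exclusive by construction
#' (one label per voxel).
#'
#' @param labels 3-D integer array matching `grid$dim`; values >= 0.
#' @param grid a [voxel_grid()].
#' @param names named integer vector mapping region names to labels
#'   (e.g. `c(kidney_R = 1L, background = 11L)`).
#' @return an object of class `label_map`.
#' @export
label_map <- function(labels, grid, names) {
  storage.mode(labels) <- "integer"
  if (length(dim(labels)) != 3L)
    stop("label_map: 'labels' must be a 3-D array")
  if (!identical(as.integer(dim(labels)), grid$dim))
    stop("label_map: array dimensions do not match the grid")
  if (any(is.na(labels)) || any(labels < 0L))
    stop("label_map: labels must be non-negative integers")
  names <- vapply(names, as.integer, 1L)
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(present, unname(names))
  if (length(missing))
    stop("label_map: labels present but absent from the names table: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, grid = grid, names = names),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %d named regions, %d nonzero voxels\n",
              length(x$names), sum(x$labels != 0L)))
  print(x$grid)
  invisible(x)
}

#' Binary mask of one region of a label map
#'
#' @param labels a [label_map()].
#' @param label integer label or region name.
#' @return logical 3-D array.
#' @export
region_mask <- function(labels, label) {
  if (is.character(label)) {
    if (!label %in% names(labels$names))
      stop("region_mask: unknown region name '", label, "'")
    label <- labels$names[[label]]
  }
  labels$labels == as.integer(label)
}

#' Labels present in a label map (excluding 0)
#' @param labels a [label_map()].
#' @return sorted integer vector.
#' @export
region_labels <- function(labels) {
  setdiff(sort(unique(as.vector(labels$labels))), 0L)
}
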