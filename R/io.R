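#' Read / write activity images and label maps as NIfTI-1
#'
#' Images are stored as `.nii` / `.nii.gz` with the grid geometry in the
#' sform/qform affine (diagonal spacing, translation = physical coordinate of
#' the first voxel center); the unit and provenance flags live in a JSON
#' sidecar (`<stem>.json`) next to the volume. The round-trip preserves
#' values, spacing, and origin to 1e-6 relative.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_image()` returns an [activity_image()];
#'   `read_labels()` a [label_map()].
#' @export
read_image <- function(path) {
  raw <- read_nifti_raw(path)
  meta <- read_sidecar(raw$sidecar)
  unit <- meta$unit %||% "Bq_per_mL"
  corrected <- isTRUE(meta$corrected)
  activity_image(raw$values, raw$grid, unit = unit, corrected = corrected)
}

#' @rdname read_image
#' @param image an [activity_image()] to write.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "activity_image"))
  write_nifti_raw(image$values, image$grid, path)
  write_sidecar(path, list(kind = "activity_image", unit = image$unit,
                           corrected = image$corrected))
  invisible(path)
}

#' @rdname read_image
#' @param names named integer vector of region names for the label map; if
#'   NULL, taken from the sidecar (if present) or auto-named `region_<k>`.
#' @export
read_labels <- function(path, names = NULL) {
  raw <- read_nifti_raw(path)
  v <- raw$values
  if (max(abs(v - round(v))) > 1e-6)
    stop("read_labels: volume contains non-integral values; not a label map")
  v <- array(as.integer(round(v)), dim(v))
  if (is.null(names)) {
    meta <- read_sidecar(raw$sidecar)
    if (!is.null(meta$region_names)) {
      names <- unlist(meta$region_names)
    } else {
      labs <- setdiff(sort(unique(as.vector(v))), 0L)
      names <- stats::setNames(labs, paste0("region_", labs))
    }
  }
  label_map(v, raw$grid, names)
}

#' @rdname read_image
#' @param labels a [label_map()] to write.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  write_nifti_raw(labels$labels, labels$grid, path, datatype = "int16")
  write_sidecar(path, list(kind = "label_map",
                           region_names = as.list(labels$names)))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

read_sidecar <- function(path) {
  if (is.character(path) && file.exists(path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else NULL
}

write_sidecar <- function(nii_path, meta) {
  jsonlite::write_json(meta, sidecar_path(nii_path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop("read_image: file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop("read_image: expected 3-D volume, got ",
         if (is.null(d)) "a vector" else paste0(length(d), "-D"))
  xf <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  # sform stores RAS coordinates; we write a positive diagonal affine so the
  # translation column is the physical center of voxel (0,0,0).
  origin <- xf[1:3, 4]
  values <- array(as.numeric(img), d)
  if (any(!is.finite(values)))
    stop("read_image: non-finite voxels in ", path)
  grid <- voxel_grid(d, spacing, origin)
  list(values = values, grid = grid, sidecar = sidecar_path(path))
}

write_nifti_raw <- function(values, grid, path, datatype = "auto") {
  # keep the image non-internal (plain array backing) so geometry can be set
  img <- RNifti::asNifti(array(as.numeric(values), grid$dim))
  RNifti::pixdim(img) <- grid$spacing
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
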