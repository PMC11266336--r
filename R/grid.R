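#' Regular voxel grid
#'
#' Defines the geometry shared by activity images and label maps: array
#' dimensions, per-axis voxel spacing in mm, and the physical position (mm) of
#' the *center* of voxel (0,0,0). Voxel indices are 0-based in physical-space
#' formulas: the center of voxel (i,j,k) sits at `origin + c(i,j,k) * spacing`.
#'
#' @param dim integer triple, array dimensions (nx, ny, nz); all >= 1.
#' @param spacing numeric triple (or scalar, recycled), voxel size in mm; all > 0.
#' @param origin numeric triple, physical coordinate (mm) of the center of the
#'   first voxel. Default places the grid symmetrically about the origin.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(dim, spacing, origin = NULL) {
  dim <- as.integer(dim)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (length(dim) != 3L) stop("voxel_grid: 'dim' must have length 3")
  if (any(dim < 1L)) stop("voxel_grid: all dimensions must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel_grid: all spacing components must be > 0")
  if (is.null(origin)) origin <- -(dim - 1L) / 2 * spacing
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(dim = dim, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d, spacing %s mm, origin (%s) mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Physical coordinates of voxel centers along one axis
#'
#' @param grid a [voxel_grid()].
#' @param axis 1, 2 or 3.
#' @return numeric vector of length `grid$dim[axis]` (mm).
#' @export
grid_axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dim[axis]) - 1) * grid$spacing[axis]
}

#' Voxel volume of a grid
#'
#' @param grid a [voxel_grid()].
#' @param unit `"mm3"` or `"mL"`.
#' @return scalar volume of one voxel.
#' @export
voxel_volume <- function(grid, unit = c("mm3", "mL")) {
  unit <- match.arg(unit)
  v <- prod(grid$spacing)
  if (unit == "mL") v / 1000 else v
}

grids_equal <- function(g1, g2, tol = 1e-6) {
  identical(g1$dim, g2$dim) &&
    all(abs(g1$spacing - g2$spacing) <= tol * pmax(1, abs(g1$spacing))) &&
    all(abs(g1$origin - g2$origin) <= tol * pmax(1, abs(g1$origin)))
}

#' Full matrix of voxel-center coordinates (used by rasterization)
#'
#' @param grid a [voxel_grid()].
#' @param subset optional list of integer index vectors (1-based) per axis.
#' @return n x 3 matrix of physical coordinates (mm).
#' @keywords internal
grid_coords_matrix <- function(grid, subset = NULL) {
  ax <- lapply(1:3, function(a) {
    co <- grid_axis_coords(grid, a)
    if (!is.null(subset)) co[subset[[a]]] else co
  })
  n <- vapply(ax, length, 1L)
  cbind(rep(ax[[1]], times = n[2] * n[3]),
        rep(rep(ax[[2]], each = n[1]), times = n[3]),
        rep(ax[[3]], each = n[1] * n[2]))
}
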