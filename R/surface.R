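# Triangulated isosurface area by marching tetrahedra.
#
# Each grid cell (8 voxel centers) is split into 6 tetrahedra sharing the main
# diagonal; the 0.5-level surface is triangulated inside each tetrahedron by
# linear interpolation along its edges and the triangle areas are summed.
# This is a marching-cubes-style mesh area — not exposed-voxel-face counting,
# which overestimates the area of smooth objects by up to 50%.

tet_corner_offsets <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))

# 6-tetrahedron decomposition around the 1->7 diagonal (1-based corners)
tet_decomposition <- rbind(
  c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

tri_area_rows <- function(p, q, r) {
  u <- q - p; v <- r - p
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Isosurface area of a scalar field (marching tetrahedra)
#'
#' @param x 3-D numeric array (fractional occupancy in \[0, 1\]).
#' @param spacing per-axis voxel size, mm (scalar recycled).
#' @param level iso level (default 0.5).
#' @return total triangulated surface area, mm^2.
#' @export
mesh_surface_area <- function(x, spacing, level = 0.5) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  d <- dim(x)
  # zero-pad one layer so surfaces at the array edge are closed
  xp <- array(0, d + 2L)
  xp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- x
  d <- dim(xp)
  nc <- d - 1L
  # corner-value vectors over all cells
  corner_vals <- lapply(seq_len(8), function(c8) {
    o <- tet_corner_offsets[c8, ]
    as.vector(xp[(1 + o[1]):(nc[1] + o[1]),
                 (1 + o[2]):(nc[2] + o[2]),
                 (1 + o[3]):(nc[3] + o[3])])
  })
  ncell <- prod(nc)
  # physical coordinates of cell base corners (origin-free; area is invariant)
  cell_coord <- function(idx, axis) {
    i <- switch(axis,
                (idx - 1L) %% nc[1],
                ((idx - 1L) %/% nc[1]) %% nc[2],
                (idx - 1L) %/% (nc[1] * nc[2]))
    i * spacing[axis]
  }
  total <- 0
  for (t in seq_len(nrow(tet_decomposition))) {
    corners <- tet_decomposition[t, ]
    v <- lapply(corners, function(c8) corner_vals[[c8]])
    above <- lapply(v, function(vv) vv > level)
    caseid <- above[[1]] + 2L * above[[2]] + 4L * above[[3]] + 8L * above[[4]]
    active <- which(caseid != 0L & caseid != 15L)
    if (!length(active)) next
    offs <- lapply(corners, function(c8)
      tet_corner_offsets[c8, ] * spacing)
    pos <- function(vertex, idx)  # n x 3 coordinates of tet vertex
      cbind(cell_coord(idx, 1) + offs[[vertex]][1],
            cell_coord(idx, 2) + offs[[vertex]][2],
            cell_coord(idx, 3) + offs[[vertex]][3])
    interp <- function(i1, i2, idx) {
      vv1 <- v[[i1]][idx]; vv2 <- v[[i2]][idx]
      tt <- (level - vv1) / (vv2 - vv1)
      p1 <- pos(i1, idx); p2 <- pos(i2, idx)
      p1 + tt * (p2 - p1)
    }
    for (cs in setdiff(sort(unique(caseid[active])), c(0L, 15L))) {
      idx <- active[caseid[active] == cs]
      bits <- as.logical(bitwAnd(cs, c(1L, 2L, 4L, 8L)))
      A <- which(bits); B <- which(!bits)
      if (length(A) == 1L || length(A) == 3L) {
        lone <- if (length(A) == 1L) A else B
        rest <- setdiff(1:4, lone)
        p1 <- interp(lone, rest[1], idx)
        p2 <- interp(lone, rest[2], idx)
        p3 <- interp(lone, rest[3], idx)
        total <- total + sum(tri_area_rows(p1, p2, p3))
      } else {
        m1 <- interp(A[1], B[1], idx)
        m2 <- interp(A[1], B[2], idx)
        m3 <- interp(A[2], B[2], idx)
        m4 <- interp(A[2], B[1], idx)
        total <- total + sum(tri_area_rows(m1, m2, m3)) +
                         sum(tri_area_rows(m1, m3, m4))
      }
    }
  }
  total
}

#' Volume, surface and surface-to-volume ratio of a voxelized object
#'
#' Volume is the 0.5-thresholded voxel count times the voxel volume; surface
#' is the triangulated 0.5-isosurface mesh area ([mesh_surface_area()]).
#' Before meshing, the field is smoothed with a narrow Gaussian
#' (`presmooth_sigma` voxels): the tetrahedral triangulation of a sharp
#' (one-voxel) transition overestimates area by ~5-6% from residual staircase
#' zigzag, while the smoothing's curvature shrinkage stays below 1% for radii
#' of curvature above ~6 voxels. Accepts binary masks or, preferably, the
#' fractional occupancy from [rasterize_shape()].
#'
#' @param x 3-D occupancy (preferred) or binary mask array.
#' @param spacing per-axis voxel size, mm (scalar recycled).
#' @param presmooth_sigma Gaussian pre-smoothing width in voxels.
#' @return list with `volume_cm3`, `surface_cm2`, `sv_cm` (cm^-1).
#' @export
surface_to_volume <- function(x, spacing, presmooth_sigma = 0.6) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  mask <- x >= 0.5
  if (!any(mask)) stop("surface_to_volume: empty mask")
  volume_mm3 <- sum(mask) * prod(spacing)
  field <- x
  if (presmooth_sigma > 0) {
    taps <- gaussian_kernel_1d(presmooth_sigma, 1, 3)
    for (a in 1:3) field <- convolve_axis(field, taps, a)
  }
  surface_mm2 <- mesh_surface_area(field, spacing)
  list(volume_cm3 = volume_mm3 / 1e3,
       surface_cm2 = surface_mm2 / 1e2,
       sv_cm = (surface_mm2 / 1e2) / (volume_mm3 / 1e3))
}
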