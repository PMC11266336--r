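#' Activity-concentration table for the three modified IEC phantom series
#'
#' Background and target (spheres + kidneys) activity concentrations at the
#' start of each of the six acquisitions per phantom, with the associated
#' target-to-background ratio. Concentrations are in MBq/L as tabulated;
#' [phantom_spec()] converts to the canonical Bq/mL internally.
#'
#' @return data.frame with columns `phantom` (1-3), `pair`
#'   ("small"/"medium"/"large"), `background_MBq_L`, `target_MBq_L`, `tbr`.
#' @export
iec_activity_table <- function() {
  data.frame(
    phantom = rep(1:3, each = 6),
    pair = rep(c("small", "medium", "large"), each = 6),
    background_MBq_L = c(33.8, 39.7, 49.9, 65.1, 96.1, 190.2,
                         29.6, 34.8, 43.6, 58.6, 88.2, 171.7,
                         32.4, 38.4, 48.2, 62.1, 104.4, 192.1),
    target_MBq_L = c(378.7, 375.8, 374.9, 373.8, 372.7, 371.1,
                     354.8, 352.9, 351.7, 350.9, 349.9, 347.7,
                     357.5, 356.6, 355.6, 354.8, 354.1, 353.3),
    tbr = c(11.2, 9.5, 7.5, 5.7, 3.9, 2.0,
            12.0, 10.1, 8.1, 6.0, 4.0, 2.0,
            11.0, 9.3, 7.4, 5.7, 3.4, 1.8),
    stringsAsFactors = FALSE)
}

#' Standard IEC sphere-insert diameters (mm)
#' @export
iec_sphere_diameters <- function() c(10, 13, 17, 22, 28, 37)

#' Region labels of the assembled phantom
#'
#' Labels 1-2 kidneys (R, L), 3-8 spheres in increasing diameter, 9 lung
#' insert, 10 holder plate, 11 background; 0 is outside the body.
#' @return named integer vector.
#' @export
phantom_region_names <- function() {
  c(kidney_R = 1L, kidney_L = 2L,
    sphere_10mm = 3L, sphere_13mm = 4L, sphere_17mm = 5L,
    sphere_22mm = 6L, sphere_28mm = 7L, sphere_37mm = 8L,
    lung = 9L, holder = 10L, background = 11L)
}

#' Declarative description of one modified IEC phantom instance
#'
#' Geometry defaults reproduce an IEC body phantom (elliptical-cylinder
#' interior ~300 x 220 mm cross-section, 180 mm length) with a central cold
#' lung insert (51 mm diameter), a cold 10 mm holder plate (IEC outline
#' scaled 0.85, with a hole clearing the lung insert), six spheres
#' (10-37 mm) on a 57 mm ring in one axial plane, and two kidney surrogates
#' placed laterally below the sphere plane with their long axes
#' anterior-posterior. The layout keeps every structure >= 10 mm from every
#' other structure and from the body shell (validated on the rasterized
#' label map at assembly).
#'
#' @param kidneys list of two `kidney_surrogate` objects (R then L), or two
#'   `phantom_shape` kidney shapes.
#' @param background_conc,target_conc activity concentrations; interpreted in
#'   `conc_unit` (default MBq/L, converted x1000 to Bq/mL at ingest).
#' @param conc_unit `"MBq_per_L"` or `"Bq_per_mL"`.
#' @param grid working [voxel_grid()]; default 2.21 mm isotropic over a
#'   350 x 260 x 220 mm field of view.
#' @param sphere_diameters mm, placed on the ring in increasing size.
#' @param noise NULL or list(kappa=, seed=) forwarded to
#'   [simulate_observation()].
#' @param truth_mode `"fractional"` (default): boundary voxels mix
#'   concentrations by fractional occupancy; `"binary"`: truth is piecewise
#'   constant on the 0.5-threshold label partition.
#' @param supersample occupancy sub-sampling for rasterization.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(kidneys,
                         background_conc, target_conc,
                         conc_unit = c("MBq_per_L", "Bq_per_mL"),
                         grid = NULL,
                         sphere_diameters = iec_sphere_diameters(),
                         noise = NULL,
                         truth_mode = c("fractional", "binary"),
                         supersample = 3) {
  conc_unit <- match.arg(conc_unit)
  truth_mode <- match.arg(truth_mode)
  f <- if (conc_unit == "MBq_per_L") 1000 else 1
  background_conc <- background_conc * f
  target_conc <- target_conc * f
  if (background_conc <= 0 || target_conc <= 0)
    stop("phantom_spec: concentrations must be > 0")
  if (is.null(grid))
    grid <- voxel_grid(c(159, 118, 100), 2.21)
  kid_shapes <- lapply(kidneys, function(k) {
    if (inherits(k, "kidney_surrogate")) k$shape
    else if (inherits(k, "phantom_shape") && k$type == "kidney") k
    else stop("phantom_spec: kidneys must be kidney_surrogate or kidney shapes")
  })
  if (length(kid_shapes) != 2L) stop("phantom_spec: exactly two kidneys required")
  structure(list(
    grid = grid,
    body = list(semiaxes = c(150, 110), zrange = c(-90, 90)),
    lung = list(radius = 25.5),
    holder = list(zrange = c(-78, -68), scale = 0.85, hole_radius = 36),
    sphere_diameters = sort(sphere_diameters),
    sphere_ring_radius = 57,
    sphere_plane_z = 45,
    # large spheres at +-90 deg (far from the kidneys on the x axis)
    sphere_angles_deg = c(210, 30, 330, 150, 270, 90),
    kidney_shapes = kid_shapes,
    kidney_centers = list(c(75, 0, -35), c(-75, 0, -35)),
    background_conc = background_conc,
    target_conc = target_conc,
    noise = noise,
    truth_mode = truth_mode,
    supersample = supersample),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: bg %.0f Bq/mL, target %.0f Bq/mL (TBR %.1f), %s truth\n",
              x$background_conc, x$target_conc,
              x$target_conc / x$background_conc, x$truth_mode))
  print(x$grid)
  invisible(x)
}

phantom_shapes <- function(spec) {
  body <- shape_elliptical_cylinder(c(0, 0), spec$body$semiaxes,
                                    spec$body$zrange)
  lung <- shape_cylinder(c(0, 0), spec$lung$radius,
                         spec$body$zrange + c(10, -10))
  holder <- shape_elliptical_cylinder(c(0, 0),
                                      spec$body$semiaxes * spec$holder$scale,
                                      spec$holder$zrange,
                                      hole_radius = spec$holder$hole_radius)
  ang <- spec$sphere_angles_deg * pi / 180
  spheres <- lapply(seq_along(spec$sphere_diameters), function(i)
    shape_sphere(c(spec$sphere_ring_radius * cos(ang[i]),
                   spec$sphere_ring_radius * sin(ang[i]),
                   spec$sphere_plane_z),
                 spec$sphere_diameters[i] / 2))
  kidneys <- lapply(1:2, function(i) {
    sh <- spec$kidney_shapes[[i]]
    sh$center <- spec$kidney_centers[[i]]
    # mirror the left kidney so the hilum faces medially on both sides
    if (i == 2L) sh$orient <- sh$orient %*% diag(c(1, -1, 1))
    sh
  })
  list(body = body, lung = lung, holder = holder,
       spheres = spheres, kidneys = kidneys)
}

# minimum-distance check between rasterized structures (and the body shell)
check_clearance <- function(masks, body_mask, spacing, min_mm = 10) {
  grow <- function(m) {
    kern <- ball_offsets(min_mm, spacing)
    fft_convolve_kernel(m + 0, kern) > 0.5
  }
  nm <- names(masks)
  grown <- lapply(masks, grow)
  for (i in seq_along(masks)) {
    if (any(grown[[i]] & !body_mask))
      stop("phantom clearance violation: ", nm[i],
           " is closer than ", min_mm, " mm to the body shell")
    for (j in seq_along(masks)) {
      if (j <= i) next
      if (any(grown[[i]] & masks[[j]]))
        stop("phantom clearance violation: ", nm[i], " and ", nm[j],
             " are closer than ", min_mm, " mm")
    }
  }
  invisible(TRUE)
}

#' Assemble a phantom: ground-truth activity image and 11-region label map
#'
#' Rasterizes all structures, validates the >= 10 mm clearance invariant,
#' and builds the truth image (fractional-occupancy mixing at boundaries by
#' default) and the 0.5-threshold label partition: labels 1-11 exactly cover
#' the body support; lung insert and holder are 0-activity; outside the body
#' is 0 with label 0.
#'
#' @param spec a [phantom_spec()].
#' @param check_clearances logical; skip only when reusing a layout already
#'   validated (e.g. inside [tbr_series()]).
#' @return list with `truth` ([activity_image()]), `labels` ([label_map()]),
#'   and `occupancy` (per-structure occupancy fields, reused by
#'   [tbr_series()]).
#' @export
assemble_phantom <- function(spec, check_clearances = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  ss <- spec$supersample
  sh <- phantom_shapes(spec)
  occ_body <- rasterize_shape(sh$body, g, ss)
  occ <- list()
  occ$kidney_R <- rasterize_shape(sh$kidneys[[1]], g, ss)
  occ$kidney_L <- rasterize_shape(sh$kidneys[[2]], g, ss)
  for (i in seq_along(sh$spheres))
    occ[[sprintf("sphere_%dmm", spec$sphere_diameters[i])]] <-
      rasterize_shape(sh$spheres[[i]], g, ss)
  occ$lung <- rasterize_shape(sh$lung, g, ss)
  occ$holder <- rasterize_shape(sh$holder, g, ss)

  names_tab <- phantom_region_names()
  struct_names <- setdiff(names(names_tab), "background")
  if (!identical(sort(names(occ)), sort(struct_names)))
    stop("assemble_phantom: sphere diameters must be the standard IEC set ",
         "matching the label table")

  body_mask <- occ_body >= 0.5
  masks <- lapply(occ, function(o) o >= 0.5)
  if (check_clearances)
    check_clearance(masks, body_mask, g$spacing, min_mm = 10)

  labels <- array(0L, g$dim)
  labels[body_mask] <- names_tab[["background"]]
  for (nm in struct_names)
    labels[masks[[nm]]] <- names_tab[[nm]]
  lmap <- label_map(labels, g, names_tab)

  occ_target <- occ$kidney_R + occ$kidney_L
  for (d in spec$sphere_diameters)
    occ_target <- occ_target + occ[[sprintf("sphere_%dmm", d)]]
  occ_cold <- occ$lung + occ$holder
  occupancy <- list(body = occ_body, target = occ_target, cold = occ_cold,
                    structures = occ)

  truth <- phantom_truth(spec, occupancy, lmap)
  list(truth = truth, labels = lmap, occupancy = occupancy, spec = spec)
}

phantom_truth <- function(spec, occupancy, lmap) {
  if (spec$truth_mode == "fractional") {
    occ_bg <- pmax(0, occupancy$body - occupancy$target - occupancy$cold)
    vals <- spec$target_conc * occupancy$target + spec$background_conc * occ_bg
  } else {
    lab <- lmap$labels
    target_labels <- phantom_region_names()[c("kidney_R", "kidney_L",
      sprintf("sphere_%dmm", spec$sphere_diameters))]
    vals <- array(0, spec$grid$dim)
    tmask <- lab %in% target_labels
    dim(tmask) <- spec$grid$dim
    vals[tmask] <- spec$target_conc
    vals[lab == phantom_region_names()[["background"]]] <- spec$background_conc
  }
  activity_image(array(vals, spec$grid$dim), spec$grid, unit = "Bq_per_mL")
}

#' Truth-image series over a table of activity concentrations
#'
#' Builds one truth image per row of a concentration table (columns
#' `background_MBq_L`, `target_MBq_L`, or `background`/`target` in Bq/mL),
#' all sharing one label map — mirroring a phantom refilled by adding
#' background activity between acquisitions. Errors if the background
#' decreases across rows (activity can only be added).
#'
#' @param spec a [phantom_spec()] (its own concentrations are ignored).
#' @param conc_table data.frame of concentrations, one row per acquisition.
#' @return list with `truths` (list of [activity_image()]), `labels`,
#'   `tbr` (per-row target/background), `occupancy`, `spec`.
#' @export
tbr_series <- function(spec, conc_table) {
  if (!is.null(conc_table$background_MBq_L)) {
    bg <- conc_table$background_MBq_L * 1000
    tg <- conc_table$target_MBq_L * 1000
  } else {
    bg <- conc_table$background
    tg <- conc_table$target
  }
  if (any(bg <= 0) || any(tg <= 0))
    stop("tbr_series: concentrations must be positive")
  if (any(diff(bg) < 0))
    stop("tbr_series: background decreases across rows; ",
         "activity can only be added")
  asm <- assemble_phantom(spec)
  truths <- lapply(seq_along(bg), function(i) {
    s <- spec
    s$background_conc <- bg[i]
    s$target_conc <- tg[i]
    phantom_truth(s, asm$occupancy, asm$labels)
  })
  list(truths = truths, labels = asm$labels, tbr = tg / bg,
       occupancy = asm$occupancy, spec = spec)
}
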