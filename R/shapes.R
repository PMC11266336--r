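# Analytic shape primitives used by the phantom generator.
#
# Every shape answers two questions: does a physical point lie inside
# (`shape_contains`, vectorized over an n x 3 matrix of mm coordinates), and
# what is its axis-aligned bounding box (`shape_bbox`, 2 x 3 matrix lo/hi).
# Extruded shapes (cylinders, plates) also expose a separable fast path used
# by the rasterizer.

#' Analytic shapes for phantom construction
#'
#' Constructors for the solid primitives the phantom generator rasterizes:
#' spheres, ellipsoids, extruded (elliptical) cylinders with an optional
#' central hole, and the parametric kidney "bean" (ellipsoid minus a hilum
#' indentation sphere).
#'
#' @param center physical center, mm (length 3; length 2 for extruded shapes,
#'   the in-plane center).
#' @param radius sphere / cylinder / hole radius, mm.
#' @param semiaxes ellipsoid semi-axes, mm (length 3; length 2 in-plane for
#'   elliptical cylinders).
#' @param zrange length-2 extrusion range along z, mm.
#' @return an object of class `phantom_shape`.
#' @name shapes
NULL

#' @rdname shapes
#' @export
shape_sphere <- function(center, radius) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(type = "sphere", center = as.numeric(center),
                 radius = as.numeric(radius)),
            class = "phantom_shape")
}

#' @rdname shapes
#' @export
shape_ellipsoid <- function(center, semiaxes) {
  stopifnot(length(center) == 3, length(semiaxes) == 3, all(semiaxes > 0))
  structure(list(type = "ellipsoid", center = as.numeric(center),
                 semiaxes = as.numeric(semiaxes)),
            class = "phantom_shape")
}

#' @rdname shapes
#' @param hole_radius radius of a circular hole around the in-plane center
#'   (0 = no hole); used for the holder plate that clears the lung insert.
#' @export
shape_elliptical_cylinder <- function(center, semiaxes, zrange,
                                      hole_radius = 0) {
  stopifnot(length(center) == 2, length(semiaxes) == 2, length(zrange) == 2,
            all(semiaxes > 0), zrange[2] > zrange[1], hole_radius >= 0)
  structure(list(type = "ecyl", center = as.numeric(center),
                 semiaxes = as.numeric(semiaxes),
                 zrange = as.numeric(zrange),
                 hole_radius = as.numeric(hole_radius)),
            class = "phantom_shape")
}

#' @rdname shapes
#' @export
shape_cylinder <- function(center, radius, zrange) {
  shape_elliptical_cylinder(center, c(radius, radius), zrange)
}

#' @rdname shapes
#' @param scale isotropic scale `a`, mm: the long semi-axis of the bean before
#'   elongation. The base semi-axes follow the anatomical aspect ratio
#'   `aspect` = (1, 0.55, 0.35) in local (long, wide, thick) coordinates.
#' @param elongation multiplier on the long semi-axis (>= 1).
#' @param bite_radius_frac hilum indentation sphere radius as a fraction of
#'   the wide semi-axis.
#' @param bite_penetration_frac indentation depth knob in [0, 1]: 0 means the
#'   bite sphere is tangent from outside (no indentation); 1 buries its
#'   center `0.6 * wide semi-axis` beyond the surface.
#' @param lobulation_amp relative amplitude of a smooth cosine surface
#'   lobulation (0 = smooth ellipsoid boundary). Emulates the surface
#'   roughness / fetal lobulation of CT-segmented printed kidneys, whose S:V
#'   ratios exceed what any smooth bean can reach; engaged by the surrogate
#'   fitter only when the indentation knob saturates.
#' @param lobulation_waves number of lobulation periods across each semi-axis.
#' @param orient 3 x 3 orthonormal matrix mapping local (long, wide, thick)
#'   axes to world axes; default long axis along world y, wide along x.
#' @export
shape_kidney <- function(center = c(0, 0, 0), scale,
                         elongation = 1,
                         bite_radius_frac = 0.85,
                         bite_penetration_frac = 0,
                         lobulation_amp = 0,
                         lobulation_waves = 4,
                         aspect = c(1, 0.55, 0.35),
                         orient = NULL) {
  stopifnot(scale > 0, elongation > 0, bite_radius_frac > 0,
            bite_penetration_frac >= 0, lobulation_amp >= 0)
  if (is.null(orient))  # local long -> y, wide -> x, thick -> z
    orient <- matrix(c(0, 1, 0,  1, 0, 0,  0, 0, 1), 3, 3)
  semi <- scale * aspect
  semi[1] <- semi[1] * elongation
  b <- semi[2]
  r_b <- bite_radius_frac * b
  # bite-sphere center along local +wide axis; penetration measured from the
  # tangent-from-outside position (b + r_b) down to b + r_b - p_max
  p_max <- r_b + 0.6 * b
  v0 <- b + r_b - bite_penetration_frac * p_max
  structure(list(type = "kidney", center = as.numeric(center),
                 semiaxes = semi, orient = orient,
                 bite_radius = r_b, bite_center_local = c(0, v0, 0),
                 scale = scale, elongation = elongation,
                 bite_radius_frac = bite_radius_frac,
                 bite_penetration_frac = bite_penetration_frac,
                 lobulation_amp = lobulation_amp,
                 lobulation_waves = lobulation_waves,
                 aspect = aspect),
            class = "phantom_shape")
}

#' Point-membership test for a shape
#' @param shape a `phantom_shape`.
#' @param pts n x 3 matrix of physical coordinates, mm.
#' @return logical vector of length n.
#' @export
shape_contains <- function(shape, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  switch(shape$type,
    sphere = {
      d2 <- (pts[, 1] - shape$center[1])^2 + (pts[, 2] - shape$center[2])^2 +
            (pts[, 3] - shape$center[3])^2
      d2 <= shape$radius^2
    },
    ellipsoid = {
      u <- sweep(pts, 2, shape$center)
      (u[, 1] / shape$semiaxes[1])^2 + (u[, 2] / shape$semiaxes[2])^2 +
        (u[, 3] / shape$semiaxes[3])^2 <= 1
    },
    ecyl = {
      shape_contains_2d(shape, pts[, 1:2, drop = FALSE]) &
        pts[, 3] >= shape$zrange[1] & pts[, 3] <= shape$zrange[2]
    },
    kidney = {
      u <- sweep(pts, 2, shape$center) %*% shape$orient  # world -> local
      q <- sqrt((u[, 1] / shape$semiaxes[1])^2 + (u[, 2] / shape$semiaxes[2])^2 +
                (u[, 3] / shape$semiaxes[3])^2)
      thr <- 1
      if (shape$lobulation_amp > 0) {
        k <- pi * shape$lobulation_waves
        thr <- 1 + shape$lobulation_amp *
          cos(k * u[, 1] / shape$semiaxes[1]) *
          cos(k * u[, 2] / shape$semiaxes[2]) *
          cos(k * u[, 3] / shape$semiaxes[3])
      }
      inside <- q <= thr
      bc <- shape$bite_center_local
      bite <- (u[, 1] - bc[1])^2 + (u[, 2] - bc[2])^2 + (u[, 3] - bc[3])^2 <=
        shape$bite_radius^2
      inside & !bite
    },
    stop("unknown shape type ", shape$type))
}

# in-plane membership for extruded shapes (separable rasterization fast path)
shape_contains_2d <- function(shape, pts2) {
  u <- sweep(pts2, 2, shape$center)
  inside <- (u[, 1] / shape$semiaxes[1])^2 + (u[, 2] / shape$semiaxes[2])^2 <= 1
  if (shape$hole_radius > 0)
    inside <- inside & (u[, 1]^2 + u[, 2]^2 > shape$hole_radius^2)
  inside
}

#' Axis-aligned bounding box of a shape
#' @param shape a `phantom_shape`.
#' @return 2 x 3 matrix: rows are lo and hi (mm).
#' @export
shape_bbox <- function(shape) {
  switch(shape$type,
    sphere = rbind(shape$center - shape$radius, shape$center + shape$radius),
    ellipsoid = rbind(shape$center - shape$semiaxes,
                      shape$center + shape$semiaxes),
    ecyl = rbind(c(shape$center - shape$semiaxes, shape$zrange[1]),
                 c(shape$center + shape$semiaxes, shape$zrange[2])),
    kidney = {
      half <- abs(shape$orient) %*% (shape$semiaxes * (1 + shape$lobulation_amp))
      rbind(shape$center - as.vector(half), shape$center + as.vector(half))
    },
    stop("unknown shape type ", shape$type))
}
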