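# Frame, localizer and scan-plane geometry.
#
# Frame coordinate convention: origin at the center of the frame base,
# +y anterior, +z superior, +x completing a right-handed system (the
# patient-right lateral direction). All lengths are millimeters; angles
# are radians internally and degrees in every external interface.

.UNIT_TOL <- 1e-12

.norm2 <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .norm2(v)
  if (!is.finite(n) || n < 1e-300)
    stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

#' Construct a rod axis line
#'
#' A rod's cylindrical axis as a finite 3D line segment in frame
#' coordinates. Rods are modeled as mathematical lines of zero radius;
#' only the center of a rod's cross-section in a scan image is ever
#' used downstream.
#'
#' @param base Numeric length-3, the segment start point (mm).
#' @param direction Numeric length-3 direction; normalized internally.
#' @param length Segment length along the axis (mm), positive.
#' @param label Rod label, one of `"A"`, `"B"`, `"C"`.
#' @return An object of class `"rod_line"`.
#' @export
rod_line <- function(base, direction, length, label = "B") {
  stopifnot(length(base) == 3, length(direction) == 3, is.numeric(length))
  if (!all(is.finite(base)) || !all(is.finite(direction)))
    stop("rod base and direction must be finite", call. = FALSE)
  if (length <= 0) stop("rod length must be positive", call. = FALSE)
  structure(list(base = as.numeric(base), direction = .unit(direction),
                 length = as.numeric(length), label = as.character(label)),
            class = "rod_line")
}

#' Sturm-Pastyr localizer geometry
#'
#' A V-shaped localizer: two diagonal rods A and C and one vertical rod
#' B whose cylindrical axes are coplanar and meet at the apex. At local
#' height h above the apex, rod B sits on the vertical axis while rods A
#' and C are offset by -h*tan(alpha) and +h*tan(alpha) along the
#' in-plane axis, so an untilted slice at height h yields
#' inter-fiducial distances d_AB = d_BC = h*tan(alpha) and
#' d_AC = 2*h*tan(alpha).
#'
#' @param apex Numeric length-3, the shared rod base (mm).
#' @param in_plane Unit 3-vector, horizontal direction within the
#'   localizer plane (rod C opens toward `+in_plane`).
#' @param up Unit 3-vector, vertical direction (default frame +z).
#' @param tan_alpha Tangent of the V half-angle, positive.
#' @param extent Vertical span of the rods (mm), positive.
#' @param id Localizer identifier string.
#' @return An object of class `"sp_localizer"`.
#' @export
sp_localizer <- function(apex, in_plane, up = c(0, 0, 1), tan_alpha = 0.8,
                         extent = 190, id = "sp") {
  stopifnot(length(apex) == 3)
  in_plane <- .unit(in_plane); up <- .unit(up)
  if (abs(sum(in_plane * up)) > .UNIT_TOL)
    stop("in_plane and up axes must be orthogonal", call. = FALSE)
  if (!is.finite(tan_alpha) || tan_alpha <= 0)
    stop("tan_alpha must be positive", call. = FALSE)
  if (tan_alpha >= tan(pi / 2 - 1e-9))
    stop("half-angle must lie in (0, pi/2)", call. = FALSE)
  if (!is.finite(extent) || extent <= 0)
    stop("extent must be positive", call. = FALSE)
  structure(list(apex = as.numeric(apex), in_plane = in_plane, up = up,
                 tan_alpha = tan_alpha, extent = extent, id = id),
            class = "sp_localizer")
}

#' Rod axes of a Sturm-Pastyr localizer
#'
#' @param geom An `"sp_localizer"` object.
#' @return Named list of three `"rod_line"` objects `A`, `B`, `C`.
#' @export
sp_rods <- function(geom) {
  t <- geom$tan_alpha
  diag_len <- geom$extent * sqrt(1 + t^2)
  list(
    A = rod_line(geom$apex, geom$up - t * geom$in_plane, diag_len, "A"),
    B = rod_line(geom$apex, geom$up, geom$extent, "B"),
    C = rod_line(geom$apex, geom$up + t * geom$in_plane, diag_len, "C")
  )
}

#' N-localizer geometry
#'
#' Two vertical rods joined by one diagonal rod in an N shape: rod A is
#' vertical at `-width/2` along the in-plane axis, rod C vertical at
#' `+width/2`, and the diagonal rod B runs from the top of rod A to the
#' bottom of rod C. All three axes are coplanar.
#'
#' @param apex Numeric length-3, center of the localizer base (mm).
#' @param in_plane Unit 3-vector, horizontal direction within the
#'   localizer plane.
#' @param up Unit 3-vector, vertical direction.
#' @param width Horizontal separation of the vertical rods (mm).
#' @param height Vertical span of the rods (mm).
#' @param id Localizer identifier string.
#' @return An object of class `"n_localizer"`.
#' @export
n_localizer <- function(apex, in_plane, up = c(0, 0, 1), width = 120,
                        height = 140, id = "n") {
  stopifnot(length(apex) == 3)
  in_plane <- .unit(in_plane); up <- .unit(up)
  if (abs(sum(in_plane * up)) > .UNIT_TOL)
    stop("in_plane and up axes must be orthogonal", call. = FALSE)
  if (width <= 0 || height <= 0)
    stop("width and height must be positive", call. = FALSE)
  structure(list(apex = as.numeric(apex), in_plane = in_plane, up = up,
                 width = width, height = height, id = id),
            class = "n_localizer")
}

#' Rod axes of an N-localizer
#'
#' @param geom An `"n_localizer"` object.
#' @return Named list of `"rod_line"` objects `A` (vertical), `B`
#'   (diagonal, from top of A to bottom of C), `C` (vertical).
#' @export
n_rods <- function(geom) {
  w2 <- geom$width / 2
  baseA <- geom$apex - w2 * geom$in_plane
  baseC <- geom$apex + w2 * geom$in_plane
  topA <- baseA + geom$height * geom$up
  diag_len <- .norm2(baseC - topA)
  list(
    A = rod_line(baseA, geom$up, geom$height, "A"),
    B = rod_line(topA, baseC - topA, diag_len, "B"),
    C = rod_line(baseC, geom$up, geom$height, "C")
  )
}

.ASPECTS <- c("anterior", "left", "right", "posterior")

# In-plane tangent axes rotate with the aspect (clockwise viewed from
# above), so four localizers are exact 90-degree rotations of one
# another; this is what makes the four-localizer target RMSe curves
# superimpose under rotational symmetry.
.aspect_frame <- function(aspect, radius) {
  switch(aspect,
    anterior  = list(apex = c(0, radius, 0),  in_plane = c(1, 0, 0)),
    posterior = list(apex = c(0, -radius, 0), in_plane = c(-1, 0, 0)),
    right     = list(apex = c(radius, 0, 0),  in_plane = c(0, -1, 0)),
    left      = list(apex = c(-radius, 0, 0), in_plane = c(0, 1, 0)),
    stop("unknown frame aspect: ", aspect, call. = FALSE)
  )
}

#' Build a stereotactic frame with attached localizers
#'
#' Places Sturm-Pastyr or N-localizers on the named aspects of a
#' circular frame of the given radius. Localizer planes are vertical
#' and tangent to the frame at each aspect; four localizers sit at 90
#' degree intervals about the frame axis. The classic configuration
#' uses three Sturm-Pastyr localizers (anterior, left, right); an
#' optional fourth occupies the posterior aspect.
#'
#' @param type `"sp"` or `"n"`.
#' @param aspects Character vector of aspects, a subset of
#'   `c("anterior", "left", "right", "posterior")`.
#' @param radius Placement radius (mm), positive.
#' @param tan_alpha,extent Sturm-Pastyr parameters (see
#'   [sp_localizer()]).
#' @param n_width,n_height N-localizer parameters (see
#'   [n_localizer()]).
#' @return An object of class `"stereo_frame"`: a list with elements
#'   `type`, `radius`, and `localizers` (named list of geometries in
#'   the order given).
#' @export
build_frame <- function(type = c("sp", "n"),
                        aspects = c("anterior", "left", "right"),
                        radius = 100, tan_alpha = 0.8, extent = 190,
                        n_width = 120, n_height = 140) {
  type <- match.arg(type)
  aspects <- as.character(aspects)
  if (length(aspects) < 1 || anyDuplicated(aspects))
    stop("aspects must be distinct", call. = FALSE)
  bad <- setdiff(aspects, .ASPECTS)
  if (length(bad))
    stop("unknown frame aspect(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.finite(radius) || radius <= 0)
    stop("radius must be positive", call. = FALSE)
  locs <- lapply(aspects, function(a) {
    af <- .aspect_frame(a, radius)
    if (type == "sp")
      sp_localizer(af$apex, af$in_plane, tan_alpha = tan_alpha,
                   extent = extent, id = a)
    else
      n_localizer(af$apex, af$in_plane, width = n_width,
                  height = n_height, id = a)
  })
  names(locs) <- aspects
  structure(list(type = type, radius = radius, localizers = locs,
                 tan_alpha = if (type == "sp") tan_alpha else NA_real_,
                 extent = if (type == "sp") extent else n_height),
            class = "stereo_frame")
}

#' @export
print.stereo_frame <- function(x, ...) {
  cat(sprintf("<stereo_frame> %s localizers (%s), radius %g mm\n",
              toupper(x$type), paste(names(x$localizers), collapse = ", "),
              x$radius))
  invisible(x)
}

#' Construct a scan-plane pose
#'
#' The CT slice as an oriented plane with an orthonormal in-plane
#' (u, v) chart. The plane passes through `(0, 0, z0)` on the frame's
#' central vertical axis and is tilted anteroposteriorly by `theta`
#' (positive = anterior higher), i.e. its points satisfy
#' `z = z0 + y * tan(theta)`. The chart axis `e_u` is the frame +x
#' direction, so `u` stays aligned with left-right; the chart is an
#' isometry, which is what makes image distances usable as 3D
#' distances.
#'
#' @param z0 Plane height on the central axis (mm).
#' @param theta Anteroposterior tilt (radians), `|theta| < pi/2`.
#' @return An object of class `"scan_plane"` with elements `z0`,
#'   `theta`, `origin`, `e_u`, `e_v`, `normal`.
#' @export
make_plane <- function(z0, theta = 0) {
  if (!is.finite(z0) || !is.finite(theta))
    stop("z0 and theta must be finite", call. = FALSE)
  if (abs(theta) >= pi / 2)
    stop("|theta| must be smaller than pi/2", call. = FALSE)
  structure(list(
    z0 = z0, theta = theta,
    origin = c(0, 0, z0),
    e_u = c(1, 0, 0),
    e_v = c(0, cos(theta), sin(theta)),
    normal = c(0, -sin(theta), cos(theta))
  ), class = "scan_plane")
}

#' @export
print.scan_plane <- function(x, ...) {
  cat(sprintf("<scan_plane> z0 = %g mm, tilt = %g deg\n",
              x$z0, x$theta * 180 / pi))
  invisible(x)
}

#' Intersect a rod axis with a scan plane
#'
#' @param rod A `"rod_line"` object.
#' @param plane A `"scan_plane"` object.
#' @param tol Tolerance (mm) on the segment-extent check.
#' @return Numeric length-3 frame point lying on both the rod axis and
#'   the plane.
#' @export
intersect_rod_plane <- function(rod, plane, tol = 1e-9) {
  denom <- sum(plane$normal * rod$direction)
  if (abs(denom) < 1e-12)
    stop("degenerate geometry: rod axis parallel to the scan plane",
         call. = FALSE)
  s <- sum(plane$normal * (plane$origin - rod$base)) / denom
  if (s < -tol || s > rod$length + tol)
    stop(sprintf(
      "scan plane misses rod %s: intersection at %.3f mm along a %.3f mm rod",
      rod$label, s, rod$length), call. = FALSE)
  rod$base + s * rod$direction
}

#' Chart a frame point into image coordinates
#'
#' Projects an on-plane 3D point into the plane's 2D (u, v) chart. The
#' chart is an isometry: distances between image points equal the 3D
#' distances between the corresponding frame points.
#'
#' @param p Numeric length-3 frame point, on the plane to within `tol`.
#' @param plane A `"scan_plane"` object.
#' @param tol Off-plane tolerance (mm).
#' @return Numeric length-2 `(u, v)` in mm.
#' @export
to_image <- function(p, plane, tol = 1e-6) {
  stopifnot(length(p) == 3)
  d <- p - plane$origin
  off <- abs(sum(d * plane$normal))
  if (off > tol)
    stop(sprintf("point is %.3g mm off the scan plane", off), call. = FALSE)
  c(u = sum(d * plane$e_u), v = sum(d * plane$e_v))
}

#' Map image coordinates back to a frame point
#'
#' Inverse of [to_image()]: returns the 3D frame point at chart
#' coordinates `(u, v)` on the plane.
#'
#' @param q Numeric length-2 `(u, v)` in mm.
#' @param plane A `"scan_plane"` object.
#' @return Numeric length-3 frame point.
#' @export
to_frame <- function(q, plane) {
  stopifnot(length(q) == 2)
  plane$origin + q[[1]] * plane$e_u + q[[2]] * plane$e_v
}

# Lowest z reached by the plane within the placement radius; a slice
# that would cut the frame base (z < 0 anywhere within the radius) is
# invalid, which is why the minimum usable height grows with tilt.
.plane_base_clearance <- function(plane, radius) {
  plane$z0 - radius * abs(tan(plane$theta))
}
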