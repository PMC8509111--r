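# N-localizer forward model and inverse.
#
# The diagonal rod's fiducial divides the segment between the two
# vertical rods' fiducials in the same ratio that the slice divides
# the diagonal rod, so the crossing point on the diagonal is recovered
# by linear interpolation — exactly, at any tilt, because all three
# fiducial centers lie on the intersection line of the two planes.
# The vertical rods contribute only their fixed frame (x, y), which
# tightens the fit in x and y but carries no height information.

#' Forward model: fiducial centers created by an N-localizer
#'
#' @param geom An `"n_localizer"`.
#' @param plane A `"scan_plane"`.
#' @return A `"fiducial_set"` with `A` and `C` the vertical rods and
#'   `B` the diagonal fiducial between them.
#' @export
n_forward <- function(geom, plane) {
  rods <- n_rods(geom)
  pts <- lapply(rods, intersect_rod_plane, plane = plane)
  fiducial_set(to_image(pts$A, plane), to_image(pts$B, plane),
               to_image(pts$C, plane), id = geom$id)
}

#' N-localizer inverse
#'
#' Computes the fraction `f = d_AB / d_AC` and interpolates the
#' diagonal rod's 3D segment at that fraction, yielding the frame
#' point where the slice crosses the diagonal. Exact on noise-free
#' input at any tilt angle; under noise the solution remains on the
#' diagonal axis by construction.
#'
#' @param fid A `"fiducial_set"` from an N-localizer.
#' @param geom The matching `"n_localizer"`.
#' @param tol Tolerance on the extent check `0 <= f <= 1`.
#' @return An object of class `"n_solution"`: list with `pB` (frame
#'   point on the diagonal), `f` (interpolation fraction), and `xyA`,
#'   `xyC` (the vertical rods' fixed frame `(x, y)` pairs).
#' @export
n_solve <- function(fid, geom, tol = 1e-9) {
  d <- fiducial_distances(fid)
  if (!is.finite(d[["AC"]]) || d[["AC"]] <= 0)
    stop("N-localizer solve requires d_AC > 0", call. = FALSE)
  f <- d[["AB"]] / d[["AC"]]
  if (f < -tol || f > 1 + tol)
    stop(sprintf(
      "diagonal fraction f = %.4f outside [0, 1]: slice misses the diagonal rod",
      f), call. = FALSE)
  f <- min(max(f, 0), 1)
  rods <- n_rods(geom)
  e1 <- rods$B$base
  e2 <- rods$B$base + rods$B$length * rods$B$direction
  structure(list(
    pB = e1 + f * (e2 - e1), f = f,
    xyA = rods$A$base[1:2], xyC = rods$C$base[1:2],
    id = fid$id
  ), class = "n_solution")
}

#' @export
print.n_solution <- function(x, ...) {
  cat(sprintf("<n_solution> %s: f = %.4f, pB = (%.3f, %.3f, %.3f) mm\n",
              x$id, x$f, x$pB[1], x$pB[2], x$pB[3]))
  invisible(x)
}

#' @export
correspondences.n_solution <- function(sol, fid) {
  data.frame(
    localizer = fid$id, label = c("A", "B", "C"),
    u = fid$uv[, "u"], v = fid$uv[, "v"],
    x = c(sol$xyA[1], sol$pB[1], sol$xyC[1]),
    y = c(sol$xyA[2], sol$pB[2], sol$xyC[2]),
    z = c(NA_real_, sol$pB[3], NA_real_),
    kind = c("xy_only", "full", "xy_only"), row.names = NULL
  )
}
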