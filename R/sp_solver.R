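# Sturm-Pastyr forward model and inverses.
#
# A slice through the V-shaped localizer yields three fiducial centers
# whose pairwise image distances d_AB, d_BC, d_AC encode where the
# slice cut the rods. Noise-free centers are collinear, so
# d_AC = d_AB + d_BC and the distances carry a single degree of
# freedom; image noise breaks collinearity and makes the three
# distances linearly independent, which the three-point solve exploits
# to recover one point per rod axis instead of one point per localizer.

#' Measured fiducial centers of one localizer
#'
#' @param uvA,uvB,uvC Numeric length-2 image coordinates (mm) of the
#'   fiducial centers of rods A, B and C.
#' @param id Localizer identifier.
#' @return An object of class `"fiducial_set"` holding a 3 x 2 matrix
#'   `uv` with rows `A`, `B`, `C`. Distances are always recomputed
#'   from the stored centers, never stored independently; see
#'   [fiducial_distances()].
#' @export
fiducial_set <- function(uvA, uvB, uvC, id = "sp") {
  uv <- rbind(A = as.numeric(uvA), B = as.numeric(uvB), C = as.numeric(uvC))
  if (!all(is.finite(uv)) || ncol(uv) != 2)
    stop("fiducial centers must be finite (u, v) pairs", call. = FALSE)
  colnames(uv) <- c("u", "v")
  structure(list(id = id, uv = uv), class = "fiducial_set")
}

#' Inter-fiducial distances of a fiducial set
#'
#' @param fid A `"fiducial_set"`.
#' @return Named numeric `c(AB, BC, AC)` of Euclidean distances (mm)
#'   between the stored centers.
#' @export
fiducial_distances <- function(fid) {
  uv <- fid$uv
  d <- function(i, j) sqrt(sum((uv[i, ] - uv[j, ])^2))
  c(AB = d("A", "B"), BC = d("B", "C"), AC = d("A", "C"))
}

#' Collinearity residual d_AC - (d_AB + d_BC)
#'
#' Zero (to rounding) for noise-free centers, which are collinear;
#' nonzero with probability one under fiducial-center noise. A useful
#' per-localizer noise diagnostic.
#'
#' @param fid A `"fiducial_set"`.
#' @return Residual in mm (nonpositive up to rounding, by the triangle
#'   inequality).
#' @export
collinearity_residual <- function(fid) {
  d <- fiducial_distances(fid)
  unname(d["AC"] - d["AB"] - d["BC"])
}

#' @export
print.fiducial_set <- function(x, ...) {
  d <- fiducial_distances(x)
  cat(sprintf("<fiducial_set> %s: d_AB %.3f, d_BC %.3f, d_AC %.3f mm\n",
              x$id, d["AB"], d["BC"], d["AC"]))
  invisible(x)
}

#' Forward model: fiducial centers created by a Sturm-Pastyr localizer
#'
#' Intersects the scan plane with the three rod axes and charts the
#' intersection points into image coordinates.
#'
#' @param geom An `"sp_localizer"`.
#' @param plane A `"scan_plane"`.
#' @return A `"fiducial_set"`.
#' @export
sp_forward <- function(geom, plane) {
  rods <- sp_rods(geom)
  pts <- lapply(rods, intersect_rod_plane, plane = plane)
  fiducial_set(to_image(pts$A, plane), to_image(pts$B, plane),
               to_image(pts$C, plane), id = geom$id)
}

#' Classic one-point Sturm-Pastyr solve
#'
#' The original method: the slice height on the vertical rod B is read
#' off the outer distance alone, `h_B = d_AC / (2 * tan(alpha))`, and
#' a single frame point on rod B is returned. Exact for an untilted
#' slice; a tilted slice biases the estimate, which is the weakness
#' the three-point solve addresses.
#'
#' @param fid A `"fiducial_set"`.
#' @param geom The matching `"sp_localizer"`.
#' @param clamp If `TRUE` (default), a height beyond the rod extent is
#'   clamped to the extent with a warning; if `FALSE` it is an error.
#' @return Numeric length-3 frame point on rod B, with attribute
#'   `"height"` (the local height, mm).
#' @export
solve_classic <- function(fid, geom, clamp = TRUE) {
  d <- fiducial_distances(fid)
  if (!is.finite(d[["AC"]]) || d[["AC"]] <= 0)
    stop("classic solve requires d_AC > 0", call. = FALSE)
  h <- d[["AC"]] / (2 * geom$tan_alpha)
  if (h > geom$extent) {
    if (clamp) {
      warning(sprintf(
        "classic height %.2f mm beyond rod extent %.2f mm; clamped",
        h, geom$extent), call. = FALSE)
      h <- geom$extent
    } else {
      stop(sprintf("classic height %.2f mm beyond rod extent %.2f mm",
                   h, geom$extent), call. = FALSE)
    }
  }
  p <- geom$apex + h * geom$up
  attr(p, "height") <- h
  class(p) <- "sp_classic_point"
  p
}

# ---------------------------------------------------------------------------
# Three-point solve.
#
# In the localizer plane, parameterize points on the rod axes by local
# height: P_A = (-a*t, a), P_B = (0, b), P_C = (c*t, c) with
# t = tan(alpha). The constraints |P_A-P_B| = d_AB, |P_B-P_C| = d_BC,
# |P_A-P_C| = d_AC form three equations in (a, b, c). With T = t^2,
# s = a + c, q = a - c the outer constraint collapses to
#   T s^2 + q^2 = d_AC^2                                           (i)
# and eliminating b from the difference and sum of the inner
# constraints leaves a quadratic in g = q^2:
#   (K^2 + T D^2) g^2 + D^2 (K - T d_AC^2) g + D^4 / 4 = 0          (ii)
# where D = d_AB^2 - d_BC^2, E = d_AB^2 + d_BC^2 - d_AC^2 and
# K = (T - 1) d_AC^2 / 2 - E. Each root yields
#   s = q (K + D^2 / (2 g)) / (T D),  b = ((1 + T) s - D / q) / 2,
# with the sign of q fixed by s >= 0. The symmetric family (q = 0,
# s = d_AC / t, b = s/2 +/- sqrt(d_AB^2 - T s^2/4)) covers D -> 0.
# Every candidate is polished by a few Newton steps on the full
# system, and the branch kept is the real, in-extent solution nearest
# the classic estimate: the noise bound is small (<= 1 mm), so the
# true branch is the one adjacent to the unperturbed geometry.
# ---------------------------------------------------------------------------

# Vectorized, monotone Newton polish on the three distance equations.
# A step is accepted only where it reduces the residual: collinear
# (noise-free) input sits on a fold of the distance map where the
# Jacobian is singular and a raw Newton step diverges, but there the
# closed-form candidate is already exact, so keep-best is safe.
.sp3_polish <- function(a, b, c, d1sq, d2sq, d3sq, T, iters = 10L,
                        steps = c(1, 0.5, 0.25)) {
  res <- .sp3_resid(a, b, c, d1sq, d2sq, d3sq, T)
  for (k in seq_len(iters)) {
    F1 <- T * a^2 + (a - b)^2 - d1sq
    F2 <- T * c^2 + (c - b)^2 - d2sq
    F3 <- T * (a + c)^2 + (c - a)^2 - d3sq
    J11 <- 2 * T * a + 2 * (a - b); J12 <- -2 * (a - b)
    J22 <- -2 * (c - b);            J23 <- 2 * T * c + 2 * (c - b)
    J31 <- 2 * T * (a + c) - 2 * (c - a)
    J33 <- 2 * T * (a + c) + 2 * (c - a)
    det <- J11 * J22 * J33 + J12 * J23 * J31
    ok <- is.finite(det) & abs(det) > 1e-300 &
      is.finite(F1) & is.finite(F2) & is.finite(F3)
    det <- ifelse(ok, det, 1)
    da <- (F1 * J22 * J33 - J12 * (F2 * J33 - J23 * F3)) / det
    db <- (J11 * (F2 * J33 - J23 * F3) + F1 * J23 * J31) / det
    dc <- (J11 * J22 * F3 + J12 * J31 * F2 - F1 * J22 * J31) / det
    # full step with damped alternatives, all taken from the same
    # starting point: a full step can overshoot along the flat
    # (near-singular) direction close to the collinear fold
    a1 <- a; b1 <- b; c1 <- c
    for (step in steps) {
      a2 <- a1 - step * da; b2 <- b1 - step * db; c2 <- c1 - step * dc
      res2 <- .sp3_resid(a2, b2, c2, d1sq, d2sq, d3sq, T)
      take <- ok & is.finite(res2) & res2 < res
      a <- ifelse(take, a2, a)
      b <- ifelse(take, b2, b)
      c <- ifelse(take, c2, c)
      res <- ifelse(take, res2, res)
    }
  }
  list(a = a, b = b, c = c)
}

.sp3_resid <- function(a, b, c, d1sq, d2sq, d3sq, T) {
  pmax(abs(T * a^2 + (a - b)^2 - d1sq),
       abs(T * c^2 + (c - b)^2 - d2sq),
       abs(T * (a + c)^2 + (c - a)^2 - d3sq))
}

# Vectorized three-point solver over parallel distance vectors.
# Returns list(hA, hB, hC, residual) with NA entries where no valid
# solution exists (degenerate input, no real root, or out of extent).
.sp3_batch <- function(d1, d2, d3, tan_alpha, extent, min_dac = 1,
                       deep = FALSE) {
  n <- length(d3)
  T <- tan_alpha^2
  d1sq <- d1^2; d2sq <- d2^2; d3sq <- d3^2
  hc <- d3 / (2 * tan_alpha)                       # classic anchor
  D <- d1sq - d2sq
  E <- d1sq + d2sq - d3sq
  K <- (T - 1) * d3sq / 2 - E
  qa <- K^2 + T * D^2
  qb <- D^2 * (K - T * d3sq)
  qc <- D^4 / 4
  # The discriminant qb^2 - 4*qa*qc factors exactly as
  #   T * D^4 * (d1+d2+d3)(d1+d2-d3)(d3-d1+d2)(d3+d1-d2),
  # a product of well-conditioned terms (one is the collinearity
  # residual). The expanded form cancels catastrophically near the
  # collinear double root, where noise-free input always sits; the
  # factored form keeps full relative accuracy there. It is clamped
  # at zero (triangle-degenerate rounding): candidates are only
  # Newton starting points and the post-polish residual check
  # discards any that do not solve the system.
  disc <- T * D^4 * ((d1 + d2 + d3) * (d1 + d2 - d3) *
                       (d3 - d1 + d2) * (d3 + d1 - d2))
  have_root <- is.finite(disc) & qa > 0
  sq <- sqrt(pmax(disc, 0))
  # stable quadratic roots: qb <= 0 here is not guaranteed, so split
  # on its sign to avoid subtracting nearly equal quantities
  tq <- -(qb + sign(qb) * sq) / 2
  g_roots <- list(ifelse(abs(tq) > 0, tq / qa, 0),
                  ifelse(abs(tq) > 0, qc / tq, 0))

  cand <- vector("list", 5L)
  for (i in 1:2) {
    g <- g_roots[[i]]
    good <- have_root & is.finite(g) & g > 0 & abs(D) > 0
    g <- ifelse(good, g, NA_real_)
    q <- sqrt(g)
    s <- q * (K + D^2 / (2 * g)) / (T * D)
    q <- ifelse(s < 0, -q, q)
    s <- abs(s)
    b <- ((1 + T) * s - D / q) / 2
    cand[[i]] <- list(a = (s + q) / 2, b = b, c = (s - q) / 2)
  }
  # symmetric family: exact when d_AB = d_BC, a robust start otherwise.
  # The fully symmetric point covers the doubly degenerate case
  # a = b = c (equal heights on all rods), where the +/- sqrt branch
  # offset is pure rounding noise.
  a0 <- hc
  r0 <- sqrt(pmax(d1sq - T * a0^2, 0))
  cand[[3]] <- list(a = a0, b = a0 + r0, c = a0)
  cand[[4]] <- list(a = a0, b = a0 - r0, c = a0)
  cand[[5]] <- list(a = a0, b = a0, c = a0)

  # Branch selection: nearest to the classic estimate by summed
  # squared height difference. The symmetric pair b = a0 +/- r0 is
  # exactly tied under that score, so near-ties are broken
  # deterministically toward the greater rod-B height.
  tol_res <- 1e-9 * pmax(d3sq, 1)
  tol_h <- 1e-7 * pmax(extent, 1)
  best <- list(a = rep(NA_real_, n), b = rep(NA_real_, n),
               c = rep(NA_real_, n))
  best_score <- rep(Inf, n)
  pol_iters <- if (deep) 20L else 10L
  pol_steps <- if (deep) c(1, 0.5, 0.25, 0.1, 0.03, 0.01) else
    c(1, 0.5, 0.25)
  for (cd in cand) {
    p <- .sp3_polish(cd$a, cd$b, cd$c, d1sq, d2sq, d3sq, T,
                     iters = pol_iters, steps = pol_steps)
    res <- .sp3_resid(p$a, p$b, p$c, d1sq, d2sq, d3sq, T)
    valid <- is.finite(p$a) & is.finite(p$b) & is.finite(p$c) &
      res <= tol_res &
      p$a >= -tol_h & p$b >= -tol_h & p$c >= -tol_h &
      p$a <= extent + tol_h & p$b <= extent + tol_h & p$c <= extent + tol_h
    score <- ifelse(valid,
                    (p$a - hc)^2 + (p$b - hc)^2 + (p$c - hc)^2, Inf)
    tie <- is.finite(score) & is.finite(best_score) &
      abs(score - best_score) <= 1e-6 * (1 + pmin(score, best_score))
    take <- (score < best_score & !tie) | (tie & p$b > best$b)
    take[is.na(take)] <- FALSE
    best_score <- ifelse(take, score, best_score)
    best$a <- ifelse(take, p$a, best$a)
    best$b <- ifelse(take, p$b, best$b)
    best$c <- ifelse(take, p$c, best$c)
  }
  # Fold preference: collinear (noise-free) input sits on a fold of
  # the distance map, where residual-driven iteration can drift along
  # the flat valley — the heights are determined only to sqrt of the
  # residual there. When the collinear-projection point already
  # satisfies all three exact equations within the residual
  # tolerance, the distances cannot resolve any split around the
  # fold, so that point is returned outright; under measurable noise
  # its residual is of order d_AC times the collinearity residual and
  # the rule is inert. The test oracle applies the same rule.
  fold <- .sp3_collinear_batch(d1, d2, d3, tan_alpha, extent,
                               min_dac = min_dac)
  fold_res <- .sp3_resid(fold$hA, fold$hB, fold$hC, d1sq, d2sq, d3sq, T)
  force_fold <- !is.na(fold$hA) & is.finite(fold_res) &
    fold_res <= tol_res
  best$a <- ifelse(force_fold, fold$hA, best$a)
  best$b <- ifelse(force_fold, fold$hB, best$b)
  best$c <- ifelse(force_fold, fold$hC, best$c)
  best_score <- ifelse(force_fold, 0, best_score)

  degenerate <- !is.finite(d3) | d3 < min_dac
  fail <- degenerate | !is.finite(best_score)
  best$a[fail] <- NA_real_; best$b[fail] <- NA_real_; best$c[fail] <- NA_real_
  list(hA = best$a, hB = best$b, hC = best$c,
       residual = .sp3_resid(best$a, best$b, best$c, d1sq, d2sq, d3sq, T),
       degenerate = degenerate)
}

# ---------------------------------------------------------------------------
# Collinear-projection solve.
#
# Noise-free fiducial centers are collinear (the scan plane cuts the
# localizer plane in a line), so the true configuration always lies on
# the collinear manifold where d_AC = d_AB + d_BC. The collinear
# solve fits that manifold through the three linearly independent
# measured distances instead of interpolating them exactly: with
# e = d_AB - d_BC and T = tan^2(alpha), the collinear configuration
# with |P_A - P_C| = d_AC and split ratio matched to e has
#   s = a + c = d_AC^2 / sqrt(T d_AC^2 + e^2),   q = a - c = s e / d_AC,
#   a = (s + q)/2,  c = (s - q)/2,  b = 2 a c / (a + c)
# (the rod-B height is the harmonic mean, because height is affine
# along the intersection line). This discards the transverse noise
# component that the exact-distance solve would fold into the rod-B
# height, is exact on noise-free input at any tilt, and is smooth in
# the data — no branch choice, no fold amplification.
# ---------------------------------------------------------------------------
.sp3_collinear_batch <- function(d1, d2, d3, tan_alpha, extent,
                                 min_dac = 1) {
  T <- tan_alpha^2
  e <- d1 - d2
  s <- d3^2 / sqrt(T * d3^2 + e^2)
  q <- s * e / d3
  a <- (s + q) / 2
  c <- (s - q) / 2
  b <- ifelse(a + c > 0, 2 * a * c / (a + c), NA_real_)
  tol_h <- 1e-7 * pmax(extent, 1)
  degenerate <- !is.finite(d3) | d3 < min_dac
  ok <- !degenerate & is.finite(a) & is.finite(b) & is.finite(c) &
    a >= -tol_h & b >= -tol_h & c >= -tol_h &
    a <= extent + tol_h & b <= extent + tol_h & c <= extent + tol_h
  list(hA = ifelse(ok, a, NA_real_), hB = ifelse(ok, b, NA_real_),
       hC = ifelse(ok, c, NA_real_),
       residual = abs(d3 - d1 - d2) / 2, degenerate = degenerate)
}

#' Three-point Sturm-Pastyr solve
#'
#' Recovers one frame point per rod axis from the three inter-fiducial
#' distances, which are linearly independent under image noise. Two
#' formulations are provided:
#'
#' * `"collinear"` (default): fits the collinear configuration — the
#'   manifold the true fiducials always lie on — through the measured
#'   distances. Exact on noise-free input at any tilt, smooth in the
#'   data, and the formulation that realizes the accuracy gain of
#'   three points per localizer; this method drives the Monte Carlo
#'   engine. The outer distance `|pA - pC|` is reproduced exactly and
#'   the inner distances up to half the collinearity residual each.
#' * `"exact"`: solves the three distance equations exactly (closed
#'   form via a quadratic plus damped Newton polish); among the real,
#'   in-extent branches the one nearest the classic estimate is
#'   returned, near-ties broken toward the greater rod-B height. All
#'   three pairwise distances are reproduced to solver tolerance, at
#'   the cost of folding transverse noise into the rod-B height.
#'
#' @param fid A `"fiducial_set"`.
#' @param geom The matching `"sp_localizer"`.
#' @param method `"collinear"` or `"exact"`.
#' @param min_dac Degeneracy threshold (mm): solves are rejected when
#'   `d_AC` falls below it, i.e. the slice is essentially at the apex.
#' @return An object of class `"sp_solution"`: list with frame points
#'   `pA`, `pB`, `pC`, local `heights`, `collinearity_residual` (mm),
#'   the `method`, and the solver `residual` on the distance
#'   equations (for `"collinear"`, half the collinearity residual —
#'   the unavoidable misfit of the inner distances).
#' @export
solve_three_point <- function(fid, geom,
                              method = c("collinear", "exact"),
                              min_dac = 1) {
  method <- match.arg(method)
  d <- fiducial_distances(fid)
  if (!all(is.finite(d)) || any(d[c("AB", "BC")] < 0) || d[["AC"]] <= 0)
    stop("inter-fiducial distances must be finite and d_AC positive",
         call. = FALSE)
  if (d[["AC"]] < min_dac)
    stop(sprintf(
      "degenerate input: d_AC = %.3f mm is below the %.3f mm threshold (slice near the apex)",
      d[["AC"]], min_dac), call. = FALSE)
  sol <- if (method == "collinear")
    .sp3_collinear_batch(d[["AB"]], d[["BC"]], d[["AC"]],
                         geom$tan_alpha, geom$extent, min_dac = min_dac)
  else
    .sp3_batch(d[["AB"]], d[["BC"]], d[["AC"]],
               geom$tan_alpha, geom$extent, min_dac = min_dac,
               deep = TRUE)
  if (is.na(sol$hA))
    stop(sprintf(
      paste0("no real in-extent solution for distances ",
             "d_AB = %.4f, d_BC = %.4f, d_AC = %.4f mm ",
             "(collinearity residual %.4f mm)"),
      d[["AB"]], d[["BC"]], d[["AC"]],
      d[["AC"]] - d[["AB"]] - d[["BC"]]), call. = FALSE)
  t <- geom$tan_alpha
  structure(list(
    pA = geom$apex + sol$hA * (geom$up - t * geom$in_plane),
    pB = geom$apex + sol$hB * geom$up,
    pC = geom$apex + sol$hC * (geom$up + t * geom$in_plane),
    heights = c(A = sol$hA, B = sol$hB, C = sol$hC),
    collinearity_residual = unname(d["AC"] - d["AB"] - d["BC"]),
    residual = sol$residual,
    method = method,
    id = fid$id
  ), class = "sp_solution")
}

#' @export
print.sp_solution <- function(x, ...) {
  cat(sprintf(
    "<sp_solution> %s: heights (%.3f, %.3f, %.3f) mm, collinearity %.2e mm\n",
    x$id, x$heights["A"], x$heights["B"], x$heights["C"],
    x$collinearity_residual))
  invisible(x)
}

#' Pair measured image coordinates with solved frame coordinates
#'
#' Builds the correspondence records that feed the least-squares
#' image-to-frame fit: three full `(u,v) <-> (x,y,z)` pairs per
#' localizer in three-point mode, one pair (fiducial B against the
#' single solved point) in classic mode, and for the N-localizer one
#' full pair from the diagonal rod plus two `(x, y)`-only pairs from
#' the vertical rods.
#'
#' @param sol A solver result: `"sp_solution"`, `"sp_classic_point"`,
#'   or `"n_solution"`.
#' @param fid The `"fiducial_set"` the solution was computed from.
#' @return A data frame with columns `localizer`, `label`, `u`, `v`,
#'   `x`, `y`, `z`, `kind` (`"full"` or `"xy_only"`; `z` is `NA` for
#'   `xy_only` rows).
#' @export
correspondences <- function(sol, fid) UseMethod("correspondences")

#' @export
correspondences.sp_solution <- function(sol, fid) {
  data.frame(
    localizer = fid$id, label = c("A", "B", "C"),
    u = fid$uv[, "u"], v = fid$uv[, "v"],
    x = c(sol$pA[1], sol$pB[1], sol$pC[1]),
    y = c(sol$pA[2], sol$pB[2], sol$pC[2]),
    z = c(sol$pA[3], sol$pB[3], sol$pC[3]),
    kind = "full", row.names = NULL
  )
}

#' @export
correspondences.sp_classic_point <- function(sol, fid) {
  data.frame(
    localizer = fid$id, label = "B",
    u = fid$uv["B", "u"], v = fid$uv["B", "v"],
    x = sol[1], y = sol[2], z = sol[3],
    kind = "full", row.names = NULL
  )
}
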