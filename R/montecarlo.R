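# Monte Carlo registration-accuracy engine.
#
# Protocol per height cell: forward-model every localizer on the
# unperturbed plane, fit the unperturbed transformation, then over n
# iterations perturb every fiducial center with bounded 2D noise,
# re-solve, re-fit, and map the target points with both matrices. The
# root-mean-square 3D error over iterations,
#   RMSe = sqrt( (1/n) * sum_i [ (x_i - x^_i)^2 + (y_i - y^_i)^2
#                                + (z_i - z^_i)^2 ] ),
# is reported per target. The whole iteration axis is vectorized; one
# deterministic RNG seed is derived per (base seed, height) cell so
# results are reproducible and order-independent, and scenarios
# compared at the same height share noise draws (common random
# numbers), which pairs the relational comparisons.

#' Bounded fiducial-center noise model
#'
#' Every perturbation is an independent 2D displacement of one
#' fiducial center with Euclidean norm at most `max_magnitude`. The
#' default distribution is uniform over the closed disk of that
#' radius; "maximum magnitude" bounds the norm, and the disk is the
#' least informative choice consistent with it. Alternatives are
#' uniform per component (norm bound `max_magnitude` on each axis) and
#' a Gaussian truncated at the magnitude bound.
#'
#' @param max_magnitude Noise bound (mm), nonnegative; default 1.0.
#' @param distribution One of `"disk_uniform"`, `"component_uniform"`,
#'   `"truncated_gaussian"`.
#' @param sd Standard deviation (mm) for the truncated Gaussian;
#'   default `max_magnitude / 2`.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(max_magnitude = 1,
                        distribution = c("disk_uniform", "component_uniform",
                                         "truncated_gaussian"),
                        sd = max_magnitude / 2) {
  distribution <- match.arg(distribution)
  if (!is.finite(max_magnitude) || max_magnitude < 0)
    stop("max_magnitude must be nonnegative", call. = FALSE)
  structure(list(max_magnitude = max_magnitude, distribution = distribution,
                 sd = sd), class = "noise_model")
}

#' Draw fiducial-center perturbations
#'
#' @param noise A `"noise_model"`.
#' @param n Number of draws.
#' @return An `n` x 2 matrix of `(du, dv)` displacements (mm), each
#'   row of Euclidean norm at most `noise$max_magnitude` (for the disk
#'   and truncated-Gaussian distributions; the per-component uniform
#'   bounds each component instead).
#' @export
draw_noise <- function(noise, n) {
  mm <- noise$max_magnitude
  switch(noise$distribution,
    disk_uniform = {
      r <- mm * sqrt(stats::runif(n))
      ph <- stats::runif(n, 0, 2 * pi)
      cbind(du = r * cos(ph), dv = r * sin(ph))
    },
    component_uniform = cbind(du = stats::runif(n, -mm, mm),
                              dv = stats::runif(n, -mm, mm)),
    truncated_gaussian = {
      du <- stats::rnorm(n, 0, noise$sd)
      dv <- stats::rnorm(n, 0, noise$sd)
      bad <- which(du^2 + dv^2 > mm^2)
      while (length(bad)) {
        du[bad] <- stats::rnorm(length(bad), 0, noise$sd)
        dv[bad] <- stats::rnorm(length(bad), 0, noise$sd)
        bad <- bad[du[bad]^2 + dv[bad]^2 > mm^2]
      }
      cbind(du = du, dv = dv)
    }
  )
}

#' Perturb the fiducial centers of one set
#'
#' Displaces each center independently by a random vector drawn from
#' the noise model; distances are recomputed from the perturbed
#' centers (so the perturbed centers are no longer collinear and
#' `d_AC != d_AB + d_BC` with probability one).
#'
#' @param fid A `"fiducial_set"`.
#' @param noise A `"noise_model"`.
#' @return A perturbed `"fiducial_set"`.
#' @export
perturb_fiducials <- function(fid, noise) {
  off <- draw_noise(noise, 3)
  uv <- fid$uv + off
  fiducial_set(uv["A", ], uv["B", ], uv["C", ], id = fid$id)
}

#' Default simulation target points
#'
#' The six target points, in mm relative to the image center: center
#' (0,0), right lateral (+50,0), left lateral (-50,0), anterior
#' (0,+50), posterior (0,-50), anterolateral (+50,+50).
#'
#' @return A 6 x 2 matrix with named rows.
#' @export
default_targets <- function() {
  m <- rbind(center = c(0, 0), right = c(50, 0), left = c(-50, 0),
             anterior = c(0, 50), posterior = c(0, -50),
             anterolateral = c(50, 50))
  colnames(m) <- c("u", "v")
  m
}

#' Define a Monte Carlo scenario
#'
#' @param id Scenario identifier (e.g. `"fig3"`).
#' @param frame A `"stereo_frame"`.
#' @param mode Solver mode: `"classic"` or `"three_point"` for a
#'   Sturm-Pastyr frame, `"n_localizer"` for an N frame.
#' @param theta_deg Anteroposterior tilt (degrees).
#' @param z_min,z_max,z_step Height sweep (mm); default step 2 mm.
#' @param n_iter Iterations per height; the full protocol uses `2^21`.
#' @param targets Target (u, v) matrix; default [default_targets()].
#' @param noise A `"noise_model"`; default 1.0 mm disk-uniform.
#' @return An object of class `"mc_scenario"`.
#' @export
mc_scenario <- function(id, frame, mode = c("three_point", "classic",
                                            "n_localizer"),
                        theta_deg = 0, z_min = 5, z_max = 155, z_step = 2,
                        n_iter = 2^21, targets = default_targets(),
                        noise = noise_model()) {
  mode <- match.arg(mode)
  stopifnot(inherits(frame, "stereo_frame"))
  if (frame$type == "sp" && mode == "n_localizer")
    stop("mode 'n_localizer' requires an N frame", call. = FALSE)
  if (frame$type == "n" && mode != "n_localizer")
    stop("a Sturm-Pastyr solver mode requires an SP frame", call. = FALSE)
  if (z_step <= 0 || z_max < z_min)
    stop("invalid height range", call. = FALSE)
  if (n_iter < 1) stop("n_iter must be positive", call. = FALSE)
  structure(list(id = id, frame = frame, mode = mode,
                 theta_deg = theta_deg, z = seq(z_min, z_max, by = z_step),
                 n_iter = as.integer(n_iter), targets = as.matrix(targets),
                 noise = noise),
            class = "mc_scenario")
}

#' @export
print.mc_scenario <- function(x, ...) {
  cat(sprintf(
    "<mc_scenario> %s: %d %s localizers, mode %s, tilt %g deg, z %g..%g mm, n = %d\n",
    x$id, length(x$frame$localizers), toupper(x$frame$type), x$mode,
    x$theta_deg, min(x$z), max(x$z), x$n_iter))
  invisible(x)
}

# Deterministic 31-bit seed for one (base seed, height) cell. The
# scenario does not enter, so scenarios compared at the same height
# reuse the same noise stream (common random numbers).
.cell_seed <- function(seed, z0) {
  s <- abs(as.numeric(seed)) %% 65536
  zi <- abs(round(z0 * 4)) %% 32768
  as.integer(s * 32768 + zi)
}

# Draw the full noise block for one cell: per localizer (in frame
# order), per fiducial A, B, C, one n x 2 block. Fixed order makes the
# first three localizers' draws identical across 3- and 4-localizer
# frames under the same cell seed.
.mc_draw <- function(noise, n, n_loc) {
  lapply(seq_len(n_loc), function(j) {
    offs <- lapply(1:3, function(f) draw_noise(noise, n))
    list(du = cbind(offs[[1]][, 1], offs[[2]][, 1], offs[[3]][, 1]),
         dv = cbind(offs[[1]][, 2], offs[[2]][, 2], offs[[3]][, 2]))
  })
}

# Solve the symmetric 3x3 system S m = b elementwise over parallel
# vectors (Cramer). Returns list(m1, m2, m3).
.solve3sym <- function(s11, s12, s13, s22, s23, s33, b1, b2, b3) {
  c11 <- s22 * s33 - s23 * s23
  c12 <- s12 * s33 - s23 * s13
  c13 <- s12 * s23 - s22 * s13
  det <- s11 * c11 - s12 * c12 + s13 * c13
  list(
    m1 = (b1 * c11 - s12 * (b2 * s33 - s23 * b3) +
            s13 * (b2 * s23 - s22 * b3)) / det,
    m2 = (s11 * (b2 * s33 - b3 * s23) - b1 * c12 +
            s13 * (s12 * b3 - b2 * s13)) / det,
    m3 = (s11 * (s22 * b3 - s23 * b2) - s12 * (s12 * b3 - b2 * s13) +
            b1 * c13) / det
  )
}

# Vectorized least-squares fit over parallel correspondence rows.
# rows: list of list(u, v, x, y, z, full) with vector (or scalar)
# entries of common iteration length. Returns the nine matrix entries
# as vectors, column-major: x column (m1x, m2x, m3x), etc.
.fit_batch <- function(rows, n) {
  zero <- numeric(n)
  Suu <- zero; Suv <- zero; Su <- zero; Svv <- zero; Sv <- zero; S1 <- 0
  bx1 <- zero; bx2 <- zero; bx3 <- zero
  by1 <- zero; by2 <- zero; by3 <- zero
  fSuu <- zero; fSuv <- zero; fSu <- zero; fSvv <- zero; fSv <- zero; f1 <- 0
  bz1 <- zero; bz2 <- zero; bz3 <- zero
  for (r in rows) {
    Suu <- Suu + r$u * r$u; Suv <- Suv + r$u * r$v; Su <- Su + r$u
    Svv <- Svv + r$v * r$v; Sv <- Sv + r$v; S1 <- S1 + 1
    bx1 <- bx1 + r$u * r$x; bx2 <- bx2 + r$v * r$x; bx3 <- bx3 + r$x
    by1 <- by1 + r$u * r$y; by2 <- by2 + r$v * r$y; by3 <- by3 + r$y
    if (r$full) {
      fSuu <- fSuu + r$u * r$u; fSuv <- fSuv + r$u * r$v; fSu <- fSu + r$u
      fSvv <- fSvv + r$v * r$v; fSv <- fSv + r$v; f1 <- f1 + 1
      bz1 <- bz1 + r$u * r$z; bz2 <- bz2 + r$v * r$z; bz3 <- bz3 + r$z
    }
  }
  mx <- .solve3sym(Suu, Suv, Su, Svv, Sv, S1, bx1, bx2, bx3)
  my <- .solve3sym(Suu, Suv, Su, Svv, Sv, S1, by1, by2, by3)
  mz <- .solve3sym(fSuu, fSuv, fSu, fSvv, fSv, f1, bz1, bz2, bz3)
  list(x = mx, y = my, z = mz)
}

# Per-iteration correspondence rows for one localizer, given perturbed
# centers (n-vectors uh, vh indexed [ , fiducial]). Returns
# list(rows = <list>, valid = <logical n-vector>).
.mc_rows <- function(geom, mode, uh, vh, min_dac) {
  dist2 <- function(i, j) sqrt((uh[, i] - uh[, j])^2 + (vh[, i] - vh[, j])^2)
  if (mode == "classic") {
    d3 <- dist2(1, 3)
    h <- d3 / (2 * geom$tan_alpha)
    valid <- is.finite(h) & d3 > 0 & h <= geom$extent
    p <- lapply(1:3, function(k) geom$apex[k] + h * geom$up[k])
    rows <- list(list(u = uh[, 2], v = vh[, 2],
                      x = p[[1]], y = p[[2]], z = p[[3]], full = TRUE))
  } else if (mode == "three_point") {
    sol <- .sp3_collinear_batch(dist2(1, 2), dist2(2, 3), dist2(1, 3),
                                geom$tan_alpha, geom$extent,
                                min_dac = min_dac)
    valid <- !is.na(sol$hA)
    t <- geom$tan_alpha
    dirA <- geom$up - t * geom$in_plane
    dirC <- geom$up + t * geom$in_plane
    rows <- list(
      list(u = uh[, 1], v = vh[, 1],
           x = geom$apex[1] + sol$hA * dirA[1],
           y = geom$apex[2] + sol$hA * dirA[2],
           z = geom$apex[3] + sol$hA * dirA[3], full = TRUE),
      list(u = uh[, 2], v = vh[, 2],
           x = geom$apex[1] + sol$hB * geom$up[1],
           y = geom$apex[2] + sol$hB * geom$up[2],
           z = geom$apex[3] + sol$hB * geom$up[3], full = TRUE),
      list(u = uh[, 3], v = vh[, 3],
           x = geom$apex[1] + sol$hC * dirC[1],
           y = geom$apex[2] + sol$hC * dirC[2],
           z = geom$apex[3] + sol$hC * dirC[3], full = TRUE)
    )
  } else {                               # n_localizer
    rods <- n_rods(geom)
    e1 <- rods$B$base
    e2 <- rods$B$base + rods$B$length * rods$B$direction
    d1 <- dist2(1, 2); d3 <- dist2(1, 3)
    f <- d1 / d3
    valid <- is.finite(f) & d3 > 0 & f >= 0 & f <= 1
    rows <- list(
      list(u = uh[, 1], v = vh[, 1],
           x = rods$A$base[1], y = rods$A$base[2], z = NA_real_,
           full = FALSE),
      list(u = uh[, 2], v = vh[, 2],
           x = e1[1] + f * (e2[1] - e1[1]),
           y = e1[2] + f * (e2[2] - e1[2]),
           z = e1[3] + f * (e2[3] - e1[3]), full = TRUE),
      list(u = uh[, 3], v = vh[, 3],
           x = rods$C$base[1], y = rods$C$base[2], z = NA_real_,
           full = FALSE)
    )
  }
  list(rows = rows, valid = valid)
}

# Core of one Monte Carlo cell, given pre-drawn noise blocks (one per
# localizer, each n x 3 in du and dv). Returns a per-target data
# frame. Separated from the RNG so tests can replay identical draws
# through the scalar solver path.
.mc_cell_core <- function(frame, mode, plane, draws, targets,
                          min_dac = 1) {
  locs <- frame$localizers
  forward <- if (frame$type == "sp") sp_forward else n_forward
  fids <- lapply(locs, forward, plane = plane)

  # unperturbed transformation via the scalar solver path
  cs0 <- do.call(rbind, lapply(seq_along(locs), function(j) {
    sol0 <- switch(mode,
      classic = solve_classic(fids[[j]], locs[[j]], clamp = FALSE),
      three_point = solve_three_point(fids[[j]], locs[[j]],
                                      min_dac = min_dac),
      n_localizer = n_solve(fids[[j]], locs[[j]]))
    correspondences(sol0, fids[[j]])
  }))
  M0 <- fit_transform(cs0)
  t0 <- apply_transform(M0, targets)

  n <- nrow(draws[[1]]$du)
  rows <- list()
  valid <- rep(TRUE, n)
  for (j in seq_along(locs)) {
    uv0 <- fids[[j]]$uv
    uh <- cbind(uv0[1, 1] + draws[[j]]$du[, 1],
                uv0[2, 1] + draws[[j]]$du[, 2],
                uv0[3, 1] + draws[[j]]$du[, 3])
    vh <- cbind(uv0[1, 2] + draws[[j]]$dv[, 1],
                uv0[2, 2] + draws[[j]]$dv[, 2],
                uv0[3, 2] + draws[[j]]$dv[, 3])
    rj <- .mc_rows(locs[[j]], mode, uh, vh, min_dac)
    valid <- valid & rj$valid
    rows <- c(rows, rj$rows)
  }
  idx <- which(valid)
  n_failed <- n - length(idx)
  if (!length(idx))
    stop("all iterations failed in this cell", call. = FALSE)
  rows <- lapply(rows, function(r) {
    r$u <- r$u[idx]; r$v <- r$v[idx]
    if (length(r$x) > 1) r$x <- r$x[idx]
    if (length(r$y) > 1) r$y <- r$y[idx]
    if (length(r$z) > 1) r$z <- r$z[idx]
    r
  })
  M <- .fit_batch(rows, length(idx))

  out <- vector("list", nrow(targets))
  for (k in seq_len(nrow(targets))) {
    ut <- targets[k, 1]; vt <- targets[k, 2]
    xh <- M$x$m1 * ut + M$x$m2 * vt + M$x$m3
    yh <- M$y$m1 * ut + M$y$m2 * vt + M$y$m3
    zh <- M$z$m1 * ut + M$z$m2 * vt + M$z$m3
    e2 <- (xh - t0[k, 1])^2 + (yh - t0[k, 2])^2 + (zh - t0[k, 3])^2
    rmse <- sqrt(mean(e2))
    se <- if (rmse > 0 && length(e2) > 1)
      stats::sd(e2) / sqrt(length(e2)) / (2 * rmse) else 0
    out[[k]] <- data.frame(target = rownames(targets)[k], rmse_mm = rmse,
                           se_mm = se, n_used = length(idx),
                           n_failed = n_failed)
  }
  do.call(rbind, out)
}

#' Run one Monte Carlo height cell
#'
#' Simulates `scenario$n_iter` noise perturbations at one scan height
#' and reports the RMSe per target point, together with a
#' delta-method Monte Carlo standard error, the number of iterations
#' used, and the number excluded because a solver failed (near-apex
#' cells can fail at the stated noise level; they are counted, not
#' fatal). Deterministic given `(seed, z0)`.
#'
#' @param scenario An `"mc_scenario"`.
#' @param z0 Scan height (mm), which must clear the frame base at the
#'   scenario tilt and cross all rods within extent.
#' @param seed Base integer seed.
#' @return A data frame with one row per target: `scenario_id`,
#'   `mode`, `theta_deg`, `target`, `z_mm`, `rmse_mm`, `se_mm`,
#'   `n_used`, `n_failed`.
#' @export
run_height <- function(scenario, z0, seed = 1) {
  stopifnot(inherits(scenario, "mc_scenario"))
  theta <- scenario$theta_deg * pi / 180
  plane <- make_plane(z0, theta)
  if (.plane_base_clearance(plane, scenario$frame$radius) < 0)
    stop(structure(class = c("stereofid_invalid_height", "error",
                             "condition"),
                   list(message = sprintf(
                     "z0 = %g mm: scan plane would cut the frame base at %g deg tilt",
                     z0, scenario$theta_deg), call = NULL)))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(.cell_seed(seed, z0))
  draws <- .mc_draw(scenario$noise, scenario$n_iter,
                    length(scenario$frame$localizers))
  res <- tryCatch(
    .mc_cell_core(scenario$frame, scenario$mode, plane, draws,
                  scenario$targets),
    error = function(e) {
      stop(structure(class = c("stereofid_invalid_height", "error",
                               "condition"),
                     list(message = sprintf("z0 = %g mm: %s", z0,
                                            conditionMessage(e)),
                          call = NULL)))
    })
  cbind(data.frame(scenario_id = scenario$id, mode = scenario$mode,
                   theta_deg = scenario$theta_deg, z_mm = z0,
                   row.names = NULL),
        res)[, c("scenario_id", "mode", "theta_deg", "target", "z_mm",
                 "rmse_mm", "se_mm", "n_used", "n_failed")]
}

#' Sweep Monte Carlo scenarios over their height ranges
#'
#' Runs every (scenario, height) cell and binds the per-target RMSe
#' rows into one table. Heights a scenario cannot simulate (plane
#' cutting the frame base, slice missing a rod) are skipped with a
#' message rather than aborting the sweep.
#'
#' @param scenarios A list of `"mc_scenario"` objects (a single
#'   scenario is accepted).
#' @param seed Base integer seed; every cell's RNG stream is derived
#'   from it deterministically.
#' @param n_iter Optional override of each scenario's iteration count.
#' @param quiet Suppress skip messages.
#' @return An RMSe table: data frame with columns `scenario_id`,
#'   `mode`, `theta_deg`, `target`, `z_mm`, `rmse_mm`, `se_mm`,
#'   `n_used`, `n_failed`.
#' @export
sweep_scenarios <- function(scenarios, seed = 1, n_iter = NULL,
                            quiet = FALSE) {
  if (inherits(scenarios, "mc_scenario")) scenarios <- list(scenarios)
  out <- list()
  for (sc in scenarios) {
    if (!is.null(n_iter)) sc$n_iter <- as.integer(n_iter)
    for (z0 in sc$z) {
      rows <- tryCatch(run_height(sc, z0, seed = seed),
                       stereofid_invalid_height = function(e) {
                         if (!quiet)
                           message("skipping ", sc$id, " (", sc$mode, "): ",
                                   conditionMessage(e))
                         NULL
                       })
      if (!is.null(rows)) out[[length(out) + 1L]] <- rows
    }
  }
  if (!length(out))
    return(data.frame(scenario_id = character(), mode = character(),
                      theta_deg = numeric(), target = character(),
                      z_mm = numeric(), rmse_mm = numeric(),
                      se_mm = numeric(), n_used = integer(),
                      n_failed = integer()))
  do.call(rbind, out)
}
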