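# The forward model and both inverses of the V-shaped localizer.

frame3 <- build_frame("sp")

test_that("forward model reproduces the V distance law", {
  # with tan(alpha) = 0.4 an untilted slice at 50 mm gives 20/20/40
  l <- sp_localizer(c(0, 100, 0), c(1, 0, 0), tan_alpha = 0.4,
                    extent = 180)
  d <- fiducial_distances(sp_forward(l, make_plane(50, 0)))
  expect_equal(unname(d), c(20, 20, 40), tolerance = 1e-12)

  # untilted: d_AB = d_BC and the centers are collinear at any height
  for (z in c(8, 45, 110)) {
    f <- sp_forward(frame3$localizers$left, make_plane(z, 0))
    d <- fiducial_distances(f)
    expect_equal(d[["AB"]], d[["BC"]], tolerance = 1e-9)
    expect_lt(abs(collinearity_residual(f)), 1e-9)
  }
  # noise-free centers stay collinear under tilt
  f10 <- sp_forward(frame3$localizers$left, make_plane(50, 10 * pi / 180))
  expect_lt(abs(collinearity_residual(f10)), 1e-9)
})

test_that("tilted forward model agrees with a direct per-rod derivation", {
  # independent oracle: solve z = z0 + y*tan(theta) against each rod's
  # height parameterization by hand, then chart with explicit axes
  th <- 10 * pi / 180; z0 <- 50
  g <- frame3$localizers$left           # apex (-100, 0, 0), in-plane +y
  t <- g$tan_alpha
  hs <- c(A = z0 / (1 + t * tan(th)), B = z0, C = z0 / (1 - t * tan(th)))
  pts <- list(A = c(-100, -hs[["A"]] * t, hs[["A"]]),
              B = c(-100, 0, hs[["B"]]),
              C = c(-100, hs[["C"]] * t, hs[["C"]]))
  e_u <- c(1, 0, 0); e_v <- c(0, cos(th), sin(th)); org <- c(0, 0, z0)
  chart <- function(p) c(sum((p - org) * e_u), sum((p - org) * e_v))
  f <- sp_forward(g, make_plane(z0, th))
  for (lab in c("A", "B", "C"))
    expect_lt(max(abs(f$uv[lab, ] - chart(pts[[lab]]))), 1e-9)
})

test_that("classic solve inverts the untilted forward model exactly", {
  l <- sp_localizer(c(0, 100, 0), c(1, 0, 0), tan_alpha = 0.4,
                    extent = 180)
  f <- sp_forward(l, make_plane(50, 0))
  p <- solve_classic(f, l)
  expect_equal(attr(p, "height"), 50, tolerance = 1e-12)

  for (z0 in seq(10, 150, by = 20)) {
    g <- frame3$localizers$right
    f <- sp_forward(g, make_plane(z0, 0))
    truth <- intersect_rod_plane(sp_rods(g)$B, make_plane(z0, 0))
    expect_lt(max(abs(solve_classic(f, g) - truth)), 1e-9)
  }
})

test_that("classic solve has a tilt bias that grows with the angle", {
  g <- frame3$localizers$left
  bias <- sapply(c(0, 2, 5, 10), function(deg) {
    pl <- make_plane(50, deg * pi / 180)
    truth <- intersect_rod_plane(sp_rods(g)$B, pl)
    sqrt(sum((unclass(solve_classic(sp_forward(g, pl), g)) - truth)^2))
  })
  expect_lt(bias[1], 1e-9)
  expect_true(all(diff(bias) > 0))
})

test_that("classic solve validates its input", {
  f <- fiducial_set(c(0, 0), c(0, 0), c(0, 0))
  expect_error(solve_classic(f, frame3$localizers$left), "d_AC > 0")
  far <- fiducial_set(c(-200, 0), c(0, 0), c(200, 0))
  expect_warning(p <- solve_classic(far, frame3$localizers$left,
                                    clamp = TRUE), "clamped")
  expect_equal(attr(p, "height"), frame3$localizers$left$extent)
  expect_error(solve_classic(far, frame3$localizers$left, clamp = FALSE),
               "beyond rod extent")
})

test_that("three-point solve recovers all rod intersections noise-free", {
  # both formulations, every aspect, tilts 0/5/10, heights across the
  # sweep range: recovery below 1e-9 mm
  for (method in c("collinear", "exact")) {
    worst <- 0
    for (th in c(0, 5, 10)) for (z0 in seq(5, 155, by = 15)) {
      if (z0 < 100 * abs(tan(th * pi / 180)) + 1) next
      pl <- make_plane(z0, th * pi / 180)
      for (g in frame3$localizers) {
        sol <- solve_three_point(sp_forward(g, pl), g, method = method)
        for (lab in c("A", "B", "C")) {
          truth <- intersect_rod_plane(sp_rods(g)[[lab]], pl)
          worst <- max(worst,
                       max(abs(sol[[paste0("p", lab)]] - truth)))
        }
      }
    }
    expect_lt(worst, 1e-9)
  }
})

test_that("solved points lie on their rod axes even for noisy input", {
  set.seed(31)
  nm <- noise_model(1)
  g <- frame3$localizers$anterior
  rods <- sp_rods(g)
  off_axis <- function(p, rod) {
    w <- p - rod$base
    sqrt(sum((w - sum(w * rod$direction) * rod$direction)^2))
  }
  for (i in 1:50) {
    pl <- make_plane(runif(1, 20, 140), 0)
    f <- perturb_fiducials(sp_forward(g, pl), nm)
    for (method in c("collinear", "exact")) {
      sol <- solve_three_point(f, g, method = method)
      expect_lt(off_axis(sol$pA, rods$A), 1e-9)
      expect_lt(off_axis(sol$pB, rods$B), 1e-9)
      expect_lt(off_axis(sol$pC, rods$C), 1e-9)
    }
  }
})

test_that("the exact method reproduces all three distances, the collinear
           method the outer one", {
  set.seed(57)
  nm <- noise_model(1)
  g <- frame3$localizers$left
  for (i in 1:100) {
    th <- sample(c(0, 10), 1) * pi / 180
    pl <- make_plane(runif(1, 100 * tan(th) + 5, 150), th)
    f <- perturb_fiducials(sp_forward(g, pl), nm)
    d <- fiducial_distances(f)
    se <- solve_three_point(f, g, method = "exact")
    expect_equal(sqrt(sum((se$pA - se$pB)^2)), d[["AB"]], tolerance = 1e-7)
    expect_equal(sqrt(sum((se$pB - se$pC)^2)), d[["BC"]], tolerance = 1e-7)
    expect_equal(sqrt(sum((se$pA - se$pC)^2)), d[["AC"]], tolerance = 1e-7)
    sc <- solve_three_point(f, g, method = "collinear")
    expect_equal(sqrt(sum((sc$pA - sc$pC)^2)), d[["AC"]], tolerance = 1e-7)
    # collinear solution points are exactly collinear
    v1 <- sc$pB - sc$pA; v2 <- sc$pC - sc$pA
    expect_lt(sqrt(sum(pracma::cross(v1, v2)^2)) / sum(v2^2), 1e-9)
  }
})

test_that("degenerate near-apex input is rejected with the threshold", {
  g <- frame3$localizers$left
  tiny <- fiducial_set(c(-0.3, 0), c(0, 0), c(0.3, 0))
  expect_error(solve_three_point(tiny, g), "degenerate input")
  expect_error(solve_three_point(tiny, g, method = "exact"),
               "degenerate input")
})

test_that("collinearity residual is zero noise-free and negative under noise", {
  set.seed(8)
  g <- frame3$localizers$right
  f0 <- sp_forward(g, make_plane(70, 0))
  expect_lt(abs(collinearity_residual(f0)), 1e-9)
  res <- replicate(200, collinearity_residual(
    perturb_fiducials(f0, noise_model(1))))
  # triangle inequality: d_AC <= d_AB + d_BC, strict with probability 1
  expect_true(all(res < 0))
})

test_that("correspondences carry three pairs per localizer, one in classic
           mode", {
  pl <- make_plane(50, 0)
  cs3 <- lapply(frame3$localizers, function(g) {
    f <- sp_forward(g, pl)
    correspondences(solve_three_point(f, g), f)
  })
  expect_equal(nrow(do.call(rbind, cs3)), 9)     # 3 localizers x 3 points
  cs1 <- lapply(frame3$localizers, function(g) {
    f <- sp_forward(g, pl)
    correspondences(solve_classic(f, g), f)
  })
  expect_equal(nrow(do.call(rbind, cs1)), 3)
  fr4 <- build_frame("sp", aspects = c("anterior", "left", "right",
                                       "posterior"))
  cs12 <- lapply(fr4$localizers, function(g) {
    f <- sp_forward(g, pl)
    correspondences(solve_three_point(f, g), f)
  })
  expect_equal(nrow(do.call(rbind, cs12)), 12)
  expect_true(all(do.call(rbind, cs12)$kind == "full"))
})
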