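# Independent numerical oracle for the three-point solve.
#
# Uses a different elimination than the package solver: parameterize
# by the rod-B height b, solve the two inner distance constraints in
# closed form per sign branch, and root-find the remaining outer
# constraint in b by bracketed bisection (uniroot) over a fine grid,
# with explicit handling of root pairs that fall inside one grid
# interval. Branch selection mirrors the documented rule: nearest to
# the classic estimate, near-ties broken toward the greater rod-B
# height.
oracle_three_point <- function(d, tan_alpha, extent, npts = 20001) {
  T <- tan_alpha^2
  d1 <- d[["AB"]]; d2 <- d[["BC"]]; d3 <- d[["AC"]]
  hc <- d3 / (2 * tan_alpha)
  tol_h <- 1e-7 * max(extent, 1)
  # fold preference, mirroring the solver: if the collinear-projection
  # point satisfies all three exact equations within the residual
  # tolerance, the distances cannot resolve a split around the fold
  e <- d1 - d2
  s0 <- d3^2 / sqrt(T * d3^2 + e^2)
  q0 <- s0 * e / d3
  af <- (s0 + q0) / 2; cf <- (s0 - q0) / 2
  bf <- if (af + cf > 0) 2 * af * cf / (af + cf) else NA_real_
  if (is.finite(bf)) {
    fres <- max(abs(T * af^2 + (af - bf)^2 - d1^2),
                abs(T * cf^2 + (cf - bf)^2 - d2^2),
                abs(T * (af + cf)^2 + (cf - af)^2 - d3^2))
    if (fres <= 1e-9 * max(d3^2, 1) &&
        min(af, bf, cf) >= -tol_h && max(af, bf, cf) <= extent + tol_h)
      return(c(A = af, B = bf, C = cf))
  }
  sols <- list()
  bcap <- min(extent, d1 * sqrt((1 + T) / T), d2 * sqrt((1 + T) / T))
  if (bcap <= 0) return(NULL)
  # uniform grid plus geometric refinement toward bcap, where the two
  # sign families meet (sqrt vanishes) and root pairs can crowd the
  # boundary
  bs <- sort(unique(c(seq(0, bcap, length.out = npts),
                      bcap * (1 - 10^seq(-3, -12, by = -0.5)))))
  for (sa in c(-1, 1)) for (sc in c(-1, 1)) {
    g3 <- function(b) {
      D1 <- d1^2 * (1 + T) - T * b^2
      D2 <- d2^2 * (1 + T) - T * b^2
      a <- (b + sa * sqrt(pmax(D1, 0))) / (1 + T)
      cc <- (b + sc * sqrt(pmax(D2, 0))) / (1 + T)
      ifelse(D1 < 0 | D2 < 0, NA_real_,
             T * (a + cc)^2 + (cc - a)^2 - d3^2)
    }
    keep_root <- function(b) {
      D1 <- d1^2 * (1 + T) - T * b^2
      D2 <- d2^2 * (1 + T) - T * b^2
      a <- (b + sa * sqrt(max(D1, 0))) / (1 + T)
      cc <- (b + sc * sqrt(max(D2, 0))) / (1 + T)
      if (a >= -tol_h && cc >= -tol_h &&
          a <= extent + tol_h && cc <= extent + tol_h)
        sols[[length(sols) + 1]] <<- c(A = a, B = b, C = cc)
    }
    vals <- g3(bs)
    sgn <- which(!is.na(vals[-1]) & !is.na(vals[-length(vals)]) &
                   vals[-1] * vals[-length(vals)] <= 0)
    for (k in sgn) {
      r <- tryCatch(stats::uniroot(g3, c(bs[k], bs[k + 1]), tol = 1e-15),
                    error = function(e) NULL)
      if (!is.null(r)) keep_root(r$root)
    }
    v <- vals; v[is.na(v)] <- Inf
    loc <- which(diff(sign(diff(v))) > 0) + 1
    for (k in loc) {
      if (k <= 1 || k >= length(bs) || v[k] < 0) next
      op <- stats::optimize(g3, c(bs[k - 1], bs[k + 1]), tol = 1e-14)
      if (op$objective < 0) {
        r1 <- tryCatch(stats::uniroot(g3, c(bs[k - 1], op$minimum),
                                      tol = 1e-15), error = function(e) NULL)
        r2 <- tryCatch(stats::uniroot(g3, c(op$minimum, bs[k + 1]),
                                      tol = 1e-15), error = function(e) NULL)
        if (!is.null(r1)) keep_root(r1$root)
        if (!is.null(r2)) keep_root(r2$root)
      } else if (op$objective < 1e-9 * max(d3^2, 1)) keep_root(op$minimum)
    }
  }
  if (!length(sols)) return(NULL)
  best <- NULL; best_score <- Inf
  for (s in sols) {
    score <- sum((s - hc)^2)
    tie <- is.finite(best_score) &&
      abs(score - best_score) <= 1e-6 * (1 + min(score, best_score))
    if ((score < best_score && !tie) || (tie && s[["B"]] > best[["B"]])) {
      best <- s; best_score <- score
    }
  }
  best
}
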