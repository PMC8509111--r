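# Image-to-frame registration.
#
# The map from image (u, v) to frame (x, y, z) for a fixed slice is
# affine, so it is captured by a 3 x 3 matrix M acting on the row
# vector [u, v, 1]. With more correspondences than unknowns the
# columns are fit independently by ordinary least squares; (x, y)-only
# records (from N-localizer vertical rods) enter the x and y columns
# but never the z column.

#' Fit the 3 x 3 image-to-frame transformation
#'
#' Solves each output column by unweighted linear least squares over
#' the design matrix `[u, v, 1]`. The `x` and `y` columns use all
#' records; the `z` column uses only full records. At least three
#' non-collinear full records are required.
#'
#' @param cs Correspondence data frame as produced by
#'   [correspondences()] (columns `u`, `v`, `x`, `y`, `z`, and
#'   optionally `kind`; rows from several localizers may be bound
#'   together with `rbind`).
#' @return A 3 x 3 matrix of class `"frame_transform"` mapping
#'   `[u, v, 1]` to `[x, y, z]`, with the residual sum of squares per
#'   column in attribute `"rss"`.
#' @export
fit_transform <- function(cs) {
  stopifnot(is.data.frame(cs), all(c("u", "v", "x", "y", "z") %in% names(cs)))
  kind <- if ("kind" %in% names(cs)) cs$kind else rep("full", nrow(cs))
  full <- kind == "full"
  if (sum(full) < 3)
    stop("at least 3 full (u,v) <-> (x,y,z) records are required",
         call. = FALSE)
  A <- cbind(cs$u, cs$v, 1)
  qr_all <- qr(A)
  qr_full <- qr(A[full, , drop = FALSE])
  if (qr_all$rank < 3 || qr_full$rank < 3)
    stop("degenerate fit: fiducial (u,v) coordinates are collinear",
         call. = FALSE)
  cxy <- qr.coef(qr_all, cbind(cs$x, cs$y))
  cz <- qr.coef(qr_full, cs$z[full])
  M <- cbind(cxy, cz)
  dimnames(M) <- list(c("u", "v", "1"), c("x", "y", "z"))
  fitted_xy <- A %*% cxy
  rss <- c(colSums((cbind(cs$x, cs$y) - fitted_xy)^2),
           sum((cs$z[full] - A[full, , drop = FALSE] %*% cz)^2))
  names(rss) <- c("x", "y", "z")
  structure(M, rss = rss, class = c("frame_transform", "matrix"))
}

#' Apply an image-to-frame transformation to target points
#'
#' @param M A `"frame_transform"` (or any 3 x 3 matrix) mapping
#'   `[u, v, 1]` to `[x, y, z]`.
#' @param target Numeric length-2 `(u, v)`, or an n x 2 matrix of
#'   target points (mm).
#' @return Frame coordinates: numeric length-3 for a single target, or
#'   an n x 3 matrix.
#' @export
apply_transform <- function(M, target) {
  stopifnot(all(dim(M) == c(3, 3)))
  single <- is.null(dim(target))
  tm <- if (single) matrix(as.numeric(target), 1, 2) else as.matrix(target)
  stopifnot(ncol(tm) == 2)
  out <- cbind(tm, 1) %*% unclass(M)
  colnames(out) <- c("x", "y", "z")
  if (single) drop(out) else out
}

#' @export
print.frame_transform <- function(x, ...) {
  cat("<frame_transform> [u, v, 1] %*% M = [x, y, z]\n")
  print(unclass(x)[, ])
  cat(sprintf("residual sum of squares: x %.3g, y %.3g, z %.3g mm^2\n",
              attr(x, "rss")["x"], attr(x, "rss")["y"], attr(x, "rss")["z"]))
  invisible(x)
}
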