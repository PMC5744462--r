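#' Fibers
#'
#' A fiber is an ordered 3-D polyline stored as a plain numeric matrix with
#' one row per point and columns x, y, z, in millimetres (world space).
#' Voxel indices never appear in fiber coordinates; all metric parameters of
#' the pipeline (length bounds, distance cutoffs) are in mm.
#'
#' @name fiber
NULL

#' Arc length of a fiber
#'
#' Sum of consecutive Euclidean segment lengths of the polyline.
#'
#' @param f numeric matrix, one point per row (x, y, z), mm.
#' @return Length in mm (0 for a degenerate single-point polyline).
#' @export
#' @examples
#' fiber_length(rbind(c(0, 0, 0), c(30, 40, 0)))  # 50
fiber_length <- function(f) {
  f <- as_fiber_matrix(f)
  if (nrow(f) < 2L) return(0)
  seg <- diff(f)
  sum(sqrt(rowSums(seg^2)))
}

#' Resample a fiber to equidistant points
#'
#' Re-parameterizes the polyline by cumulative chord length and linearly
#' interpolates `n` points at uniform arc-length spacing. The first and last
#' points are the original endpoints. Centroid fibers are conventionally
#' resampled to 51 points before any distance computation, so that
#' corresponding-point distances are defined.
#'
#' @param f numeric matrix of points (mm), at least 2 distinct points.
#' @param n number of output points (default 51).
#' @return An `n` x 3 matrix with uniform arc-length spacing.
#' @export
resample_fiber <- function(f, n = 51L) {
  f <- as_fiber_matrix(f)
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (nrow(f) < 2L) stop("fiber must have at least 2 points")
  seg <- sqrt(rowSums(diff(f)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate fiber: all points identical")
  # drop zero-length segments so approx() sees strictly increasing knots
  keep <- c(TRUE, seg > 0)
  fk <- f[keep, , drop = FALSE]
  sk <- s[keep]
  at <- seq(0, total, length.out = n)
  out <- vapply(1:3, function(c) {
    stats::approx(sk, fk[, c], xout = at, rule = 2)$y
  }, numeric(n))
  out[1L, ] <- f[1L, ]
  out[n, ] <- f[nrow(f), ]
  dimnames(out) <- NULL
  out
}

#' Oversample a fiber
#'
#' Resample to `factor` times its current point count; used before cortical
#' endpoint detection so that at least one extremity point falls inside the
#' connected ROI voxels.
#'
#' @param f fiber matrix.
#' @param factor integer oversampling factor.
#' @return Resampled fiber matrix.
#' @export
oversample_fiber <- function(f, factor = 10L) {
  f <- as_fiber_matrix(f)
  resample_fiber(f, nrow(f) * as.integer(factor))
}

#' Reverse a fiber's point order
#' @param f fiber matrix.
#' @return The same polyline traversed in the opposite direction.
#' @export
reverse_fiber <- function(f) {
  f <- as_fiber_matrix(f)
  f[rev(seq_len(nrow(f))), , drop = FALSE]
}

as_fiber_matrix <- function(f) {
  if (!is.matrix(f)) f <- matrix(as.numeric(f), ncol = 3L)
  if (ncol(f) != 3L) stop("a fiber is an n x 3 matrix of xyz coordinates")
  if (!all(is.finite(f))) stop("fiber coordinates must be finite")
  storage.mode(f) <- "double"
  f
}

# Pack a list of equally-sampled fibers into the flat layout the C++
# kernels expect (fiber-major, point-major, xyz contiguous).
pack_fibers <- function(fibers) {
  np <- unique(vapply(fibers, nrow, integer(1)))
  if (length(np) != 1L)
    stop("all fibers must share the same point count; resample first")
  list(coords = as.numeric(t(do.call(rbind, fibers))),
       n = length(fibers), np = np)
}
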