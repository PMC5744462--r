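#' Symmetrized maximum corresponding-point distance between two fibers
#'
#' For two fibers with the same point count, computes the maximum Euclidean
#' distance between corresponding points, taken in both traversal
#' directions, and returns the smaller of the two:
#' `min( max_i ||a_i - b_i||, max_i ||a_i - b_(N-1-i)|| )`.
#' The reversal makes the metric independent of the (arbitrary) orientation
#' in which a streamline was tracked. It is the most restrictive of the
#' usual streamline distances: it is 0 only when the fibers coincide
#' point-for-point (possibly reversed).
#'
#' @param a,b fiber matrices with equal point counts (resample first).
#' @return Distance in mm.
#' @export
d_me <- function(a, b) {
  a <- as_fiber_matrix(a); b <- as_fiber_matrix(b)
  if (nrow(a) != nrow(b))
    stop("fibers have different point counts; resample to a common count")
  cpp_dme(a, b)
}

#' Length-difference penalty
#'
#' The dimensionless normalization factor added to the corresponding-point
#' distance during segmentation:
#' `(|l_a - l_b| / max(l_a, l_b) + 1)^2 - 1`.
#' It is 0 for equal lengths and always below 3 (the length ratio term is
#' below 1), and penalizes pairing an atlas centroid with a subject fiber
#' of very different length.
#'
#' @param l_a,l_b fiber lengths in mm (positive).
#' @return Dimensionless penalty, added as-is to a mm distance.
#' @export
dnf <- function(l_a, l_b) {
  if (any(l_a <= 0) || any(l_b <= 0)) stop("fiber lengths must be positive")
  (abs(l_a - l_b) / pmax(l_a, l_b) + 1)^2 - 1
}

#' Length-normalized fiber distance
#'
#' `d_me(a, b)` plus the [dnf()] length penalty when the penalty is
#' positive — the distance used to decide whether a subject fiber is close
#' enough to an atlas bundle centroid during segmentation. Always at least
#' `d_me(a, b)`.
#'
#' @param a,b fiber matrices with equal point counts.
#' @param l_a,l_b lengths to use for the penalty; default the polyline
#'   lengths of `a` and `b` (pass pre-resampling lengths when available).
#' @return Distance in mm (plus the dimensionless penalty).
#' @export
d_men <- function(a, b, l_a = fiber_length(a), l_b = fiber_length(b)) {
  pen <- dnf(l_a, l_b)
  d_me(a, b) + if (pen > 0) pen else 0
}

#' Sparse pairwise distances under a cutoff
#'
#' Computes `d_me` for every unordered fiber pair and stores exactly the
#' pairs at or below `d_max` — the sparse distance set from which the
#' affinity graph is built. For whole-hemisphere centroid sets only a few
#' percent of the pairs survive a 30 mm cutoff, which is what makes the
#' clustering tractable.
#'
#' @param fibers list of fiber matrices with a common point count.
#' @param d_max cutoff in mm (default 30, the usual cluster diameter bound).
#' @return An object of class `sparse_dist`: parallel vectors `i`, `j`
#'   (1-based, `i < j`, lexicographic order) and `d` (mm), plus `d_max` and
#'   `n_elements`.
#' @export
sparse_pairwise <- function(fibers, d_max = 30) {
  pk <- pack_fibers(fibers)
  sp <- cpp_sparse_pairwise(pk$coords, pk$n, pk$np, d_max)
  structure(list(i = sp$i, j = sp$j, d = sp$d, d_max = d_max,
                 n_elements = pk$n),
            class = "sparse_dist")
}

#' @export
print.sparse_dist <- function(x, ...) {
  cat(sprintf("<sparse_dist> %d elements, %d pairs <= %.1f mm (%.1f%% of all)\n",
              x$n_elements, length(x$d), x$d_max,
              if (x$n_elements > 1)
                200 * length(x$d) / (x$n_elements * (x$n_elements - 1))
              else 0))
  invisible(x)
}

#' Intersection fractions between two bundles
#'
#' For each bundle, the fraction of its fibers having at least one fiber of
#' the other bundle closer than `d_fiber` (strict `<`). A pair of bundles
#' from independent groups is considered the same anatomical bundle when
#' both fractions exceed 0.5.
#'
#' @param ba,bb bundles: lists of fiber matrices (or [bundle()] objects).
#' @param d_fiber closeness threshold in mm (default 5).
#' @return Named numeric vector `c(frac_a, frac_b)`, each in \[0, 1\].
#' @export
intersection_fractions <- function(ba, bb, d_fiber = 5) {
  fa <- bundle_fibers(ba); fb <- bundle_fibers(bb)
  if (!length(fa) || !length(fb)) stop("bundles must be nonempty")
  pa <- pack_fibers(fa); pb <- pack_fibers(fb)
  if (pa$np != pb$np) stop("bundles must share a common point count")
  mina <- cpp_cross_min(pa$coords, pa$n, pb$coords, pb$n, pa$np)
  minb <- cpp_cross_min(pb$coords, pb$n, pa$coords, pa$n, pa$np)
  c(frac_a = mean(mina < d_fiber), frac_b = mean(minb < d_fiber))
}

#' Mean distance between two bundles
#'
#' Mean of `d_me` over all cross pairs (`mode = "all_pairs"`), or `d_me`
#' between the two bundle centroids (`mode = "centroid"`). Used to compare
#' bundle sets, e.g. an atlas against an independently built one, under a
#' restrictive maximum mean distance.
#'
#' @param ba,bb bundles (lists of fiber matrices or [bundle()] objects).
#' @param mode `"all_pairs"` (default) or `"centroid"`.
#' @return Distance in mm; symmetric in its arguments.
#' @export
bundle_mean_distance <- function(ba, bb, mode = c("all_pairs", "centroid")) {
  mode <- match.arg(mode)
  fa <- bundle_fibers(ba); fb <- bundle_fibers(bb)
  if (!length(fa) || !length(fb)) stop("bundles must be nonempty")
  if (mode == "centroid")
    return(d_me(pointwise_centroid(fa), pointwise_centroid(fb)))
  pa <- pack_fibers(fa); pb <- pack_fibers(fb)
  if (pa$np != pb$np) stop("bundles must share a common point count")
  mean(cpp_cross_dme(pa$coords, pa$n, pb$coords, pb$n, pa$np))
}

bundle_fibers <- function(b) {
  if (inherits(b, "bundle")) b$fibers
  else if (inherits(b, "centroid_set")) b$fibers
  else lapply(b, as_fiber_matrix)
}
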