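#' Select short-fiber centroids by length
#'
#' Keeps centroids whose polyline length lies between `min_mm` and `max_mm`
#' inclusive (35-85 mm by default). Shorter fibers are mostly tractography
#' artifacts with highly variable shape; longer ones are not U-shaped short
#' association fibers. Lengths recorded in the set (computed on the
#' original geometry, before any resampling) are used.
#'
#' @param cs a [centroid_set()].
#' @param min_mm,max_mm inclusive length bounds in mm.
#' @return The filtered set.
#' @export
length_filter <- function(cs, min_mm = 35, max_mm = 85) {
  subset_set(cs, cs$lengths >= min_mm & cs$lengths <= max_mm)
}

#' Deep-white-matter reference set
#'
#' A named collection of deep-white-matter (DWM) bundles — e.g. anterior
#' and posterior arcuate segments, uncinate, cingulum portions, fornix,
#' thalamic radiations, and per-hemisphere portions of the corpus
#' callosum — used to discard short centroids that are really fragments of
#' known long tracts. Because DWM bundles are dense and stable across
#' subjects, only a random 20% sample of their fibers is compared against
#' (about 400 fibers per bundle at atlas scale).
#'
#' @param bundles named list of fiber lists, all resampled to a common
#'   point count.
#' @param sample_fraction fraction of fibers sampled per bundle (default
#'   0.2).
#' @param seed integer seed making the sampling reproducible.
#' @return An object of class `dwm_reference`.
#' @export
dwm_reference <- function(bundles, sample_fraction = 0.2, seed = 1L) {
  if (sample_fraction <= 0 || sample_fraction > 1)
    stop("sample_fraction must be in (0, 1]")
  bundles <- lapply(bundles, function(b) lapply(b, as_fiber_matrix))
  structure(list(bundles = bundles, sample_fraction = sample_fraction,
                 seed = as.integer(seed)),
            class = "dwm_reference")
}

# Draw the per-bundle sample once, uniformly without replacement.
sample_dwm <- function(ref) {
  out <- withr::with_seed(ref$seed, {
    lapply(ref$bundles, function(b) {
      k <- max(1L, ceiling(ref$sample_fraction * length(b)))
      b[sort(sample.int(length(b), k))]
    })
  })
  unlist(out, recursive = FALSE, use.names = FALSE)
}

#' Remove centroids resembling deep-white-matter bundles
#'
#' Discards every centroid whose minimum `d_me` to the sampled reference
#' fibers is below `threshold_mm` (strict `<`; default 10 mm). The
#' threshold is restrictive for long bundles, so only centroids that are
#' truly DWM-like — cut long-tract fibers and similar artifacts — are
#' removed. Both sets must already be in a common (affine-normalized)
#' space.
#'
#' @param cs a [centroid_set()] with fibers resampled to the reference's
#'   point count.
#' @param ref a [dwm_reference()].
#' @param threshold_mm discard threshold in mm (default 10).
#' @return The filtered set; an empty reference passes everything through
#'   with a warning.
#' @export
dwm_filter <- function(cs, ref, threshold_mm = 10) {
  stopifnot(inherits(ref, "dwm_reference"))
  sampled <- sample_dwm(ref)
  if (!length(sampled)) {
    warning("empty DWM reference; no centroids discarded")
    return(cs)
  }
  if (!length(cs$fibers)) return(cs)
  pc <- pack_fibers(cs$fibers)
  pr <- pack_fibers(sampled)
  if (pc$np != pr$np)
    stop("centroids and DWM reference must share a common point count")
  mind <- cpp_cross_min(pc$coords, pc$n, pr$coords, pr$n, pc$np)
  subset_set(cs, mind >= threshold_mm)
}
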