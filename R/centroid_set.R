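#' Centroid sets
#'
#' A `centroid_set` is one subject's collection of fiber centroids, with the
#' metadata needed before any intersubject operation: the subject id, the
#' hemisphere the centroids belong to, and the space their coordinates live
#' in (`native`, `talairach`, or `template`). Fiber lengths are recorded on
#' the geometry the set was built from, so a later resampling does not
#' change the lengths the selection filters see.
#'
#' @param fibers list of fiber matrices (mm).
#' @param subject_id subject identifier.
#' @param hemisphere `"left"` or `"right"`.
#' @param space `"native"`, `"talairach"` or `"template"`.
#' @param lengths optional per-fiber lengths (mm); computed from the fibers
#'   when missing.
#' @return An object of class `centroid_set`.
#' @export
centroid_set <- function(fibers, subject_id = "s1",
                         hemisphere = c("left", "right"),
                         space = c("native", "talairach", "template"),
                         lengths = NULL) {
  hemisphere <- match.arg(hemisphere)
  space <- match.arg(space)
  fibers <- lapply(fibers, as_fiber_matrix)
  if (is.null(lengths)) lengths <- vapply(fibers, fiber_length, numeric(1))
  if (length(lengths) != length(fibers))
    stop("lengths must match the number of fibers")
  structure(list(fibers = fibers, subject_id = as.character(subject_id),
                 hemisphere = hemisphere, space = space,
                 lengths = as.numeric(lengths)),
            class = "centroid_set")
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("<centroid_set> subject %s, %s hemisphere, %s space: %d fibers\n",
              x$subject_id, x$hemisphere, x$space, length(x$fibers)))
  if (length(x$fibers)) {
    cat(sprintf("  point counts: %s; lengths %.1f-%.1f mm\n",
                paste(unique(vapply(x$fibers, nrow, integer(1))),
                      collapse = "/"),
                min(x$lengths), max(x$lengths)))
  }
  invisible(x)
}

#' @export
length.centroid_set <- function(x) length(x$fibers)

#' Resample every fiber of a centroid set
#'
#' @param cs a `centroid_set`.
#' @param n target point count (default 51).
#' @return The set with every fiber resampled; recorded lengths are kept.
#' @export
resample_set <- function(cs, n = 51L) {
  cs$fibers <- lapply(cs$fibers, resample_fiber, n = n)
  cs
}

subset_set <- function(cs, idx) {
  cs$fibers <- cs$fibers[idx]
  cs$lengths <- cs$lengths[idx]
  cs
}
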