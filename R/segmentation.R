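#' Per-bundle segmentation thresholds from bundle length
#'
#' Segmentation accepts a subject fiber into a bundle only when its
#' length-normalized distance to the bundle centroid is at most a
#' restrictive threshold between 6 and 8 mm, set according to bundle
#' length: the mean fiber length of the bundle is mapped linearly from
#' \[35, 85\] mm onto \[6, 8\] mm (clamped), so longer bundles tolerate
#' slightly more spread.
#'
#' @param mean_length_mm mean atlas-bundle fiber length(s), mm.
#' @param thr_range threshold range in mm (default `c(6, 8)`).
#' @param len_range length range mapped onto it (default `c(35, 85)`).
#' @return Threshold(s) in mm.
#' @export
segmentation_threshold <- function(mean_length_mm, thr_range = c(6, 8),
                                   len_range = c(35, 85)) {
  t <- (mean_length_mm - len_range[1L]) / diff(len_range)
  pmin(pmax(thr_range[1L] + t * diff(thr_range), thr_range[1L]),
       thr_range[2L])
}

#' Segment a subject's fibers with an atlas
#'
#' Computes, for every subject fiber, the length-normalized distance
#' [d_men()] to each atlas bundle centroid, and assigns the fiber to the
#' closest bundle if and only if that distance is within the bundle's
#' threshold. Each fiber goes to at most one bundle (the arg-min), keeping
#' bundle volumes well defined.
#'
#' @param cs the subject's [centroid_set()], resampled to the atlas point
#'   count and in the atlas space.
#' @param a an [atlas()].
#' @param thresholds per-bundle thresholds in mm; default
#'   [segmentation_threshold()] of each bundle's mean fiber length.
#' @return An object of class `segmentation_result`: tibble `assignments`
#'   (`fiber`, `bundle_idx`, `bundle_id`, `label`, `distance`), the
#'   per-bundle tibble `bundles` (`bundle_id`, `label`, `n_fibers`,
#'   `threshold`, `present`), and the inputs needed downstream.
#' @export
segment_subject <- function(cs, a, thresholds = NULL) {
  stopifnot(inherits(cs, "centroid_set"), inherits(a, "atlas"))
  if (!length(a$bundles)) stop("atlas has no bundles")
  cents <- lapply(a$bundles, bundle_centroid)
  np <- nrow(cents[[1L]])
  if (length(cs$fibers) &&
      any(vapply(cs$fibers, nrow, integer(1)) != np))
    stop("subject fibers must be resampled to the atlas point count (", np,
         ")")
  mean_len <- vapply(a$bundles, function(b)
    mean(vapply(b$fibers, fiber_length, numeric(1))), numeric(1))
  if (is.null(thresholds)) thresholds <- segmentation_threshold(mean_len)
  thresholds <- rep_len(thresholds, length(a$bundles))
  nf <- length(cs$fibers)
  assign_idx <- integer(0); assign_d <- numeric(0); assign_f <- integer(0)
  if (nf) {
    pc <- pack_fibers(cs$fibers)
    pa <- pack_fibers(cents)
    dm <- cpp_cross_dme(pc$coords, pc$n, pa$coords, pa$n, np)
    cent_len <- vapply(cents, fiber_length, numeric(1))
    fib_len <- vapply(cs$fibers, fiber_length, numeric(1))
    pen <- outer(fib_len, cent_len, function(x, y) dnf(x, y))
    dm <- dm + pen
    best <- max.col(-dm, ties.method = "first")
    bestd <- dm[cbind(seq_len(nf), best)]
    ok <- bestd <= thresholds[best]
    assign_f <- which(ok)
    assign_idx <- best[ok]
    assign_d <- bestd[ok]
  }
  ids <- vapply(a$bundles, `[[`, character(1), "id")
  labs <- vapply(a$bundles, function(b) b$label %||% NA_character_,
                 character(1))
  counts <- tabulate(assign_idx, nbins = length(a$bundles))
  structure(list(
    assignments = tibble::tibble(
      fiber = assign_f, bundle_idx = assign_idx, bundle_id = ids[assign_idx],
      label = labs[assign_idx], distance = assign_d),
    bundles = tibble::tibble(
      bundle_id = ids, label = labs, n_fibers = counts,
      threshold = thresholds, present = counts > 0L),
    subject_id = cs$subject_id, hemisphere = cs$hemisphere,
    fibers = cs$fibers, n_subject_fibers = nf),
    class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation> subject %s: %d of %d fibers assigned to %d of %d bundles\n",
    x$subject_id, nrow(x$assignments), x$n_subject_fibers,
    sum(x$bundles$present), nrow(x$bundles)))
  invisible(x)
}

#' Drop small segmented bundles
#'
#' Bundles with fewer than `min_fibers` assigned fibers (default 10) are
#' marked absent for the subject — too few fibers to trust in volume or
#' laterality analyses. A 10-fiber bundle is kept ("less than 10" excludes
#' only 9 and below).
#'
#' @param sr a [segment_subject()] result.
#' @param min_fibers minimum fiber count (default 10).
#' @return The result with small bundles marked `present = FALSE` and
#'   their assignments removed.
#' @export
filter_small <- function(sr, min_fibers = 10L) {
  stopifnot(inherits(sr, "segmentation_result"))
  small <- which(sr$bundles$n_fibers < min_fibers)
  sr$bundles$present[small] <- FALSE
  sr$assignments <- sr$assignments[!(sr$assignments$bundle_idx %in% small), ]
  sr
}

#' Voxel volume of a segmented bundle
#'
#' Rasterizes the fibers onto an isotropic grid (2 mm by default, anchored
#' at the space origin with half-open cells), counts in each voxel the
#' number of *distinct* fibers with at least one point in it, and returns
#' the number of voxels crossed by more than one fiber — the binarized
#' bundle mask. A single fiber therefore has volume 0, and duplicating
#' fibers beyond multiplicity 2 changes nothing.
#'
#' @param fibers list of fiber matrices (nonempty).
#' @param voxel_mm isotropic voxel size in mm (default 2).
#' @param min_count voxel kept when at least this many distinct fibers
#'   cross it (default 2, i.e. "more than one fiber").
#' @param count `"fibers"` (default: a fiber counts once per voxel) or
#'   `"points"` (every resampled point counts).
#' @return Voxel count (integer).
#' @export
bundle_volume <- function(fibers, voxel_mm = 2, min_count = 2L,
                          count = c("fibers", "points")) {
  count <- match.arg(count)
  if (!length(fibers)) stop("fibers must be nonempty")
  keys <- unlist(lapply(fibers, function(f) {
    v <- floor(as_fiber_matrix(f) / voxel_mm)
    k <- paste(v[, 1], v[, 2], v[, 3])
    if (count == "fibers") unique(k) else k
  }))
  sum(table(keys) >= min_count)
}

#' Lateralization index of a bundle
#'
#' `LI = (R - L) / (R + L)` of the left/right bundle volumes; in \[-1, 1\],
#' negative when the bundle is left-lateralized. Undefined (NA) when both
#' volumes are 0.
#'
#' @param vol_left,vol_right voxel volumes.
#' @return LI, or `NA` when undefined.
#' @export
lateralization_index <- function(vol_left, vol_right) {
  tot <- vol_left + vol_right
  ifelse(tot > 0, (vol_right - vol_left) / tot, NA_real_)
}

#' Two-sample t-test on bundle volumes
#'
#' Classical unpaired two-tailed t-test with pooled variance between the
#' per-subject left and right volumes of a bundle (Welch's correction
#' available but off by default). The degenerate case of two constant
#' samples with equal means returns `t = 0, p = 1`; constant samples with
#' different means return an infinite statistic and `p = 0`.
#'
#' @param left,right numeric vectors of per-subject volumes (>= 2 each).
#' @param alpha significance level (default 0.05).
#' @param welch use Welch's unequal-variance correction.
#' @return A list `t`, `p`, `df`, `significant`.
#' @export
volume_ttest <- function(left, right, alpha = 0.05, welch = FALSE) {
  if (length(left) < 2L || length(right) < 2L)
    stop("need at least 2 observations per side")
  if (stats::sd(left) == 0 && stats::sd(right) == 0) {
    if (mean(left) == mean(right))
      return(list(t = 0, p = 1, df = length(left) + length(right) - 2L,
                  significant = FALSE))
    return(list(t = sign(mean(left) - mean(right)) * Inf, p = 0,
                df = length(left) + length(right) - 2L,
                significant = TRUE))
  }
  tt <- stats::t.test(left, right, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), significant = tt$p.value < alpha)
}

# One-sample t-test of per-subject lateralization indices against 0
# (the non-default laterality test).
li_ttest <- function(li, alpha = 0.05) {
  li <- li[is.finite(li)]
  if (length(li) < 2L)
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                significant = FALSE))
  if (stats::sd(li) == 0) {
    if (mean(li) == 0)
      return(list(t = 0, p = 1, df = length(li) - 1L, significant = FALSE))
    return(list(t = sign(mean(li)) * Inf, p = 0, df = length(li) - 1L,
                significant = TRUE))
  }
  tt <- stats::t.test(li, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       significant = tt$p.value < alpha)
}

#' Laterality analysis across segmented subjects
#'
#' For every bundle segmented in both hemispheres of a symmetrized atlas,
#' collects the per-subject left and right volumes, computes per-subject
#' lateralization indices, and tests the volume difference with
#' [volume_ttest()]. Absent bundles (e.g. after [filter_small()])
#' contribute volume 0 and are excluded from a subject's LI when absent on
#' both sides.
#'
#' @param left_results,right_results lists of [segment_subject()] results
#'   (parallel over subjects) for the left and right hemispheres.
#' @param labels bundle labels to analyze; default the labels shared by
#'   both sides.
#' @param voxel_mm voxel size for [bundle_volume()] (default 2).
#' @param min_fibers small-bundle cutoff applied per subject (default 10).
#' @param alpha significance level.
#' @param test `"volumes"` (default: unpaired left-vs-right volume t-test)
#'   or `"li"` (one-sample t-test of the per-subject LIs against 0).
#' @return A `laterality_report`: a tibble with one row per bundle
#'   (`label`, `n_subjects`, `mean_vol_left`, `mean_vol_right`, `mean_li`,
#'   `t`, `p`, `significant`), with the per-subject volume table in
#'   attribute `"volumes"`.
#' @export
laterality_report <- function(left_results, right_results, labels = NULL,
                              voxel_mm = 2, min_fibers = 10L, alpha = 0.05,
                              test = c("volumes", "li")) {
  test <- match.arg(test)
  stopifnot(length(left_results) == length(right_results))
  vol_table <- function(sr) {
    sr <- filter_small(sr, min_fibers)
    labs <- sr$bundles$label
    vols <- vapply(seq_along(labs), function(k) {
      idx <- sr$assignments$fiber[sr$assignments$bundle_idx == k]
      if (!sr$bundles$present[k] || !length(idx)) return(0L)
      as.integer(bundle_volume(sr$fibers[idx], voxel_mm))
    }, integer(1))
    stats::setNames(vols, labs)
  }
  lv <- lapply(left_results, vol_table)
  rv <- lapply(right_results, vol_table)
  if (is.null(labels))
    labels <- intersect(names(lv[[1L]]), names(rv[[1L]]))
  vget <- function(v, lb) if (lb %in% names(v)) v[[lb]] else 0L
  rows <- lapply(labels, function(lb) {
    L <- vapply(lv, vget, integer(1), lb = lb)
    R <- vapply(rv, vget, integer(1), lb = lb)
    li <- lateralization_index(L, R)
    tt <- if (test == "volumes") {
      volume_ttest(as.numeric(L), as.numeric(R), alpha = alpha)
    } else {
      li_ttest(li, alpha = alpha)
    }
    tibble::tibble(label = lb, n_subjects = length(L),
                   mean_vol_left = mean(L), mean_vol_right = mean(R),
                   mean_li = mean(li, na.rm = TRUE), t = tt$t, p = tt$p,
                   significant = tt$significant)
  })
  out <- do.call(rbind, rows)
  vols <- do.call(rbind, lapply(seq_along(lv), function(s) {
    tibble::tibble(subject = s, label = labels,
                   vol_left = vapply(labels, vget, integer(1),
                                     v = lv[[s]]),
                   vol_right = vapply(labels, vget, integer(1),
                                      v = rv[[s]]))
  }))
  attr(out, "volumes") <- vols
  class(out) <- c("laterality_report", class(out))
  out
}
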