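#' Intersubject clustering of one group of subjects
#'
#' Pools the (already length- and DWM-filtered, resampled, normalized)
#' centroid sets of a group, computes the sparse distance set and affinity
#' graph, builds the average-link dendrogram, partitions it at `d_clmax`,
#' and keeps only clusters reproduced in at least `min_subject_frac` of the
#' group's subjects. Each kept cluster becomes a [bundle()].
#'
#' @param sets list of [centroid_set()] objects, one per subject, with a
#'   common point count and space.
#' @param d_clmax cluster diameter bound in mm (default 30).
#' @param sigma2 affinity scale in mm (default 60).
#' @param min_subject_frac reproducibility fraction (default 0.75).
#' @param id_prefix prefix for bundle ids.
#' @return An [atlas()] of representative bundles; stage element counts are
#'   attached as attribute `"counts"`.
#' @export
group_atlas <- function(sets, d_clmax = 30, sigma2 = 60,
                        min_subject_frac = 0.75, id_prefix = "g") {
  fibers <- unlist(lapply(sets, `[[`, "fibers"), recursive = FALSE)
  subject_of <- rep(vapply(sets, `[[`, character(1), "subject_id"),
                    vapply(sets, function(s) length(s$fibers), integer(1)))
  hemisphere <- sets[[1L]]$hemisphere
  space <- sets[[1L]]$space
  sd <- sparse_pairwise(fibers, d_max = d_clmax)
  g <- build_affinity_graph(sd, sigma2 = sigma2)
  dg <- average_link_dendrogram(g)
  p <- adaptive_partition(dg, fibers, d_clmax = d_clmax)
  kept <- reproducibility_filter(p, subject_of, n_subjects = length(sets),
                                 min_frac = min_subject_frac)
  bundles <- lapply(seq_along(kept$clusters), function(k) {
    idx <- kept$clusters[[k]]
    bundle(fibers[idx], subject_of[idx],
           id = sprintf("%s_%03d", id_prefix, k), hemisphere = hemisphere,
           provenance = list(group = id_prefix))
  })
  out <- atlas(bundles, space = space, provenance = list(group = id_prefix))
  attr(out, "counts") <- c(centroids = length(fibers),
                           edges = length(sd$d),
                           clusters = length(p$clusters),
                           reproducible = length(kept$clusters))
  out
}

#' Robust atlas from two independent groups
#'
#' Runs [group_atlas()] on each group, matches the two resulting bundle
#' sets with [match_groups()], and fuses each matched pair. Bundles found
#' in only one group are discarded: the atlas keeps what replicates across
#' independent groups of subjects.
#'
#' @param sets1,sets2 per-subject centroid sets of the two groups.
#' @param d_fiber,min_match_frac intersection matching parameters (5 mm,
#'   0.5).
#' @inheritParams group_atlas
#' @return An [atlas()] of fused bundles; per-group atlases and the match
#'   table are attached as attributes `"groups"` and `"matches"`.
#' @export
robust_atlas <- function(sets1, sets2, d_clmax = 30, sigma2 = 60,
                         min_subject_frac = 0.75, d_fiber = 5,
                         min_match_frac = 0.5, id_prefix = "atlas") {
  a1 <- group_atlas(sets1, d_clmax, sigma2, min_subject_frac,
                    id_prefix = paste0(id_prefix, "1"))
  a2 <- group_atlas(sets2, d_clmax, sigma2, min_subject_frac,
                    id_prefix = paste0(id_prefix, "2"))
  matches <- match_groups(a1, a2, d_fiber = d_fiber, min_frac = min_match_frac)
  bundles <- lapply(seq_len(nrow(matches)), function(r) {
    fuse_bundles(a1$bundles[[matches$i1[r]]], a2$bundles[[matches$i2[r]]],
                 id = sprintf("%s_%03d", id_prefix, r))
  })
  out <- atlas(bundles, space = sets1[[1L]]$space,
               provenance = list(groups = c(paste0(id_prefix, 1:2))))
  attr(out, "groups") <- list(a1, a2)
  attr(out, "matches") <- matches
  out
}

#' Aggregate bagging repetitions into a final atlas
#'
#' Takes the atlases produced by repeated two-group atlas construction on
#' random subject subsets, computes a [bundle_centroid()] per bundle, runs
#' the same sparse-affinity average-link clustering and adaptive partition
#' over those centroids, and keeps the clusters whose member bundles
#' originate from at least `min_votes` distinct repetitions (8 of 10 by
#' default). Each kept cluster becomes a final bundle: the union of its
#' member bundles' fibers, with the repetition count as its vote.
#'
#' @param atlases list of [atlas()] objects (>= 2), one per repetition, in
#'   a common space. Each atlas's provenance should identify its
#'   repetition; list names are used otherwise.
#' @param d_clmax centroid cluster diameter bound in mm (default 30, the
#'   same value used inside each repetition).
#' @param sigma2 affinity scale in mm (default 60).
#' @param min_votes minimum distinct repetitions per kept cluster (default
#'   8).
#' @return An [atlas()] whose bundles carry `votes`.
#' @export
bagging_aggregate <- function(atlases, d_clmax = 30, sigma2 = 60,
                              min_votes = 8L) {
  if (!length(atlases)) stop("need at least one repetition")
  if (min_votes > length(atlases))
    stop("min_votes cannot exceed the number of repetitions")
  rep_ids <- names(atlases) %||% as.character(seq_along(atlases))
  rep_of <- list(); src <- list(); centroids <- list()
  for (k in seq_along(atlases)) {
    for (b in atlases[[k]]$bundles) {
      centroids[[length(centroids) + 1L]] <- bundle_centroid(b)
      rep_of[[length(rep_of) + 1L]] <- rep_ids[k]
      src[[length(src) + 1L]] <- b
    }
  }
  rep_of <- unlist(rep_of)
  sd <- sparse_pairwise(centroids, d_max = d_clmax)
  g <- build_affinity_graph(sd, sigma2 = sigma2)
  dg <- average_link_dendrogram(g)
  p <- adaptive_partition(dg, centroids, d_clmax = d_clmax)
  votes <- vapply(p$clusters, function(cl) length(unique(rep_of[cl])),
                  integer(1))
  keep <- which(votes >= min_votes)
  bundles <- lapply(seq_along(keep), function(k) {
    members <- src[p$clusters[[keep[k]]]]
    bundle(unlist(lapply(members, `[[`, "fibers"), recursive = FALSE),
           unlist(lapply(members, `[[`, "subjects")),
           id = sprintf("final_%03d", k),
           hemisphere = members[[1L]]$hemisphere,
           votes = votes[keep[k]],
           provenance = list(
             repetitions = sort(unique(rep_of[p$clusters[[keep[k]]]])),
             member_ids = vapply(members, `[[`, character(1), "id")))
  })
  atlas(bundles, space = atlases[[1L]]$space,
        provenance = list(bagging_reps = length(atlases),
                          min_votes = min_votes))
}

#' Bagged atlas construction driver
#'
#' Repeats the two-group robust atlas construction `reps` times: each
#' repetition samples `2 * group_size` subjects without replacement from
#' the pool, splits them into two groups, builds the [robust_atlas()], and
#' finally aggregates the repetitions with [bagging_aggregate()].
#' Per-repetition seeds are derived deterministically from `seed`.
#'
#' @param sets list of per-subject [centroid_set()] objects (the subject
#'   pool).
#' @param reps number of bagging repetitions (default 10).
#' @param group_size subjects per group (default 27; `2 * group_size` must
#'   not exceed the pool).
#' @param min_votes vote cutoff for [bagging_aggregate()] (default 8).
#' @param seed master seed.
#' @inheritParams robust_atlas
#' @return The aggregated [atlas()]; per-repetition atlases are attached as
#'   attribute `"repetitions"`.
#' @export
bagged_atlas <- function(sets, reps = 10L, group_size = 27L, min_votes = 8L,
                         d_clmax = 30, sigma2 = 60, min_subject_frac = 0.75,
                         d_fiber = 5, min_match_frac = 0.5, seed = 1L) {
  if (2L * group_size > length(sets))
    stop("pool has fewer subjects than 2 * group_size")
  atlases <- lapply(seq_len(reps), function(r) {
    idx <- withr::with_seed(derive_seed(seed, r), {
      sample(length(sets), 2L * group_size)
    })
    robust_atlas(sets[idx[seq_len(group_size)]],
                 sets[idx[group_size + seq_len(group_size)]],
                 d_clmax = d_clmax, sigma2 = sigma2,
                 min_subject_frac = min_subject_frac, d_fiber = d_fiber,
                 min_match_frac = min_match_frac,
                 id_prefix = sprintf("rep%02d", r))
  })
  names(atlases) <- sprintf("rep%02d", seq_len(reps))
  out <- bagging_aggregate(atlases, d_clmax = d_clmax, sigma2 = sigma2,
                           min_votes = min_votes)
  attr(out, "repetitions") <- atlases
  out
}

# Deterministic substream seed below 2^31, mixing a master seed with
# stream indices.
derive_seed <- function(seed, ...) {
  ks <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 0
  for (k in ks) h <- (h * 69069 + k * 12345 + 1) %% 2147483629
  as.integer(h)
}
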