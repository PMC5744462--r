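#' Build the sparse affinity graph from a distance set
#'
#' Converts stored distances to affinities `a = exp(-d / sigma2)`, where
#' `sigma2` is the similarity scale in mm (default 60). Only pairs kept by
#' the distance cutoff carry an edge; elements with no incident edge are
#' the unconnected elements `n_unconnected` and will remain singleton roots
#' of the dendrogram.
#'
#' @param sd a [sparse_pairwise()] result.
#' @param sigma2 similarity scale in mm (> 0).
#' @return An object of class `affinity_graph`.
#' @export
build_affinity_graph <- function(sd, sigma2 = 60) {
  stopifnot(inherits(sd, "sparse_dist"))
  if (sigma2 <= 0) stop("sigma2 must be positive")
  connected <- unique(c(sd$i, sd$j))
  structure(list(i = sd$i, j = sd$j, a = exp(-sd$d / sigma2),
                 sigma2 = sigma2, n_elements = sd$n_elements,
                 n_unconnected = sd$n_elements - length(connected)),
            class = "affinity_graph")
}

#' Average-link agglomerative clustering on the affinity graph
#'
#' Iteratively merges the pair of clusters with the highest current
#' affinity and updates affinities to the remaining clusters by the
#' average-linkage criterion: the mean of the original edge affinities
#' between the two clusters, weighted by the number of stored edges. Edges
#' absent from the sparse graph (distance above the cutoff) contribute
#' nothing — they are not treated as zero affinity — so on a complete graph
#' the procedure is exactly size-weighted UPGMA. Ties go to the pair whose
#' clusters contain the smallest original element indices.
#'
#' @param g an [build_affinity_graph()] result.
#' @return An object of class `dendrogram_sparse`: a `merges` data frame
#'   (`node`, `left`, `right`, `affinity`; leaves are `1..n`, internal
#'   nodes `n + k` in merge order), `n_leaves`, and `roots` (one per
#'   connected component; unconnected elements stay singleton roots).
#' @export
average_link_dendrogram <- function(g) {
  stopifnot(inherits(g, "affinity_graph"))
  m <- cpp_average_link(g$n_elements, as.integer(g$i), as.integer(g$j),
                        as.numeric(g$a))
  merges <- data.frame(node = as.integer(m[, 1]), left = as.integer(m[, 2]),
                       right = as.integer(m[, 3]), affinity = m[, 4])
  children <- c(merges$left, merges$right)
  roots <- setdiff(c(seq_len(g$n_elements), merges$node), children)
  structure(list(merges = merges, n_leaves = g$n_elements,
                 roots = as.integer(roots)),
            class = "dendrogram_sparse")
}

#' @export
print.dendrogram_sparse <- function(x, ...) {
  cat(sprintf("<dendrogram> %d leaves, %d merges, %d roots\n",
              x$n_leaves, nrow(x$merges), length(x$roots)))
  invisible(x)
}

# Leaf descendants of every node, as a list indexed by node id.
node_leaves <- function(dg) {
  n <- dg$n_leaves
  out <- vector("list", n + nrow(dg$merges))
  for (l in seq_len(n)) out[[l]] <- l
  nd <- dg$merges$node; lf <- dg$merges$left; rt <- dg$merges$right
  for (r in seq_along(nd)) out[[nd[r]]] <- c(out[[lf[r]]], out[[rt[r]]])
  out
}

#' Adaptive partition of a dendrogram
#'
#' Walks each tree breadth-first from its root. A node whose descendant
#' fibers have maximum pairwise `d_me` at most `d_clmax` is emitted as one
#' cluster; otherwise its two children are enqueued. Leaves reached this
#' way become singleton clusters. The result is a partition of all leaves
#' into clusters whose diameter (in `d_me`) is bounded by `d_clmax`.
#'
#' @param dg an [average_link_dendrogram()] result.
#' @param fibers the fibers the dendrogram leaves index (common point
#'   count).
#' @param d_clmax maximum within-cluster pairwise distance in mm (default
#'   30; typical values for fiber data are 15-45 mm).
#' @return An object of class `fiber_partition`: `clusters` (list of leaf
#'   index vectors) and `d_clmax`.
#' @export
adaptive_partition <- function(dg, fibers, d_clmax = 30) {
  stopifnot(inherits(dg, "dendrogram_sparse"))
  if (length(fibers) != dg$n_leaves)
    stop("fibers must match the dendrogram leaves")
  pk <- pack_fibers(fibers)
  leaves <- node_leaves(dg)
  kids <- rbind(matrix(NA_integer_, dg$n_leaves, 2L),
                as.matrix(dg$merges[, c("left", "right")]))
  clusters <- list()
  queue <- dg$roots
  while (length(queue)) {
    nd <- queue[1L]; queue <- queue[-1L]
    lv <- leaves[[nd]]
    if (length(lv) == 1L) {
      clusters[[length(clusters) + 1L]] <- lv
      next
    }
    idx <- as.integer(t(outer((lv - 1L) * pk$np, seq_len(pk$np), "+")))
    sub <- pk$coords[rep((idx - 1L) * 3L, each = 3L) + rep(1:3, length(idx))]
    mx <- cpp_max_pairwise(sub, length(lv), pk$np, d_clmax)
    if (mx <= d_clmax) {
      clusters[[length(clusters) + 1L]] <- lv
    } else {
      queue <- c(queue, kids[nd, 1L], kids[nd, 2L])
    }
  }
  structure(list(clusters = clusters, d_clmax = d_clmax),
            class = "fiber_partition")
}

#' @export
print.fiber_partition <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat(sprintf("<partition> %d clusters over %d elements (d_clmax %.1f mm); sizes %s\n",
              length(sz), sum(sz), x$d_clmax,
              if (length(sz)) paste0(min(sz), "-", max(sz)) else "-"))
  invisible(x)
}

#' Keep clusters reproduced across enough subjects
#'
#' A cluster is representative of the population only if its fibers come
#' from at least `ceil(min_frac * n_subjects)` distinct subjects (75% by
#' default; for a 37-subject group the cutoff is 28 subjects). All other
#' clusters — including the inevitable singletons — are discarded.
#'
#' @param p a [adaptive_partition()] result.
#' @param subject_of character/factor vector mapping each leaf index to its
#'   subject.
#' @param n_subjects number of subjects in the group.
#' @param min_frac minimum fraction of subjects (default 0.75).
#' @return The filtered partition, with the subject count of each kept
#'   cluster in attribute `"subject_counts"`.
#' @export
reproducibility_filter <- function(p, subject_of, n_subjects,
                                   min_frac = 0.75) {
  stopifnot(inherits(p, "fiber_partition"))
  nleaf <- if (length(p$clusters)) max(unlist(p$clusters)) else 0L
  if (length(subject_of) < nleaf || anyNA(subject_of[seq_len(nleaf)]))
    stop("every leaf must be mapped to a subject")
  cutoff <- reproducibility_cutoff(n_subjects, min_frac)
  counts <- vapply(p$clusters,
                   function(cl) length(unique(subject_of[cl])), integer(1))
  keep <- counts >= cutoff
  p$clusters <- p$clusters[keep]
  attr(p, "subject_counts") <- counts[keep]
  p
}

#' Reproducibility cutoff in subjects
#'
#' Smallest integer at least `min_frac * n_subjects` (e.g. 28 for 37
#' subjects at 75%).
#'
#' @param n_subjects group size.
#' @param min_frac minimum fraction (default 0.75).
#' @return Integer subject cutoff.
#' @export
reproducibility_cutoff <- function(n_subjects, min_frac = 0.75) {
  as.integer(ceiling(min_frac * n_subjects - 1e-9))
}

#' Serialize a dendrogram to a merge-list text file
#' @param dg dendrogram; `path` file path.
#' @param path file path.
#' @return `path` invisibly; `read_dendrogram` returns the dendrogram.
#' @export
write_dendrogram <- function(dg, path) {
  header <- sprintf("# n_leaves %d", dg$n_leaves)
  writeLines(c(header, sprintf("%d %d %d %.17g", dg$merges$node,
                               dg$merges$left, dg$merges$right,
                               dg$merges$affinity)), path)
  invisible(path)
}

#' @rdname write_dendrogram
#' @export
read_dendrogram <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(lines[1L], " ")[[1L]][3L])
  body <- lines[-1L]
  if (length(body)) {
    m <- do.call(rbind, strsplit(body, " "))
    merges <- data.frame(node = as.integer(m[, 1]), left = as.integer(m[, 2]),
                         right = as.integer(m[, 3]),
                         affinity = as.numeric(m[, 4]))
  } else {
    merges <- data.frame(node = integer(), left = integer(),
                         right = integer(), affinity = numeric())
  }
  roots <- setdiff(c(seq_len(n), merges$node), c(merges$left, merges$right))
  structure(list(merges = merges, n_leaves = n, roots = as.integer(roots)),
            class = "dendrogram_sparse")
}
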