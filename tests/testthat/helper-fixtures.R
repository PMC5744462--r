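# Fixture builders and independent oracles used across the suite.
# All randomness is seeded by the calling test.

straight_fiber <- function(from, to, n = 51L) {
  tt <- seq(0, 1, length.out = n)
  outer(1 - tt, from) + outer(tt, to)
}

# smooth random fiber: random endpoints plus a bending arc
random_fiber <- function(n = 51L, scale = 40) {
  a <- stats::runif(3, -scale, scale)
  b <- a + stats::rnorm(3, sd = scale / 2)
  while (sqrt(sum((b - a)^2)) < 5) b <- a + stats::rnorm(3, sd = scale / 2)
  bend <- stats::rnorm(3, sd = scale / 6)
  tt <- seq(0, 1, length.out = n)
  outer(1 - tt, a) + outer(tt, b) + outer(4 * tt * (1 - tt), bend)
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# brute-force two-pass oracle for the symmetrized max corresponding-point
# distance, independent of the package's kernel
dme_oracle <- function(a, b) {
  n <- nrow(a)
  fwd <- 0; rev <- 0
  for (i in seq_len(n)) {
    fwd <- max(fwd, sqrt(sum((a[i, ] - b[i, ])^2)))
    rev <- max(rev, sqrt(sum((a[i, ] - b[n + 1 - i, ])^2)))
  }
  min(fwd, rev)
}

# dense average-link (UPGMA-style, weight = number of original edges)
# oracle on an affinity matrix with NA marking absent edges; replicates
# the documented tie-break (lowest slot pair, slots keep the smallest
# member index)
upgma_oracle <- function(A) {
  n <- nrow(A)
  W <- ifelse(is.na(A), 0, 1)
  A[is.na(A)] <- -1
  diag(A) <- -1; diag(W) <- 0
  active <- rep(TRUE, n)
  cid <- seq_len(n)
  merges <- NULL
  for (it in seq_len(n - 1)) {
    best <- -1; bi <- 0L; bj <- 0L
    for (i in seq_len(n - 1)) {
      if (!active[i]) next
      for (j in (i + 1):n) {
        if (active[j] && A[i, j] > best) { best <- A[i, j]; bi <- i; bj <- j }
      }
    }
    if (best < 0) break
    for (w in seq_len(n)) {
      if (!active[w] || w == bi || w == bj) next
      ws <- W[bi, w] + W[bj, w]
      if (ws > 0) {
        a <- (W[bi, w] * max(A[bi, w], 0) + W[bj, w] * max(A[bj, w], 0)) / ws
        A[bi, w] <- a; A[w, bi] <- a
        W[bi, w] <- ws; W[w, bi] <- ws
      }
    }
    active[bj] <- FALSE
    A[bi, bj] <- -1; A[bj, bi] <- -1
    node <- n + (if (is.null(merges)) 1L else nrow(merges) + 1L)
    merges <- rbind(merges, c(node, cid[bi], cid[bj], best))
    cid[bi] <- node
  }
  if (is.null(merges)) {
    merges <- matrix(numeric(0), 0L, 4L)
  }
  colnames(merges) <- c("node", "left", "right", "affinity")
  as.data.frame(merges)
}

# leaf sets per node recomputed from a merge table (test-side)
leaves_from_merges <- function(merges, n) {
  out <- vector("list", n + nrow(merges))
  for (l in seq_len(n)) out[[l]] <- l
  if (nrow(merges)) {
    for (r in seq_len(nrow(merges)))
      out[[merges$node[r]]] <- c(out[[merges$left[r]]],
                                 out[[merges$right[r]]])
  }
  out
}

# top-down partition oracle on a merge table: emit a node's leaves when
# its max pairwise distance is within d_clmax, else recurse
partition_oracle <- function(merges, n, fibers, d_clmax) {
  lv <- leaves_from_merges(merges, n)
  kids <- rbind(matrix(NA_integer_, n, 2),
                as.matrix(merges[, c("left", "right")]))
  maxpair <- function(idx) {
    if (length(idx) < 2) return(0)
    mx <- 0
    for (i in seq_along(idx)[-length(idx)])
      for (j in (i + 1):length(idx))
        mx <- max(mx, dme_oracle(fibers[[idx[i]]], fibers[[idx[j]]]))
    mx
  }
  out <- list()
  emit <- function(node) {
    idx <- lv[[node]]
    if (maxpair(idx) <= d_clmax) {
      out[[length(out) + 1L]] <<- sort(idx)
    } else {
      emit(kids[node, 1]); emit(kids[node, 2])
    }
  }
  roots <- setdiff(c(seq_len(n), merges$node), c(merges$left, merges$right))
  for (r in roots) emit(r)
  out
}

cluster_set <- function(clusters) {
  sort(vapply(clusters, function(cl) paste(sort(cl), collapse = ","),
              character(1)))
}

# a small multi-subject population around the packaged synthetic scene
make_study <- function(n_templates = 4L, n_subjects = 4L, presence = 1,
                       fibers_per_bundle = 10L, distractors = 10L,
                       jitter = 1, seed = 7L, hemisphere = "left") {
  scene <- synthetic_scene(n_templates, hemisphere = hemisphere)
  spec <- population_spec(scene$templates, n_subjects = n_subjects,
                          presence_prob = presence, jitter_sigma = jitter,
                          fibers_per_bundle = fibers_per_bundle,
                          distractors_per_subject = distractors,
                          hemisphere = hemisphere, seed = seed)
  pop <- make_population(spec)
  list(scene = scene, spec = spec, pop = pop)
}

# map each bundle of an atlas to its nearest template (index) by centroid
# distance, with the distance alongside
match_to_templates <- function(a, templates) {
  t(vapply(a$bundles, function(b) {
    cen <- bundle_centroid(b)
    d <- vapply(templates, function(tp) d_me(cen, tp$centroid), numeric(1))
    c(template = which.min(d), dist = min(d))
  }, numeric(2)))
}
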