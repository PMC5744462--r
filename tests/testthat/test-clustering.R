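graph_from_matrix <- function(A, sigma2 = 60) {
  # build an affinity_graph directly from an affinity matrix (NA = absent)
  idx <- which(upper.tri(A) & !is.na(A), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  structure(list(i = idx[, 1], j = idx[, 2], a = A[idx], sigma2 = sigma2,
                 n_elements = nrow(A),
                 n_unconnected = sum(!(seq_len(nrow(A)) %in% idx))),
            class = "affinity_graph")
}

test_that("affinities are exp(-d/sigma2) and unconnected elements counted", {
  a <- straight_fiber(c(0, 0, 0), c(0, 50, 0))
  b <- a; b[, 1] <- b[, 1] + 10
  c_far <- a; c_far[, 1] <- c_far[, 1] + 200
  s <- sparse_pairwise(list(a, b, c_far), d_max = 30)
  g <- build_affinity_graph(s, sigma2 = 60)
  expect_equal(g$a, exp(-10 / 60), tolerance = 1e-12)
  expect_equal(g$n_unconnected, 1L)
  expect_error(build_affinity_graph(s, sigma2 = 0), "positive")
  # monotone: affinity decreases with distance
  expect_true(exp(-20 / 60) < exp(-10 / 60))
  # zero distance maps to affinity 1
  s2 <- sparse_pairwise(list(a, a), d_max = 30)
  expect_equal(build_affinity_graph(s2)$a, 1)
})

test_that("a single edge merges once at its affinity", {
  A <- matrix(NA_real_, 2, 2); A[1, 2] <- 0.7
  dg <- average_link_dendrogram(graph_from_matrix(A))
  expect_equal(nrow(dg$merges), 1L)
  expect_equal(dg$merges$affinity, 0.7)
  expect_equal(sort(c(dg$merges$left, dg$merges$right)), 1:2)
  expect_equal(dg$roots, 3L)
})

test_that("three-element merge follows the average-linkage update", {
  A <- matrix(NA_real_, 3, 3)
  A[1, 2] <- 0.9; A[2, 3] <- 0.5; A[1, 3] <- 0.4
  dg <- average_link_dendrogram(graph_from_matrix(A))
  expect_equal(dg$merges$affinity, c(0.9, 0.45), tolerance = 1e-12)
  expect_equal(dg$merges$left[1], 1L)
  expect_equal(dg$merges$right[1], 2L)
  expect_equal(dg$merges$node, c(4L, 5L))
})

test_that("sparse implementation reproduces the dense average-link oracle", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    # complete graphs anchor the textbook UPGMA case
    D <- as.matrix(stats::dist(matrix(stats::runif(n * 2, 0, 50), n)))
    A <- exp(-D / 60); diag(A) <- NA
    dg <- average_link_dendrogram(graph_from_matrix(A))
    oracle <- upgma_oracle(A)
    expect_equal(nrow(dg$merges), n - 1L)
    expect_equal(dg$merges$left, as.integer(oracle$left))
    expect_equal(dg$merges$right, as.integer(oracle$right))
    expect_equal(dg$merges$affinity, oracle$affinity, tolerance = 1e-9)
  }
})

test_that("sparse graphs with missing edges still match the oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    D <- as.matrix(stats::dist(matrix(stats::runif(n * 2, 0, 60), n)))
    A <- exp(-D / 60)
    A[D > 35] <- NA                      # sparsify
    diag(A) <- NA
    dg <- average_link_dendrogram(graph_from_matrix(A))
    oracle <- upgma_oracle(A)
    expect_equal(nrow(dg$merges), nrow(oracle))
    if (nrow(oracle)) {
      expect_equal(dg$merges$left, as.integer(oracle$left))
      expect_equal(dg$merges$right, as.integer(oracle$right))
      expect_equal(dg$merges$affinity, oracle$affinity, tolerance = 1e-9)
    }
  }
})

test_that("merge affinities are non-increasing on connected graphs", {
  set.seed(43)
  for (rep in 1:10) {
    n <- 20
    D <- as.matrix(stats::dist(matrix(stats::runif(n * 2, 0, 30), n)))
    A <- exp(-D / 60); diag(A) <- NA
    dg <- average_link_dendrogram(graph_from_matrix(A))
    expect_true(all(diff(dg$merges$affinity) <= 1e-9))
  }
})

test_that("merge count is N minus the connected-component count", {
  a <- straight_fiber(c(0, 0, 0), c(0, 50, 0))
  fibers <- list(a, sweep(a, 2, c(3, 0, 0), "+"),
                 sweep(a, 2, c(6, 0, 0), "+"),
                 sweep(a, 2, c(500, 0, 0), "+"))
  g <- build_affinity_graph(sparse_pairwise(fibers, 30))
  dg <- average_link_dendrogram(g)
  expect_equal(g$n_unconnected, 1L)
  # one 3-element component plus one unconnected singleton: 2 merges,
  # one root per component
  expect_equal(nrow(dg$merges), 2L)
  expect_equal(length(dg$roots), 2L)
  expect_true(4L %in% dg$roots)           # the far element stays singleton
})

test_that("adaptive partition emits tight clusters and splits loose ones", {
  a <- straight_fiber(c(0, 0, 0), c(0, 50, 0))
  tight <- lapply(c(0, 2, 4, 6), function(dx) sweep(a, 2, c(dx, 0, 0), "+"))
  g <- build_affinity_graph(sparse_pairwise(tight, 30))
  p <- adaptive_partition(average_link_dendrogram(g), tight, 30)
  expect_length(p$clusters, 1L)
  expect_setequal(p$clusters[[1]], 1:4)

  # two well-separated blobs: exactly two clusters matching the blobs
  blob2 <- lapply(tight, function(f) sweep(f, 2, c(0, 0, 200), "+"))
  fibers <- c(tight, blob2)
  g2 <- build_affinity_graph(sparse_pairwise(fibers, 30))
  p2 <- adaptive_partition(average_link_dendrogram(g2), fibers, 30)
  expect_equal(cluster_set(p2$clusters), cluster_set(list(1:4, 5:8)))

  # all pairwise distances above d_clmax: all singletons
  spread <- lapply(c(0, 40, 80, 120), function(dx)
    sweep(a, 2, c(dx, 0, 0), "+"))
  g3 <- build_affinity_graph(sparse_pairwise(spread, 200))
  p3 <- adaptive_partition(average_link_dendrogram(g3), spread, 30)
  expect_equal(cluster_set(p3$clusters),
               cluster_set(list(1, 2, 3, 4)))
})

test_that("partition matches the top-down oracle and is sound and maximal", {
  set.seed(44)
  for (rep in 1:25) {
    n <- sample(6:20, 1)
    fibers <- replicate(n, random_fiber(15, scale = 25), simplify = FALSE)
    d_clmax <- stats::runif(1, 15, 45)
    g <- build_affinity_graph(sparse_pairwise(fibers, d_clmax))
    dg <- average_link_dendrogram(g)
    p <- adaptive_partition(dg, fibers, d_clmax)
    # equivalence with the independent top-down oracle
    expect_equal(cluster_set(p$clusters),
                 cluster_set(partition_oracle(dg$merges, n, fibers,
                                              d_clmax)))
    # soundness: every cluster diameter within the bound
    for (cl in p$clusters) {
      if (length(cl) > 1) {
        dmax <- max(vapply(utils::combn(cl, 2, simplify = FALSE),
                           function(pr) dme_oracle(fibers[[pr[1]]],
                                                   fibers[[pr[2]]]),
                           numeric(1)))
        expect_lte(dmax, d_clmax)
      }
    }
    # maximality: the parent of every emitted non-root node breaks the bound
    lv <- leaves_from_merges(dg$merges, n)
    keys <- vapply(lv, function(x) paste(sort(x), collapse = ","),
                   character(1))
    for (cl in p$clusters) {
      node <- which(keys == paste(sort(cl), collapse = ","))[1]
      if (node %in% dg$roots || length(cl) == 1) next
      parent <- dg$merges$node[dg$merges$left == node |
                                 dg$merges$right == node]
      pl <- lv[[parent]]
      dmax <- max(vapply(utils::combn(pl, 2, simplify = FALSE),
                         function(pr) dme_oracle(fibers[[pr[1]]],
                                                 fibers[[pr[2]]]),
                         numeric(1)))
      expect_gt(dmax, d_clmax)
    }
  }
})

test_that("reproducibility filter applies the ceiling cutoff", {
  expect_equal(reproducibility_cutoff(37, 0.75), 28L)
  expect_equal(reproducibility_cutoff(27, 0.75), 21L)
  expect_equal(reproducibility_cutoff(8, 0.75), 6L)
  expect_equal(reproducibility_cutoff(28, 0.75), 21L)

  p <- structure(list(clusters = list(1:28, 29:55, 56:57), d_clmax = 30),
                 class = "fiber_partition")
  subject_of <- c(sprintf("s%02d", 1:28),    # 28 distinct subjects
                  sprintf("s%02d", 1:27),    # 27 distinct subjects
                  c("s01", "s01"))           # single subject
  kept <- reproducibility_filter(p, subject_of, n_subjects = 37)
  expect_length(kept$clusters, 1L)
  expect_equal(kept$clusters[[1]], 1:28)
  expect_equal(attr(kept, "subject_counts"), 28L)
  expect_error(reproducibility_filter(p, subject_of[1:10], 37), "mapped")
})

test_that("dendrograms round-trip through the merge-list text format", {
  A <- matrix(NA_real_, 3, 3)
  A[1, 2] <- 0.9; A[2, 3] <- 0.5; A[1, 3] <- 0.4
  dg <- average_link_dendrogram(graph_from_matrix(A))
  path <- withr::local_tempfile(fileext = ".txt")
  write_dendrogram(dg, path)
  dg2 <- read_dendrogram(path)
  expect_equal(dg2$merges, dg$merges, tolerance = 1e-15)
  expect_equal(dg2$roots, dg$roots)
})
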