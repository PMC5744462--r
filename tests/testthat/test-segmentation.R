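simple_atlas <- function() {
  b1 <- bundle(lapply(0:2, function(i)
    straight_fiber(c(i, 0, 0), c(i, 50, 0))), rep("s1", 3), id = "b1")
  b2 <- bundle(lapply(0:2, function(i)
    straight_fiber(c(100 + i, 0, 0), c(100 + i, 70, 0))), rep("s1", 3),
    id = "b2")
  atlas(list(b1, b2))
}

test_that("per-bundle thresholds map length linearly onto 6-8 mm", {
  expect_equal(segmentation_threshold(35), 6)
  expect_equal(segmentation_threshold(85), 8)
  expect_equal(segmentation_threshold(60), 7)
  expect_equal(segmentation_threshold(c(10, 200)), c(6, 8))  # clamped
})

test_that("fibers are assigned to the closest bundle within threshold", {
  a <- simple_atlas()
  cen <- bundle_centroid(a$bundles[[1]])
  far <- straight_fiber(c(50, 0, 0), c(50, 50, 0))
  cs <- centroid_set(list(cen, far), subject_id = "t1")
  sr <- segment_subject(cs, a)
  expect_equal(sr$assignments$fiber, 1L)
  expect_equal(sr$assignments$bundle_id, "b1")
  expect_equal(sr$assignments$distance, 0, tolerance = 1e-9)
  expect_equal(sr$bundles$n_fibers, c(1L, 0L))
})

test_that("segmentation equals a brute-force arg-min oracle", {
  set.seed(71)
  a <- simple_atlas()
  cents <- lapply(a$bundles, bundle_centroid)
  thr <- vapply(a$bundles, function(b)
    segmentation_threshold(mean(vapply(b$fibers, fiber_length,
                                       numeric(1)))), numeric(1))
  fibers <- c(
    lapply(1:10, function(k) cents[[1]] +
             matrix(stats::rnorm(3, sd = 2), 51, 3, byrow = TRUE)),
    lapply(1:10, function(k) cents[[2]] +
             matrix(stats::rnorm(3, sd = 2), 51, 3, byrow = TRUE)),
    replicate(5, random_fiber(51) + 300, simplify = FALSE))
  sr <- segment_subject(centroid_set(fibers), a)
  for (k in seq_along(fibers)) {
    d <- vapply(seq_along(cents), function(j)
      dme_oracle(fibers[[k]], cents[[j]]) +
        dnf(fiber_length(fibers[[k]]), fiber_length(cents[[j]])),
      numeric(1))
    row <- sr$assignments[sr$assignments$fiber == k, ]
    if (min(d) <= thr[which.min(d)]) {
      expect_equal(row$bundle_idx, which.min(d))
      expect_equal(row$distance, min(d), tolerance = 1e-9)
      expect_lte(row$distance, sr$bundles$threshold[row$bundle_idx])
    } else {
      expect_equal(nrow(row), 0L)
    }
  }
})

test_that("the small-bundle rule drops below-10 counts only", {
  a <- simple_atlas()
  cen1 <- bundle_centroid(a$bundles[[1]])
  cen2 <- bundle_centroid(a$bundles[[2]])
  fibers <- c(rep(list(cen1), 9), rep(list(cen2), 10))
  sr <- segment_subject(centroid_set(fibers), a)
  out <- filter_small(sr)
  expect_equal(out$bundles$present, c(FALSE, TRUE))
  expect_true(all(out$assignments$bundle_idx == 2L))
  empty <- filter_small(segment_subject(centroid_set(list()), a))
  expect_equal(nrow(empty$assignments), 0L)
})

test_that("bundle volume counts voxels crossed by more than one fiber", {
  f <- straight_fiber(c(0.5, 0.5, 0.5), c(9.5, 0.5, 0.5), 51)
  expect_equal(bundle_volume(list(f)), 0L)           # single fiber
  expect_equal(bundle_volume(list(f, f)), 5L)        # [0,2),...,[8,10)
  g <- f; g[, 2] <- g[, 2] + 0.5
  expect_equal(bundle_volume(list(f, g)), 5L)
  # duplication beyond multiplicity 2 leaves the mask unchanged
  expect_equal(bundle_volume(rep(list(f, g), 4)), 5L)
  expect_equal(bundle_volume(rev(list(f, g))), 5L)   # order invariance
  expect_error(bundle_volume(list()), "nonempty")
})

test_that("lateralization index follows (R - L) / (R + L)", {
  expect_equal(lateralization_index(50, 50), 0)
  expect_equal(lateralization_index(0, 10), 1)
  expect_equal(lateralization_index(60, 40), -0.2)
  expect_true(is.na(lateralization_index(0, 0)))
})

test_that("volume t-test matches the pooled-variance formula", {
  expect_equal(volume_ttest(c(5, 5, 5), c(5, 5, 5))[c("t", "p")],
               list(t = 0, p = 1))
  set.seed(72)
  for (k in 1:10) {
    x <- stats::rnorm(8, 100, 10); y <- stats::rnorm(11, 95, 12)
    res <- volume_ttest(x, y)
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
      (n1 + n2 - 2)
    t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p_manual <- 2 * stats::pt(-abs(t_manual), n1 + n2 - 2)
    expect_equal(res$t, t_manual, tolerance = 1e-10)
    expect_equal(res$p, p_manual, tolerance = 1e-10)
    swapped <- volume_ttest(y, x)
    expect_equal(swapped$t, -res$t, tolerance = 1e-10)
    expect_equal(swapped$p, res$p, tolerance = 1e-12)
  }
})

test_that("laterality of a subject against its own mirror is zero", {
  set.seed(73)
  a <- simple_atlas()
  a$bundles <- lapply(a$bundles, function(b) {
    b$label <- paste0(b$id, "_0i"); b
  })
  cen <- bundle_centroid(a$bundles[[1]])
  fibers <- lapply(1:12, function(k)
    cen + matrix(stats::rnorm(3, sd = 1.5), 51, 3, byrow = TRUE))
  left_cs <- centroid_set(fibers, subject_id = "s1")
  # the mirrored subject, segmented against the mirrored atlas, yields
  # identical volumes by construction
  mirror_atlas <- swmclust:::reflect_atlas(a)
  right_cs <- centroid_set(reflect_hemisphere(fibers), subject_id = "s1",
                           hemisphere = "right")
  lr <- lapply(list(1, 2), function(i) segment_subject(left_cs, a))
  rr <- lapply(list(1, 2), function(i)
    segment_subject(right_cs, mirror_atlas))
  rep_tab <- laterality_report(lr, rr)
  seen <- rep_tab[rep_tab$mean_vol_left + rep_tab$mean_vol_right > 0, ]
  expect_gt(nrow(seen), 0L)
  expect_equal(seen$mean_li, rep(0, nrow(seen)))
  expect_equal(rep_tab$t, rep(0, nrow(rep_tab)))
  expect_equal(rep_tab$p, rep(1, nrow(rep_tab)))
  expect_false(any(rep_tab$significant))
})

test_that("per-point voxel counting is available as an option", {
  f <- straight_fiber(c(0.5, 0.5, 0.5), c(9.5, 0.5, 0.5), 51)
  # a single fiber has many points per voxel, so per-point counting
  # fills its whole traversal set
  expect_equal(bundle_volume(list(f), count = "points"), 5L)
  expect_equal(bundle_volume(list(f), count = "fibers"), 0L)
})

test_that("the LI-against-zero test mode behaves on symmetric data", {
  a <- simple_atlas()
  a$bundles <- lapply(a$bundles, function(b) {
    b$label <- paste0(b$id, "_0i"); b
  })
  cen <- bundle_centroid(a$bundles[[1]])
  set.seed(74)
  fibers <- lapply(1:12, function(k)
    cen + matrix(stats::rnorm(3, sd = 1.5), 51, 3, byrow = TRUE))
  left_cs <- centroid_set(fibers, subject_id = "s1")
  right_cs <- centroid_set(reflect_hemisphere(fibers), subject_id = "s1",
                           hemisphere = "right")
  lr <- lapply(1:2, function(i) segment_subject(left_cs, a))
  rr <- lapply(1:2, function(i)
    segment_subject(right_cs, swmclust:::reflect_atlas(a)))
  rep_li <- laterality_report(lr, rr, test = "li")
  seen <- rep_li[rep_li$mean_vol_left + rep_li$mean_vol_right > 0, ]
  expect_equal(seen$t, rep(0, nrow(seen)))
  expect_equal(seen$p, rep(1, nrow(seen)))
})
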