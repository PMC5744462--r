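mk_bundle <- function(fibers, id = "b", subjects = NULL, hemi = "left") {
  bundle(fibers, subjects %||% rep("s1", length(fibers)), id = id,
         hemisphere = hemi)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

shifted_copies <- function(base, k, dx) {
  lapply(seq_len(k) - 1, function(i)
    base + matrix(c(dx * i, 0, 0), nrow(base), 3, byrow = TRUE))
}

test_that("matching a copy of an atlas pairs every bundle perfectly", {
  set.seed(61)
  b1 <- mk_bundle(replicate(5, random_fiber(51, 15), simplify = FALSE), "x")
  b2 <- mk_bundle(lapply(b1$fibers, function(f) f + 150), "y")
  a1 <- atlas(list(b1, b2))
  m <- match_groups(a1, a1)
  expect_equal(nrow(m), 2L)
  expect_equal(m$frac1, c(1, 1))
  expect_equal(m$id1, m$id2)
})

test_that("distant atlases produce no matches", {
  set.seed(62)
  b1 <- mk_bundle(replicate(4, random_fiber(51, 10), simplify = FALSE))
  b2 <- mk_bundle(lapply(b1$fibers, function(f) f + 100), "far")
  expect_equal(nrow(match_groups(atlas(list(b1)), atlas(list(b2)))), 0L)
})

test_that("intersection matching respects the 50% boundary", {
  base <- straight_fiber(c(0, 0, 0), c(0, 50, 0))
  # ten parallel fibers 1 mm apart
  fa <- shifted_copies(base, 10, 1)
  # 60% overlap: 6 coincident fibers, 4 far
  fb60 <- c(fa[1:6], lapply(fa[7:10], function(f) f + 500))
  # 40% overlap
  fb40 <- c(fa[1:4], lapply(fa[5:10], function(f) f + 500))
  a1 <- atlas(list(mk_bundle(fa, "a")))
  expect_equal(nrow(match_groups(a1, atlas(list(mk_bundle(fb60, "m60"))))),
               1L)
  expect_equal(nrow(match_groups(a1, atlas(list(mk_bundle(fb40, "m40"))))),
               0L)
})

test_that("fusing bundles unions fibers and subjects", {
  set.seed(63)
  fb <- replicate(4, random_fiber(51), simplify = FALSE)
  x <- mk_bundle(fb, "x", subjects = c("s1", "s1", "s2", "s3"))
  y <- mk_bundle(fb, "y", subjects = c("s3", "s4", "s4", "s5"))
  fz <- fuse_bundles(x, y)
  expect_length(fz$fibers, 8L)
  expect_setequal(unique(fz$subjects), c("s1", "s2", "s3", "s4", "s5"))
  expect_equal(unname(intersection_fractions(fz, x))[2], 1)
})

test_that("bundle centroids align orientations before averaging", {
  set.seed(64)
  f <- random_fiber(51)
  expect_equal(bundle_centroid(mk_bundle(list(f))), f, tolerance = 1e-9)
  # identical fiber plus its reversal: centroid is the fiber itself
  expect_equal(bundle_centroid(mk_bundle(list(f, reverse_fiber(f)))), f,
               tolerance = 1e-9)
  # two parallel straight fibers offset (0,0,2): centroid halfway
  a <- straight_fiber(c(0, 0, 0), c(0, 50, 0))
  b <- a; b[, 3] <- b[, 3] + 2
  cen <- bundle_centroid(mk_bundle(list(a, b)))
  expect_equal(cen, a + matrix(c(0, 0, 1), 51, 3, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("bagging keeps bundles by repetition votes", {
  base <- straight_fiber(c(0, 0, 0), c(0, 60, 0))
  spots <- list(A = c(0, 0, 0), B = c(150, 0, 0), C = c(0, 0, 150))
  present_in <- list(A = 1:10, B = 1:8, C = 1:7)
  atlases <- lapply(1:10, function(r) {
    bundles <- list()
    for (nm in names(spots)) {
      if (r %in% present_in[[nm]]) {
        fibers <- lapply(1:3, function(k)
          base + matrix(spots[[nm]] + c(0, 0, 0.1 * k), 51, 3, byrow = TRUE))
        bundles <- c(bundles, list(mk_bundle(fibers, paste0(nm, r))))
      }
    }
    atlas(bundles, provenance = list(rep = r))
  })
  final <- bagging_aggregate(atlases, min_votes = 8)
  expect_length(final$bundles, 2L)
  votes <- sort(vapply(final$bundles, `[[`, integer(1), "votes"))
  expect_equal(votes, c(8L, 10L))
  expect_error(bagging_aggregate(atlases, min_votes = 11), "exceed")
})

test_that("bagging with one repetition and min_votes 1 is the identity", {
  set.seed(65)
  base <- straight_fiber(c(0, 0, 0), c(0, 60, 0))
  b1 <- mk_bundle(shifted_copies(base, 3, 1), "u")
  b2 <- mk_bundle(shifted_copies(base + 200, 3, 1), "v")
  a <- atlas(list(b1, b2))
  out <- bagging_aggregate(list(a), min_votes = 1)
  expect_length(out$bundles, 2L)
  expect_setequal(
    vapply(out$bundles, function(b) length(b$fibers), integer(1)),
    c(3L, 3L))
})

test_that("planted templates survive bagging, unique distractors do not", {
  set.seed(66)
  templates <- lapply(1:3, function(k)
    straight_fiber(c(60 * k, 0, 0), c(60 * k, 55, 0)))
  atlases <- lapply(1:10, function(r) {
    bundles <- lapply(seq_along(templates), function(k) {
      fibers <- lapply(1:4, function(j)
        templates[[k]] + matrix(stats::rnorm(3), 51, 3, byrow = TRUE))
      mk_bundle(fibers, sprintf("t%d_r%d", k, r))
    })
    # one unique distractor bundle per repetition, far from everything
    distract <- straight_fiber(c(0, 0, 300 + 40 * r),
                               c(0, 55, 300 + 40 * r))
    bundles <- c(bundles, list(mk_bundle(list(distract, distract + 0.5),
                                         sprintf("d_r%d", r))))
    atlas(bundles)
  })
  final <- bagging_aggregate(atlases, min_votes = 8)
  expect_length(final$bundles, 3L)
  expect_true(all(vapply(final$bundles, `[[`, integer(1), "votes") == 10L))
})

test_that("interhemispheric correspondence finds mirrored bundles", {
  set.seed(67)
  base <- straight_fiber(c(-40, 0, 0), c(-40, 50, 10))
  lb1 <- mk_bundle(shifted_copies(base, 5, 0.5), "L1")
  lb2 <- mk_bundle(shifted_copies(base + matrix(c(0, 0, 120), 51, 3,
                                                byrow = TRUE), 5, 0.5),
                   "L2")
  left <- atlas(list(lb1, lb2))
  # right atlas mirrors only the first bundle (plus jitter below 5 mm)
  rb1_f <- lapply(lb1$fibers, function(f) {
    f[, 1] <- -f[, 1]
    f + matrix(stats::runif(3, -1, 1), 51, 3, byrow = TRUE)
  })
  right <- atlas(list(mk_bundle(rb1_f, "R1", hemi = "right")))
  corr <- interhemispheric_match(left, right)
  expect_equal(nrow(corr), 1L)
  expect_equal(corr$id1, "L1")
  sym <- symmetrize_atlas(left, right, corr)
  # common pair contributes one bundle per hemisphere; L2 carried over
  expect_length(sym$bundles, 3L)
  hemis <- vapply(sym$bundles, `[[`, character(1), "hemisphere")
  expect_equal(sum(hemis == "left"), 2L)
  # the right symmetric bundle is the exact reflection of the left
  sl <- sym$bundles[[1]]; sr <- sym$bundles[[2]]
  back <- reflect_hemisphere(sr$fibers)
  expect_equal(back, sl$fibers, ignore_attr = TRUE)
  # reflection preserves the within-bundle distance structure
  for (k in 2:3)
    expect_equal(d_me(sl$fibers[[1]], sl$fibers[[k]]),
                 d_me(sr$fibers[[1]], sr$fibers[[k]]), tolerance = 1e-9)
})

test_that("match_groups is symmetric in its arguments", {
  set.seed(68)
  mk_atlas <- function(shift) {
    bs <- lapply(1:3, function(k) {
      base <- straight_fiber(c(50 * k, 0, 0), c(50 * k, 50, 0))
      mk_bundle(shifted_copies(base + shift, 4, 0.5), paste0("b", k))
    })
    atlas(bs)
  }
  a1 <- mk_atlas(0); a2 <- mk_atlas(1)
  m12 <- match_groups(a1, a2)
  m21 <- match_groups(a2, a1)
  expect_equal(m12$id1, m21$id2)
  expect_equal(m12$id2, m21$id1)
})

test_that("atlases round-trip through the on-disk directory layout", {
  set.seed(69)
  b1 <- mk_bundle(replicate(3, random_fiber(21), simplify = FALSE), "one")
  b1$votes <- 9L
  b2 <- mk_bundle(replicate(2, random_fiber(21), simplify = FALSE), "two")
  b2$label <- "SF_SF_0l"
  dir <- withr::local_tempdir()
  for (fmt in c("txt", "trk")) {
    write_atlas(atlas(list(b1, b2)), file.path(dir, fmt), format = fmt)
    a2 <- read_atlas(file.path(dir, fmt))
    expect_length(a2$bundles, 2L)
    expect_equal(a2$bundles[[1]]$votes, 9L)
    expect_equal(a2$bundles[[2]]$label, "SF_SF_0l")
    expect_equal(a2$bundles[[1]]$fibers[[1]], b1$fibers[[1]],
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})
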