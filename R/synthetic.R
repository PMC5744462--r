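#' Synthetic U-fiber template bundle
#'
#' Constructs a smooth arc between two endpoints — the idealized U-shape of
#' a short association fiber hugging the bottom of a sulcus — with a given
#' apex depth perpendicular to the chord, then rescales the bump so the
#' numeric arc length meets `length` within 2% (the requested length must
#' be at least the endpoint separation). `depth = 0` with `length` equal to
#' the separation gives the straight segment. The construction is fully
#' deterministic.
#'
#' @param endpoints 2 x 3 matrix of the two endpoints (mm), distinct.
#' @param depth initial apex depth in mm, applied toward the coordinate
#'   origin (into the white matter for endpoints on a cortical shell).
#' @param length target arc length in mm; defaults to the length of the
#'   arc with the given depth.
#' @param roi_pair optional integer pair: the parcellation labels the
#'   endpoints are designed to fall in.
#' @param n_points sampling of the returned centroid (default 51).
#' @return An object of class `template_bundle`: `centroid` (fiber
#'   matrix), `target_length`, `achieved_length`, `endpoints`, `roi_pair`.
#' @export
make_template <- function(endpoints, depth, length = NULL, roi_pair = NULL,
                          n_points = 51L) {
  endpoints <- matrix(as.numeric(endpoints), 2L, 3L)
  a <- endpoints[1L, ]; b <- endpoints[2L, ]
  chord <- sqrt(sum((b - a)^2))
  if (chord <= 0) stop("endpoints must be distinct")
  mid <- (a + b) / 2
  u <- -mid                                  # bow toward the origin
  u <- u - sum(u * (b - a)) / chord^2 * (b - a)
  if (sqrt(sum(u^2)) < 1e-8) {               # chord passes near the origin
    u <- c(-(b - a)[2L], (b - a)[1L], 0)
    if (sqrt(sum(u^2)) < 1e-8) u <- c(0, -(b - a)[3L], (b - a)[2L])
  }
  u <- u / sqrt(sum(u^2))
  arc <- function(d) {
    tt <- seq(0, 1, length.out = 201L)
    pts <- outer(1 - tt, a) + outer(tt, b) + outer(4 * tt * (1 - tt) * d, u)
    pts
  }
  if (is.null(length)) length <- fiber_length(arc(depth))
  if (length < chord * (1 - 1e-9))
    stop("requested length ", length, " mm is shorter than the ",
         sprintf("%.1f", chord), " mm endpoint separation")
  if (abs(length - chord) / length < 1e-9) {
    d_star <- 0                              # straight segment
  } else {
    obj <- function(d) fiber_length(arc(d)) - length
    hi <- max(depth, chord)
    while (obj(hi) < 0) hi <- hi * 2
    d_star <- stats::uniroot(obj, c(0, hi), tol = 1e-8)$root
  }
  centroid <- resample_fiber(arc(d_star), n_points)
  achieved <- fiber_length(centroid)
  if (abs(achieved - length) / length > 0.02)
    stop("could not construct an arc within 2% of the requested length")
  structure(list(centroid = centroid, target_length = length,
                 achieved_length = achieved, depth = d_star,
                 endpoints = endpoints, roi_pair = roi_pair),
            class = "template_bundle")
}

#' Population specification for the synthetic generator
#'
#' Defines the multi-subject synthetic tractogram: the template bundles,
#' the number of subjects, the probability each template is present in a
#' subject (bundles are genuinely missed in some subjects — partial volume
#' effects and tractography artifacts do that to real data), the jitter
#' scale, fibers per present bundle, and unstructured distractor fibers
#' per subject. All randomness derives from `seed` through per-(subject,
#' template) substreams.
#'
#' @param templates list of [make_template()] objects.
#' @param n_subjects number of subjects.
#' @param presence_prob per-template presence probability (recycled).
#' @param jitter_sigma mm scale of the per-fiber rigid offset; per-point
#'   noise is `jitter_sigma / 4`, smoothed along the arc, keeping
#'   `d_me(fiber, template)` within about `3 * jitter_sigma`.
#' @param fibers_per_bundle jittered copies per present bundle.
#' @param distractors_per_subject unstructured arcs per subject, each at
#'   least `distractor_min_dist` from every template.
#' @param distractor_min_dist minimum `d_me` from distractor to any
#'   template (default 20 mm).
#' @param shell_radius radius of the synthetic cortical shell used to
#'   place distractors (default 60 mm).
#' @param hemisphere,space metadata for the generated sets.
#' @param seed master seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(templates, n_subjects = 8L, presence_prob = 0.9,
                            jitter_sigma = 1, fibers_per_bundle = 20L,
                            distractors_per_subject = 50L,
                            distractor_min_dist = 20,
                            shell_radius = 60, hemisphere = "left",
                            space = "template", seed = 1L) {
  structure(list(templates = templates, n_subjects = as.integer(n_subjects),
                 presence_prob = rep_len(presence_prob, length(templates)),
                 jitter_sigma = jitter_sigma,
                 fibers_per_bundle = as.integer(fibers_per_bundle),
                 distractors_per_subject = as.integer(distractors_per_subject),
                 distractor_min_dist = distractor_min_dist,
                 shell_radius = shell_radius, hemisphere = hemisphere,
                 space = space, seed = as.integer(seed)),
            class = "population_spec")
}

# Smooth jitter: one rigid offset per fiber plus low-amplitude per-point
# noise smoothed along the arc, so within-bundle spread stays controlled.
jitter_fiber <- function(f, sigma) {
  n <- nrow(f)
  offset <- matrix(stats::rnorm(3L, sd = sigma), n, 3L, byrow = TRUE)
  noise <- matrix(stats::rnorm(3L * n, sd = sigma / 4), n, 3L)
  k <- stats::dnorm(-3:3); k <- k / sum(k)
  smooth <- apply(noise, 2L, function(col)
    stats::filter(c(rep(col[1L], 3L), col, rep(col[n], 3L)), k)[4:(n + 3L)])
  f + offset + smooth
}

random_arc <- function(shell_radius, hemisphere) {
  repeat {
    dir1 <- stats::rnorm(3L); dir1 <- dir1 / sqrt(sum(dir1^2))
    dir2 <- dir1 + stats::rnorm(3L, sd = 0.45)
    dir2 <- dir2 / sqrt(sum(dir2^2))
    sgn <- if (hemisphere == "left") -1 else 1
    dir1[1L] <- sgn * abs(dir1[1L]); dir2[1L] <- sgn * abs(dir2[1L])
    ep <- shell_radius * rbind(dir1, dir2)
    chord <- sqrt(sum((ep[1L, ] - ep[2L, ])^2))
    if (chord < 25 || chord > 60) next
    len <- chord * stats::runif(1L, 1.05, 1.3)
    if (len < 35 || len > 85) next
    tb <- try(make_template(ep, depth = 0.2 * chord, length = len),
              silent = TRUE)
    if (!inherits(tb, "try-error")) return(tb$centroid)
  }
}

#' Generate a synthetic multi-subject population
#'
#' For each subject and template, includes the bundle with its presence
#' probability; present bundles contribute `fibers_per_bundle` jittered
#' copies of the template centroid. Distractor arcs are drawn on the
#' cortical shell and rejected until they are at least
#' `distractor_min_dist` (in `d_me`) from every template, so no distractor
#' can be confused with a planted bundle. Identical seeds give identical
#' populations.
#'
#' @param spec a [population_spec()].
#' @return A list: `sets` (per-subject [centroid_set()]), and `truth`, a
#'   tibble with one row per fiber (`subject`, `fiber`, `source` =
#'   template index or `"distractor"`).
#' @export
make_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  np <- nrow(spec$templates[[1L]]$centroid)
  sets <- vector("list", spec$n_subjects)
  truth <- list()
  tpl_pack <- pack_fibers(lapply(spec$templates, `[[`, "centroid"))
  for (s in seq_len(spec$n_subjects)) {
    fibers <- list(); src <- character()
    for (tpl in seq_along(spec$templates)) {
      withr::with_seed(derive_seed(spec$seed, s, tpl), {
        if (stats::runif(1L) <= spec$presence_prob[tpl]) {
          for (k in seq_len(spec$fibers_per_bundle)) {
            fibers[[length(fibers) + 1L]] <-
              jitter_fiber(spec$templates[[tpl]]$centroid, spec$jitter_sigma)
            src <- c(src, as.character(tpl))
          }
        }
      })
    }
    withr::with_seed(derive_seed(spec$seed, s, 0L), {
      made <- 0L
      while (made < spec$distractors_per_subject) {
        arc <- random_arc(spec$shell_radius, spec$hemisphere)
        dmin <- min(cpp_cross_min(as.numeric(t(arc)), 1L, tpl_pack$coords,
                                  tpl_pack$n, np))
        if (dmin >= spec$distractor_min_dist) {
          fibers[[length(fibers) + 1L]] <- arc
          src <- c(src, "distractor")
          made <- made + 1L
        }
      }
    })
    sets[[s]] <- centroid_set(fibers, subject_id = sprintf("sub%02d", s),
                              hemisphere = spec$hemisphere,
                              space = spec$space)
    truth[[s]] <- tibble::tibble(subject = sprintf("sub%02d", s),
                                 fiber = seq_along(fibers), source = src)
  }
  list(sets = sets, truth = do.call(rbind, truth))
}

#' Synthetic box parcellation
#'
#' Builds a label volume from axis-aligned boxes in mm (one per ROI label),
#' on an isotropic grid. Boxes must not overlap; voxels outside every box
#' are background. Template endpoints are designed to fall inside their
#' ROI boxes so the labeling stage can be exercised end to end.
#'
#' @param roi_boxes named list: `label -> c(xmin, xmax, ymin, ymax, zmin,
#'   zmax)` in mm; names are integer labels.
#' @param shape voxel grid dimensions (default `c(80, 80, 80)`).
#' @param voxel_mm isotropic voxel size (default 2).
#' @param origin_mm world position of voxel (0,0,0)'s center.
#' @param label_table ROI table for the volume.
#' @return A [parcellation_volume()].
#' @export
make_parcellation <- function(roi_boxes, shape = c(80L, 80L, 80L),
                              voxel_mm = 2,
                              origin_mm = -voxel_mm * (shape - 1L) / 2,
                              label_table = desikan_table()) {
  boxes <- do.call(rbind, roi_boxes)
  if (nrow(boxes) > 1L) {
    for (i in seq_len(nrow(boxes) - 1L)) for (j in (i + 1L):nrow(boxes)) {
      overlap <- all(boxes[i, c(1, 3, 5)] < boxes[j, c(2, 4, 6)] &
                     boxes[j, c(1, 3, 5)] < boxes[i, c(2, 4, 6)])
      if (overlap) stop("ROI boxes ", names(roi_boxes)[i], " and ",
                        names(roi_boxes)[j], " overlap")
    }
  }
  labels <- array(0L, dim = shape)
  affine <- diag(c(rep(voxel_mm, 3L), 1))
  affine[1:3, 4L] <- origin_mm
  ax <- origin_mm[1L] + voxel_mm * (seq_len(shape[1L]) - 1L)
  ay <- origin_mm[2L] + voxel_mm * (seq_len(shape[2L]) - 1L)
  az <- origin_mm[3L] + voxel_mm * (seq_len(shape[3L]) - 1L)
  for (k in seq_along(roi_boxes)) {
    b <- roi_boxes[[k]]
    ix <- which(ax >= b[1L] & ax <= b[2L])
    iy <- which(ay >= b[3L] & ay <= b[4L])
    iz <- which(az >= b[5L] & az <= b[6L])
    labels[ix, iy, iz] <- as.integer(names(roi_boxes)[k])
  }
  parcellation_volume(labels, affine, label_table)
}

#' A ready-made synthetic study scene
#'
#' Places `n_templates` U-fiber templates around a hemisphere cortical
#' shell at evenly spaced azimuths, assigns each endpoint its own ROI box
#' (labels 1, 2, 3, ... in template order), and builds the matching box
#' parcellation. This is the scene the package's end-to-end tests and
#' examples run on; it is synthetic and shares only the geometry scale of
#' real data.
#'
#' @param n_templates number of templates (default 10, max 17).
#' @param shell_radius cortical shell radius in mm (default 60).
#' @param hemisphere `"left"` or `"right"`.
#' @param box_mm ROI box edge length (default 14).
#' @return A list: `templates` (list of [make_template()]), `parcellation`
#'   (a [parcellation_volume()]), and `roi_boxes`.
#' @export
synthetic_scene <- function(n_templates = 10L, shell_radius = 60,
                            hemisphere = "left", box_mm = 14) {
  if (n_templates > 17L) stop("at most 17 templates fit the label table")
  sgn <- if (hemisphere == "left") -1 else 1
  shell_point <- function(polar_deg, azim_deg) {
    po <- polar_deg * pi / 180; az <- azim_deg * pi / 180
    shell_radius * c(sgn * cos(po),
                     sin(po) * cos(az), sin(po) * sin(az))
  }
  templates <- vector("list", n_templates)
  roi_boxes <- list()
  for (k in seq_len(n_templates)) {
    az <- 360 * (k - 1L) / n_templates
    e1 <- shell_point(50, az)
    e2 <- shell_point(85, az)
    chord <- sqrt(sum((e1 - e2)^2))
    labs <- c(2L * k - 1L, 2L * k)
    templates[[k]] <- make_template(rbind(e1, e2), depth = 0.25 * chord,
                                    length = 1.25 * chord, roi_pair = labs)
    for (i in 1:2) {
      e <- rbind(e1, e2)[i, ]
      roi_boxes[[as.character(labs[i])]] <-
        c(e[1L] - box_mm / 2, e[1L] + box_mm / 2,
          e[2L] - box_mm / 2, e[2L] + box_mm / 2,
          e[3L] - box_mm / 2, e[3L] + box_mm / 2)
    }
  }
  list(templates = templates,
       parcellation = make_parcellation(roi_boxes),
       roi_boxes = roi_boxes)
}
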