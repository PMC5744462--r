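#' Pipeline configuration
#'
#' All tunable parameters of the bundle-identification pipeline in one
#' validated object, with the method's standard values as defaults: length
#' window 35-85 mm, DWM discard threshold 10 mm with a 20% reference
#' sample, affinity scale 60 mm, cluster diameter bound 30 mm, 75% subject
#' reproducibility, 5 mm / 50% intersection matching, 10 bagging
#' repetitions of two 27-subject groups with an 8-vote cutoff, 50% strong
#' connection labeling, 6-8 mm segmentation thresholds, 2 mm volume
#' voxels, and a 10-fiber minimum bundle size. Nothing is hard-coded
#' elsewhere; every stage reads its parameters from here.
#'
#' @param ... overrides of the defaults listed above (see
#'   `pipeline_defaults()`).
#' @return An object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(...) {
  cfg <- utils::modifyList(pipeline_defaults(), list(...))
  unknown <- setdiff(names(cfg), names(pipeline_defaults()))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  with(cfg, {
    if (sigma2 <= 0) stop("sigma2 must be positive")
    if (d_clmax <= 0) stop("d_clmax must be positive")
    if (min_length < 0 || max_length <= min_length)
      stop("invalid length window")
    if (min_subject_frac <= 0 || min_subject_frac > 1)
      stop("min_subject_frac must be in (0, 1]")
    if (dwm_sample_fraction <= 0 || dwm_sample_fraction > 1)
      stop("dwm_sample_fraction must be in (0, 1]")
    if (min_votes > bagging_reps)
      stop("min_votes cannot exceed bagging_reps")
    if (threshold_min > threshold_max) stop("invalid segmentation thresholds")
  })
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
pipeline_defaults <- function() {
  list(min_length = 35, max_length = 85,
       dwm_threshold = 10, dwm_sample_fraction = 0.2,
       sigma2 = 60, d_clmax = 30, min_subject_frac = 0.75,
       d_fiber = 5, min_match_frac = 0.5,
       bagging_reps = 10L, group_size = 27L, min_votes = 8L,
       min_fiber_frac = 0.5,
       threshold_min = 6, threshold_max = 8,
       voxel_mm = 2, min_fibers = 10L,
       n_points = 51L, seed = 1L)
}

#' Read or write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return `read_config` returns a [pipeline_config()].
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg a [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the atlas-construction pipeline
#'
#' Orchestrates selection, two-group intersubject clustering, intergroup
#' matching and fusion, and (when a parcellation is supplied) anatomical
#' labeling, writing the atlas and a run manifest to `out_dir`. The
#' manifest records per-stage element counts (centroids in/out of each
#' filter, sparse edges, clusters, reproducible clusters, matched and
#' labeled bundles), so a run is auditable; identical inputs, config and
#' seed give identical manifests.
#'
#' @param sets list of per-subject [centroid_set()] objects (already in a
#'   common space), or a directory of per-subject streamline files.
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory.
#' @param dwm optional [dwm_reference()] for the DWM filter.
#' @param parcellation optional [parcellation_volume()] (or named list per
#'   subject) enabling the labeling stage.
#' @param groups optional integer vector of 1/2 assigning subjects to the
#'   two groups; defaults to a seeded random split in half.
#' @param format streamline format for the written atlas (default
#'   `"txt"`).
#' @return The final [atlas()], invisibly; artifacts under `out_dir`.
#' @export
run_pipeline <- function(sets, cfg = pipeline_config(), out_dir,
                         dwm = NULL, parcellation = NULL, groups = NULL,
                         format = "txt") {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.character(sets) && length(sets) == 1L) {
    paths <- sort(list.files(sets, "\\.(trk|tck|txt)$", full.names = TRUE))
    sets <- lapply(seq_along(paths), function(k)
      read_tractogram(paths[k],
                      subject_id = tools::file_path_sans_ext(
                        basename(paths[k]))))
  }
  counts <- list(subjects = length(sets),
                 centroids_in = sum(lengths(lapply(sets, `[[`, "fibers"))))
  # selection: length window, resampling, DWM removal
  sets <- lapply(sets, length_filter, min_mm = cfg$min_length,
                 max_mm = cfg$max_length)
  counts$after_length_filter <- sum(lengths(lapply(sets, `[[`, "fibers")))
  sets <- lapply(sets, resample_set, n = cfg$n_points)
  if (!is.null(dwm)) {
    sets <- lapply(sets, dwm_filter, ref = dwm,
                   threshold_mm = cfg$dwm_threshold)
  }
  counts$after_dwm_filter <- sum(lengths(lapply(sets, `[[`, "fibers")))
  # two-group split
  if (is.null(groups)) {
    groups <- withr::with_seed(derive_seed(cfg$seed, 1L), {
      sample(rep_len(1:2, length(sets)))
    })
  }
  a <- robust_atlas(sets[groups == 1L], sets[groups == 2L],
                    d_clmax = cfg$d_clmax, sigma2 = cfg$sigma2,
                    min_subject_frac = cfg$min_subject_frac,
                    d_fiber = cfg$d_fiber,
                    min_match_frac = cfg$min_match_frac)
  grp <- attr(a, "groups")
  counts$group1 <- as.list(attr(grp[[1L]], "counts"))
  counts$group2 <- as.list(attr(grp[[2L]], "counts"))
  counts$matched_bundles <- length(a$bundles)
  if (!is.null(parcellation)) {
    a <- label_atlas(a, parcellation, min_fiber_frac = cfg$min_fiber_frac)
    counts$labeled_bundles <- length(a$bundles)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_atlas(a, file.path(out_dir, "atlas"), format = format)
  manifest <- list(config = unclass(cfg), counts = counts,
                   bundles = vapply(a$bundles, function(b)
                     b$label %||% b$id, character(1)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(a)
}
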