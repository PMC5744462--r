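#' Cortical parcellation volume
#'
#' An integer label image over gyral ROIs (Desikan-Killiany by default)
#' with its voxel-to-mm affine and a label table. Label 0 is background;
#' every non-zero label present in the image must appear in the table.
#' Voxel indices never leave this container — lookups take world-mm points.
#'
#' @param labels 3-D integer array.
#' @param voxel_to_mm 4x4 affine mapping 0-based voxel indices to mm.
#' @param label_table data frame with columns `label`, `abbrev` (and
#'   optionally `name`).
#' @return An object of class `parcellation_volume`.
#' @export
parcellation_volume <- function(labels, voxel_to_mm = diag(4),
                                label_table = desikan_table()) {
  labels <- array(as.integer(labels), dim = dim(labels))
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, label_table$label)
  if (length(missing))
    stop("labels absent from the label table: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, voxel_to_mm = unname(as.matrix(voxel_to_mm)),
                 label_table = label_table),
            class = "parcellation_volume")
}

#' @export
print.parcellation_volume <- function(x, ...) {
  cat(sprintf("<parcellation> %s voxels, %d ROIs present\n",
              paste(dim(x$labels), collapse = "x"),
              length(setdiff(unique(as.integer(x$labels)), 0L))))
  invisible(x)
}

#' The Desikan-Killiany gyral ROI table
#'
#' The 34 cortical parcels per hemisphere plus the corpus callosum, with
#' the abbreviations used in bundle names (e.g. `SF` superior frontal,
#' `Op` pars opercularis).
#'
#' @return A tibble with columns `label`, `abbrev`, `name`.
#' @export
desikan_table <- function() {
  path <- system.file("extdata", "desikan_killiany.tsv", package = "swmclust",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

# Label at world-mm points (nearest voxel); 0 outside the volume.
lookup_labels <- function(pv, pts) {
  vox <- round(t(solve(pv$voxel_to_mm) %*% rbind(t(pts), 1))[, 1:3,
                                                             drop = FALSE])
  dm <- dim(pv$labels)
  inside <- vox[, 1] >= 0 & vox[, 1] < dm[1] &
            vox[, 2] >= 0 & vox[, 2] < dm[2] &
            vox[, 3] >= 0 & vox[, 3] < dm[3]
  out <- integer(nrow(pts))
  if (any(inside))
    out[inside] <- pv$labels[vox[inside, , drop = FALSE] + 1L]
  out
}

#' ROI pair connected by a fiber
#'
#' Oversamples the fiber (so an extremity point falls inside the cortical
#' ribbon even where the tracked endpoint stops just short of it), then
#' scans each extremity inward over the first `probe_depth` oversampled
#' points for the first non-zero parcellation label. Returns the sorted
#' label pair, or `NULL` when either extremity finds no label
#' (undetermined — not an error; fibers outside the volume are simply
#' undetermined). The pair is unordered, so the result is invariant to
#' fiber reversal.
#'
#' @param f fiber matrix in the parcellation's space.
#' @param pv a [parcellation_volume()].
#' @param oversample_factor point-count multiplier before probing (default
#'   10).
#' @param probe_depth how many oversampled points inward to scan per
#'   extremity (default 3).
#' @return Sorted integer pair `c(roi1, roi2)` (possibly equal, for
#'   intra-gyral connections), or `NULL`.
#' @export
endpoint_rois <- function(f, pv, oversample_factor = 10L, probe_depth = 3L) {
  f <- oversample_fiber(as_fiber_matrix(f), oversample_factor)
  n <- nrow(f)
  probe <- function(idx) {
    labs <- lookup_labels(pv, f[idx, , drop = FALSE])
    hit <- labs[labs != 0L]
    if (length(hit)) hit[1L] else NA_integer_
  }
  a <- probe(seq_len(min(probe_depth, n)))
  b <- probe(rev(n + 1L - seq_len(min(probe_depth, n))))
  if (is.na(a) || is.na(b)) return(NULL)
  sort(c(a, b))
}

#' Main cortical connection of a bundle
#'
#' Runs [endpoint_rois()] for every fiber against its subject's
#' parcellation and tallies, per unordered ROI pair, the fiber fraction
#' (over the fibers with a determined pair) and the number of subjects
#' showing the connection. The dominant pair becomes the bundle's label
#' when its fiber fraction reaches `min_fiber_frac` (default 0.5);
#' otherwise the bundle has no strong connection and is left unlabeled
#' (and is dropped from a labeled atlas).
#'
#' @param b a [bundle()].
#' @param parcellations either a single [parcellation_volume()] (shared
#'   space) or a named list keyed by subject id.
#' @param min_fiber_frac minimum fiber fraction for a strong connection.
#' @param strict count undetermined fibers against the fraction (in the
#'   denominator) instead of excluding them (default `FALSE`).
#' @param oversample_factor,probe_depth passed to [endpoint_rois()].
#' @return A list with `pair` (or `NULL`), `fraction`, `subject_count`,
#'   and the full `tally` tibble (columns `roi1`, `roi2`, `fiber_count`,
#'   `fiber_fraction`, `subject_count`).
#' @export
main_connection <- function(b, parcellations, min_fiber_frac = 0.5,
                            strict = FALSE,
                            oversample_factor = 10L, probe_depth = 3L) {
  get_pv <- function(subj) {
    if (inherits(parcellations, "parcellation_volume")) return(parcellations)
    pv <- parcellations[[subj]]
    if (is.null(pv)) stop("no parcellation for subject ", subj)
    pv
  }
  pairs <- vector("list", length(b$fibers))
  for (k in seq_along(b$fibers)) {
    # [k] <- list(...): an undetermined (NULL) result must keep its slot
    pairs[k] <- list(endpoint_rois(b$fibers[[k]], get_pv(b$subjects[k]),
                                   oversample_factor, probe_depth))
  }
  det <- !vapply(pairs, is.null, logical(1))
  empty <- tibble::tibble(roi1 = integer(), roi2 = integer(),
                          fiber_count = integer(), fiber_fraction = numeric(),
                          subject_count = integer())
  if (!any(det))
    return(list(pair = NULL, fraction = 0, subject_count = 0L,
                tally = empty))
  key <- vapply(pairs[det], function(p) paste(p, collapse = "_"),
                character(1))
  subj <- b$subjects[det]
  denom <- if (strict) length(pairs) else sum(det)
  agg <- tapply(seq_along(key), key, identity)
  tally <- do.call(rbind, lapply(names(agg), function(k) {
    idx <- agg[[k]]
    p <- as.integer(strsplit(k, "_")[[1L]])
    tibble::tibble(roi1 = p[1L], roi2 = p[2L],
                   fiber_count = length(idx),
                   fiber_fraction = length(idx) / denom,
                   subject_count = length(unique(subj[idx])))
  }))
  tally <- tally[order(-tally$fiber_count, tally$roi1, tally$roi2), ]
  best <- tally[1L, ]
  if (best$fiber_fraction >= min_fiber_frac) {
    list(pair = c(best$roi1, best$roi2), fraction = best$fiber_fraction,
         subject_count = best$subject_count, tally = tally)
  } else {
    list(pair = NULL, fraction = best$fiber_fraction,
         subject_count = best$subject_count, tally = tally)
  }
}

#' Generate bundle names from connections
#'
#' Builds names of the form `<ABB1>_<ABB2>_<n><x>`: the abbreviations of
#' the connected ROI pair (in sorted label order), a per-pair index `n`
#' starting at 0 (assigned in decreasing bundle size, so indices are
#' deterministic and only disambiguate), and a suffix `x`: `i` for bundles
#' present in both hemispheres, `l` / `r` for single-hemisphere bundles.
#'
#' @param connections list with one entry per bundle: a list holding
#'   `pair` (sorted integer ROI pair), `presence` (`"i"`, `"l"` or `"r"`),
#'   and `size` (fiber count, for index ordering).
#' @param label_table ROI table (default [desikan_table()]).
#' @return Character vector of names, parallel to `connections`; injective
#'   over its input.
#' @export
name_bundles <- function(connections, label_table = desikan_table()) {
  abb <- function(l) {
    i <- match(l, label_table$label)
    if (anyNA(i)) stop("unknown ROI label: ", paste(l[is.na(i)], collapse = ","))
    label_table$abbrev[i]
  }
  pair_key <- vapply(connections, function(cn)
    paste(sort(cn$pair), collapse = "_"), character(1))
  sizes <- vapply(connections, function(cn) cn$size %||% 0, numeric(1))
  idx <- integer(length(connections))
  for (k in unique(pair_key)) {
    members <- which(pair_key == k)
    ord <- members[order(-sizes[members], members)]
    idx[ord] <- seq_along(ord) - 1L
  }
  vapply(seq_along(connections), function(r) {
    cn <- connections[[r]]
    p <- sort(cn$pair)
    sprintf("%s_%s_%d%s", abb(p[1L]), abb(p[2L]), idx[r], cn$presence)
  }, character(1))
}

#' Label an atlas's bundles anatomically
#'
#' Applies [main_connection()] to every bundle, drops bundles without a
#' strong connection, and names the survivors with [name_bundles()].
#' Connections touching the corpus callosum label are kept but flagged in
#' the bundle provenance, since callosal-like fibers are normally removed
#' upstream by the DWM filter.
#'
#' @param a an [atlas()].
#' @param parcellations as in [main_connection()].
#' @param min_fiber_frac strong-connection cutoff (default 0.5).
#' @param presence suffix for all bundles (`"l"`, `"r"` or `"i"`), or a
#'   vector per bundle; defaults from each bundle's hemisphere.
#' @param label_table ROI table.
#' @param oversample_factor,probe_depth passed to [endpoint_rois()].
#' @return The labeled [atlas()] (unlabeled bundles removed), with the
#'   per-bundle connection info in each bundle's `provenance$connection`.
#' @export
label_atlas <- function(a, parcellations, min_fiber_frac = 0.5,
                        presence = NULL, label_table = desikan_table(),
                        oversample_factor = 10L, probe_depth = 3L) {
  cc_label <- label_table$label[label_table$abbrev == "CC"]
  cons <- lapply(a$bundles, main_connection, parcellations = parcellations,
                 min_fiber_frac = min_fiber_frac,
                 oversample_factor = oversample_factor,
                 probe_depth = probe_depth)
  keep <- which(!vapply(cons, function(cn) is.null(cn$pair), logical(1)))
  if (is.null(presence))
    presence <- vapply(a$bundles, function(b)
      substr(b$hemisphere, 1L, 1L), character(1))
  presence <- rep_len(presence, length(a$bundles))
  entries <- lapply(keep, function(k) list(
    pair = cons[[k]]$pair, presence = presence[k],
    size = length(a$bundles[[k]]$fibers)))
  nm <- if (length(entries)) name_bundles(entries, label_table) else character()
  bundles <- lapply(seq_along(keep), function(r) {
    b <- a$bundles[[keep[r]]]
    b$label <- nm[r]
    b$provenance$connection <- cons[[keep[r]]][c("pair", "fraction",
                                                 "subject_count")]
    if (length(cc_label) && cc_label %in% cons[[keep[r]]]$pair)
      b$provenance$touches_corpus_callosum <- TRUE
    b
  })
  atlas(bundles, space = a$space, provenance = a$provenance)
}
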