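#' Bundles and atlases
#'
#' A `bundle` is a multi-subject cluster of centroid fibers; an `atlas` is
#' a set of bundles in a common space, each optionally carrying a
#' connection label and a bagging vote count.
#'
#' @param fibers list of fiber matrices (common point count), nonempty.
#' @param subjects character vector parallel to `fibers` giving the subject
#'   each fiber came from.
#' @param id bundle identifier.
#' @param hemisphere `"left"` or `"right"`.
#' @param label optional connection name (e.g. `"Op_SF_0i"`).
#' @param votes bagging vote count (`NA` before aggregation).
#' @param provenance free-form list (source group / repetition ids).
#' @return An object of class `bundle`.
#' @export
bundle <- function(fibers, subjects, id = "b1", hemisphere = "left",
                   label = NULL, votes = NA_integer_, provenance = list()) {
  fibers <- lapply(fibers, as_fiber_matrix)
  if (!length(fibers)) stop("a bundle must contain at least one fiber")
  subjects <- as.character(subjects)
  if (length(subjects) != length(fibers))
    stop("subjects must be parallel to fibers")
  structure(list(id = as.character(id), fibers = fibers, subjects = subjects,
                 hemisphere = hemisphere, label = label,
                 votes = as.integer(votes), provenance = provenance),
            class = "bundle")
}

#' @export
print.bundle <- function(x, ...) {
  cat(sprintf("<bundle %s>%s %d fibers, %d subjects, %s hemisphere%s\n",
              x$id, if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              length(x$fibers), length(unique(x$subjects)), x$hemisphere,
              if (is.na(x$votes)) "" else sprintf(", votes %d", x$votes)))
  invisible(x)
}

#' @rdname bundle
#' @param bundles list of `bundle` objects with unique ids.
#' @param space space tag.
#' @export
atlas <- function(bundles, space = "template", provenance = list()) {
  ids <- vapply(bundles, function(b) b$id, character(1))
  if (anyDuplicated(ids)) stop("bundle ids must be unique")
  structure(list(bundles = bundles, space = space, provenance = provenance),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("<atlas> %d bundles in %s space\n", length(x$bundles), x$space))
  invisible(x)
}

#' @export
length.atlas <- function(x) length(x$bundles)

#' Representative centroid fiber of a bundle
#'
#' Orients every fiber to the bundle's first fiber (reversing it when the
#' reversed orientation matches better) and takes the pointwise mean,
#' which inherits the bundle's common point count. Reversal alignment
#' makes the mean well-defined under the orientation ambiguity of
#' streamlines; a single-fiber bundle is its own centroid.
#'
#' @param b a [bundle()] or list of fiber matrices.
#' @return A single fiber matrix.
#' @export
bundle_centroid <- function(b) {
  fibers <- bundle_fibers(b)
  if (!length(fibers)) stop("bundle must be nonempty")
  # the aligned pointwise mean already carries the common point count;
  # re-parameterizing would perturb a single-fiber bundle's own centroid
  pointwise_centroid(fibers)
}

pointwise_centroid <- function(fibers) {
  ref <- fibers[[1L]]
  aligned <- lapply(fibers, function(f) {
    fwd <- max(rowSums((f - ref)^2))
    rev <- max(rowSums((reverse_fiber(f) - ref)^2))
    if (rev < fwd) reverse_fiber(f) else f
  })
  Reduce(`+`, aligned) / length(aligned)
}

#' Match bundles across two independently built atlases
#'
#' Computes [intersection_fractions()] for every cross pair and declares a
#' pair similar when both fractions exceed `min_frac` (strict `>`; default
#' 0.5). Multi-way overlaps are resolved greedily: pairs are taken in
#' decreasing order of mean intersection fraction, each bundle appearing in
#' at most one pair.
#'
#' @param a1,a2 [atlas()] objects in the same space and hemisphere.
#' @param d_fiber fiber closeness threshold in mm (default 5).
#' @param min_frac intersection fraction both sides must exceed (default
#'   0.5).
#' @return A tibble with columns `i1`, `i2` (bundle indices), `id1`, `id2`,
#'   `frac1`, `frac2`.
#' @export
match_groups <- function(a1, a2, d_fiber = 5, min_frac = 0.5) {
  cand <- list()
  for (i in seq_along(a1$bundles)) {
    for (j in seq_along(a2$bundles)) {
      fr <- intersection_fractions(a1$bundles[[i]], a2$bundles[[j]], d_fiber)
      if (fr[1L] > min_frac && fr[2L] > min_frac)
        cand[[length(cand) + 1L]] <-
          c(i = i, j = j, f1 = unname(fr[1L]), f2 = unname(fr[2L]))
    }
  }
  out <- tibble::tibble(i1 = integer(), i2 = integer(),
                        id1 = character(), id2 = character(),
                        frac1 = numeric(), frac2 = numeric())
  if (!length(cand)) return(out)
  cand <- do.call(rbind, cand)
  ord <- order(-(cand[, "f1"] + cand[, "f2"]) / 2, cand[, "i"], cand[, "j"])
  cand <- cand[ord, , drop = FALSE]
  used1 <- logical(length(a1$bundles)); used2 <- logical(length(a2$bundles))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, "i"]; j <- cand[r, "j"]
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    out <- rbind(out, tibble::tibble(
      i1 = as.integer(i), i2 = as.integer(j),
      id1 = a1$bundles[[i]]$id, id2 = a2$bundles[[j]]$id,
      frac1 = unname(cand[r, "f1"]), frac2 = unname(cand[r, "f2"])))
  }
  out
}

#' Fuse two matched bundles
#'
#' Takes the fiber multiset union of a matched pair, preserving subject
#' attribution and recording both sources in the provenance. Near-duplicate
#' bundles from the two groups are fused rather than kept apart — fine
#' granularity is not desirable for short association bundles given the
#' intersubject variability.
#'
#' @param x,y matched [bundle()] objects.
#' @param id id of the fused bundle.
#' @return The fused `bundle`.
#' @export
fuse_bundles <- function(x, y, id = paste0(x$id, "+", y$id)) {
  bundle(c(x$fibers, y$fibers), c(x$subjects, y$subjects), id = id,
         hemisphere = x$hemisphere,
         provenance = list(sources = list(x$provenance, y$provenance),
                           fused_from = c(x$id, y$id)))
}

#' Interhemispheric bundle correspondence
#'
#' Reflects the right-hemisphere atlas across the midsagittal plane and
#' matches it against the left-hemisphere atlas with [match_groups()].
#' Matched pairs are the bundles common to both hemispheres (suffix `"i"`
#' in the naming scheme); unmatched bundles keep their hemisphere-only
#' suffix (`"l"` / `"r"`).
#'
#' @param left,right [atlas()] objects in a mid-sagittally aligned space.
#' @param d_fiber,min_frac as in [match_groups()].
#' @param plane_x midsagittal plane (default x = 0).
#' @return A tibble as from [match_groups()] (`i1` indexes `left`, `i2`
#'   indexes `right`).
#' @export
interhemispheric_match <- function(left, right, d_fiber = 5, min_frac = 0.5,
                                   plane_x = 0) {
  mirrored <- reflect_atlas(right, plane_x)
  match_groups(left, mirrored, d_fiber = d_fiber, min_frac = min_frac)
}

reflect_atlas <- function(a, plane_x = 0) {
  a$bundles <- lapply(a$bundles, function(b) {
    b$fibers <- reflect_hemisphere(b$fibers, plane_x)
    b$hemisphere <- if (b$hemisphere == "left") "right" else "left"
    b
  })
  a
}

#' Symmetrize an atlas from an interhemispheric correspondence
#'
#' For each common pair, fuses the left bundle with the reflected right
#' bundle into the symmetric left bundle, then reflects that bundle to
#' produce its right counterpart — so the right bundle is the exact mirror
#' of the left. Bundles without a cross-hemisphere match are carried over
#' unchanged.
#'
#' @param left,right [atlas()] objects.
#' @param correspondence result of [interhemispheric_match()].
#' @param plane_x midsagittal plane (default 0).
#' @return An [atlas()] containing symmetric left/right bundle pairs
#'   followed by the unmatched single-hemisphere bundles.
#' @export
symmetrize_atlas <- function(left, right, correspondence, plane_x = 0) {
  bundles <- list()
  for (r in seq_len(nrow(correspondence))) {
    lb <- left$bundles[[correspondence$i1[r]]]
    rb <- right$bundles[[correspondence$i2[r]]]
    rb$fibers <- reflect_hemisphere(rb$fibers, plane_x)
    sym_l <- fuse_bundles(lb, rb, id = paste0(lb$id, "_sym_l"))
    sym_l$hemisphere <- "left"
    sym_r <- sym_l
    sym_r$id <- paste0(lb$id, "_sym_r")
    sym_r$hemisphere <- "right"
    sym_r$fibers <- reflect_hemisphere(sym_l$fibers, plane_x)
    bundles <- c(bundles, list(sym_l, sym_r))
  }
  lone_l <- setdiff(seq_along(left$bundles), correspondence$i1)
  lone_r <- setdiff(seq_along(right$bundles), correspondence$i2)
  bundles <- c(bundles, left$bundles[lone_l], right$bundles[lone_r])
  atlas(bundles, space = left$space,
        provenance = list(symmetrized = TRUE))
}

#' Write or read an atlas directory
#'
#' One streamline file per bundle (named by its label or id) plus a
#' `manifest.json` recording ids, labels, hemispheres, votes, subjects and
#' provenance.
#'
#' @param a an [atlas()].
#' @param dir directory path.
#' @param format streamline format (`"trk"`, `"tck"` or `"txt"`).
#' @return `dir` invisibly; `read_atlas` returns the [atlas()].
#' @export
write_atlas <- function(a, dir, format = "trk") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(a$bundles, function(b) {
    fname <- paste0(b$label %||% b$id, ".", format)
    write_tractogram(b$fibers, file.path(dir, fname), format)
    list(id = b$id, label = b$label, hemisphere = b$hemisphere,
         votes = if (is.na(b$votes)) NULL else b$votes, file = fname,
         subjects = b$subjects, provenance = b$provenance)
  })
  manifest <- list(space = a$space, provenance = a$provenance,
                   bundles = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  bundles <- lapply(manifest$bundles, function(e) {
    cs <- read_tractogram(file.path(dir, e$file))
    bundle(cs$fibers, subjects = unlist(e$subjects), id = e$id,
           hemisphere = e$hemisphere, label = e$label,
           votes = e$votes %||% NA_integer_,
           provenance = e$provenance %||% list())
  })
  atlas(bundles, space = manifest$space %||% "template",
        provenance = manifest$provenance %||% list())
}
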