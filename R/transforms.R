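#' Spatial transforms for streamlines
#'
#' A `transform` bundles a 4x4 affine with an optional displacement-field
#' volume (mm displacements on a voxel grid with its own voxel-to-mm
#' affine). Applying it maps every point p to M p, plus the trilinearly
#' interpolated displacement sampled at M p when a field is present — the
#' composition used when streamlines are carried into a template space by a
#' precomputed affine plus deformation field. Points outside the field grid
#' take the displacement of the nearest in-field voxel (warned once).
#'
#' @param matrix 4x4 affine (must be invertible).
#' @param field optional 4-D array (x, y, z, 3) of mm displacements.
#' @param field_affine voxel-to-mm affine of the field grid.
#' @return An object of class `transform`.
#' @export
spatial_transform <- function(matrix = diag(4), field = NULL,
                              field_affine = diag(4)) {
  matrix <- unname(as.matrix(matrix))
  if (!all(dim(matrix) == c(4L, 4L))) stop("matrix must be 4x4")
  d <- det(matrix)
  if (!is.finite(d) || abs(d) < 1e-12) stop("singular transform matrix")
  if (!is.null(field)) {
    if (length(dim(field)) != 4L || dim(field)[4L] != 3L)
      stop("field must be an (x, y, z, 3) array of mm displacements")
  }
  structure(list(kind = if (is.null(field)) "affine" else "affine+field",
                 matrix = matrix, field = field,
                 field_affine = unname(as.matrix(field_affine))),
            class = "transform")
}

#' Apply a spatial transform to a centroid set
#'
#' @param cs a [centroid_set()].
#' @param tr a [spatial_transform()].
#' @param space space tag of the output set (default `"template"`).
#' @return The transformed set; fiber topology and point counts unchanged.
#' @export
apply_transform <- function(cs, tr, space = "template") {
  stopifnot(inherits(tr, "transform"))
  warned <- FALSE
  cs$fibers <- lapply(cs$fibers, function(f) {
    p <- t(tr$matrix %*% rbind(t(f), 1))[, 1:3, drop = FALSE]
    if (!is.null(tr$field)) {
      s <- sample_field(tr$field, tr$field_affine, p)
      if (s$clamped && !warned) {
        warning("points outside the displacement field; ",
                "nearest-edge displacements used")
        warned <<- TRUE
      }
      p <- p + s$disp
    }
    p
  })
  cs$space <- space
  cs
}

# Trilinear interpolation of a displacement field at world-mm points.
# Out-of-grid points are clamped to the grid edge.
sample_field <- function(field, field_affine, pts) {
  dm <- dim(field)[1:3]
  vox <- t(solve(field_affine) %*% rbind(t(pts), 1))[, 1:3, drop = FALSE]
  clamped <- any(vox < 0) || any(sweep(vox, 2L, dm - 1L, ">") )
  vox <- pmin(pmax(vox, 0), matrix(dm - 1L, nrow(vox), 3L, byrow = TRUE))
  lo <- pmin(floor(vox), matrix(dm - 2L, nrow(vox), 3L, byrow = TRUE))
  lo <- pmax(lo, 0)
  w <- vox - lo
  disp <- matrix(0, nrow(pts), 3L)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    idx <- cbind(lo[, 1] + dx, lo[, 2] + dy, lo[, 3] + dz) + 1L
    for (c in 1:3)
      disp[, c] <- disp[, c] + wt * field[cbind(idx, c)]
  }
  list(disp = disp, clamped = clamped)
}

#' Reflect a centroid set across a sagittal plane
#'
#' Maps x to `2 * plane_x - x` (y and z unchanged) and flips the hemisphere
#' tag — the symmetric reflection used to carry right-hemisphere bundles
#' into the left hemisphere for interhemispheric matching. The set must be
#' in a mid-sagittally aligned space (talairach/template), where the
#' midsagittal plane is x = 0.
#'
#' @param cs a [centroid_set()] (or a bare list of fibers).
#' @param plane_x sagittal plane position in mm (default 0).
#' @return The reflected set with the hemisphere tag flipped.
#' @export
reflect_hemisphere <- function(cs, plane_x = 0) {
  refl <- function(f) { f[, 1] <- 2 * plane_x - f[, 1]; f }
  if (inherits(cs, "centroid_set")) {
    if (cs$space == "native")
      stop("reflection requires a mid-sagittally aligned space")
    cs$fibers <- lapply(cs$fibers, refl)
    cs$hemisphere <- if (cs$hemisphere == "left") "right" else "left"
    cs
  } else {
    lapply(cs, function(f) refl(as_fiber_matrix(f)))
  }
}

#' Clip fibers at a sagittal plane
#'
#' Keeps, per fiber, the maximal run of points on one side of the plane —
#' the generic utility used to split interhemispheric fibers (e.g. callosal
#' bundles) into per-hemisphere portions.
#'
#' @param fibers list of fiber matrices.
#' @param side `"left"` (x < plane) or `"right"` (x > plane).
#' @param plane_x plane position in mm.
#' @param min_points drop clipped fibers with fewer points than this.
#' @return List of clipped fiber matrices.
#' @export
clip_at_plane <- function(fibers, side = c("left", "right"), plane_x = 0,
                          min_points = 2L) {
  side <- match.arg(side)
  out <- lapply(fibers, function(f) {
    keep <- if (side == "left") f[, 1] < plane_x else f[, 1] > plane_x
    if (!any(keep)) return(NULL)
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    f[(ends[best] - r$lengths[best] + 1L):ends[best], , drop = FALSE]
  })
  out <- out[!vapply(out, is.null, logical(1))]
  out[vapply(out, nrow, integer(1)) >= min_points]
}
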