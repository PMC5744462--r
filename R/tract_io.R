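#' Streamline file input/output
#'
#' Three interchange formats are supported. TRK (TrackVis) is a binary
#' format whose points are stored in corner-origin "voxel-mm" coordinates;
#' they are converted to world mm on read using the header's voxel size and
#' voxel-to-RAS matrix, following the published format layout. TCK (MRtrix)
#' stores world mm directly. The plain-text dialect — one "x y z" line per
#' point, fibers separated by blank lines — exists so that small fixtures
#' and diffable outputs need no binary files.
#'
#' @name tract_io
NULL

#' Read a tractogram into a centroid set
#'
#' @param path file path.
#' @param format `"trk"`, `"tck"` or `"txt"`; guessed from the extension
#'   when missing.
#' @param subject_id,hemisphere,space metadata for the resulting
#'   [centroid_set()] (streamline files carry none of these).
#' @return A `centroid_set` in world mm. An empty file yields an empty set
#'   with a warning.
#' @export
read_tractogram <- function(path, format = NULL, subject_id = "s1",
                            hemisphere = "left", space = "native") {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% guess_format(path)
  fibers <- switch(format,
    trk = read_trk(path),
    tck = read_tck(path),
    txt = read_txt_fibers(path),
    stop("unknown streamline format: ", format))
  if (!length(fibers))
    warning("no streamlines in ", path, "; returning an empty centroid_set")
  centroid_set(fibers, subject_id = subject_id, hemisphere = hemisphere,
               space = space)
}

#' Write a centroid set to a streamline file
#'
#' @param cs a `centroid_set` (or bare list of fiber matrices).
#' @param path output path.
#' @param format `"trk"`, `"tck"` or `"txt"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(cs, path, format = NULL) {
  fibers <- if (inherits(cs, "centroid_set")) cs$fibers else
    lapply(cs, as_fiber_matrix)
  format <- format %||% guess_format(path)
  switch(format,
    trk = write_trk(fibers, path),
    tck = write_tck(fibers, path),
    txt = write_txt_fibers(fibers, path),
    stop("unknown streamline format: ", format))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("trk", "tck", "txt")) ext else
    stop("cannot guess streamline format from extension: ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- plain-text dialect ----------------------------------------------------

read_txt_fibers <- function(path) {
  lines <- readLines(path)
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, diff(blank) == -1L))[!blank]
  content <- lines[!blank]
  if (!length(content)) return(list())
  fibers <- lapply(split(content, grp), function(block) {
    vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(block), "\\s+"))))
    if (anyNA(vals) || length(vals) %% 3L != 0L)
      stop("malformed txt fiber block near line with content: ",
           substr(block[1L], 1L, 40L))
    matrix(vals, ncol = 3L, byrow = TRUE)
  })
  unname(fibers)
}

write_txt_fibers <- function(fibers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(fibers)) {
    f <- fibers[[k]]
    writeLines(sprintf("%.6f %.6f %.6f", f[, 1], f[, 2], f[, 3]), con)
    if (k < length(fibers)) writeLines("", con)
  }
}

## ---- TRK (TrackVis) --------------------------------------------------------

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", 6L)
  if (!identical(rawToChar(id[1:5]), "TRACK"))
    stop("not a TRK file (bad magic at byte offset 0): ", path)
  readBin(con, "integer", 3L, size = 2L)                     # dim
  voxel_size <- readBin(con, "double", 3L, size = 4L)
  readBin(con, "double", 3L, size = 4L)                      # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L)
  readBin(con, "raw", 200L)
  n_properties <- readBin(con, "integer", 1L, size = 2L)
  readBin(con, "raw", 200L)
  vox_to_ras <- matrix(readBin(con, "double", 16L, size = 4L), 4L, 4L,
                       byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L)
  n_count <- readBin(con, "integer", 1L, size = 4L)
  readBin(con, "integer", 1L, size = 4L)                     # version
  hdr_size <- readBin(con, "integer", 1L, size = 4L)
  if (hdr_size != 1000L)
    stop("TRK header size field is ", hdr_size, ", expected 1000 (byte 996)")
  has_affine <- is.finite(vox_to_ras[4, 4]) && vox_to_ras[4, 4] != 0
  if (!has_affine) {
    warning("TRK file has no voxel-to-RAS matrix; returning raw voxel-mm")
  }
  if (any(voxel_size <= 0)) voxel_size <- c(1, 1, 1)
  fibers <- list()
  offset <- 1000L
  repeat {
    m <- readBin(con, "integer", 1L, size = 4L)
    if (!length(m)) break
    if (m < 0L || m > 1e7)
      stop("malformed TRK record at byte offset ", offset, ": n_points = ", m)
    vals <- readBin(con, "double", m * (3L + n_scalars), size = 4L)
    if (length(vals) < m * (3L + n_scalars))
      stop("truncated TRK record at byte offset ", offset)
    if (n_properties > 0L) readBin(con, "double", n_properties, size = 4L)
    pts <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3,
                                                             drop = FALSE]
    if (has_affine) {
      vox <- sweep(pts, 2L, voxel_size, "/") - 0.5
      pts <- t(vox_to_ras %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
    }
    fibers[[length(fibers) + 1L]] <- pts
    offset <- offset + 4L + 4L * (m * (3L + n_scalars) + n_properties)
    if (n_count > 0L && length(fibers) >= n_count) break
  }
  fibers
}

write_trk <- function(fibers, path, voxel_size = c(1, 1, 1),
                      vox_to_ras = diag(4)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0L)), con)
  writeBin(as.integer(c(0L, 0L, 0L)), con, size = 2L)
  writeBin(as.numeric(voxel_size), con, size = 4L)
  writeBin(numeric(3L), con, size = 4L)                      # origin
  writeBin(0L, con, size = 2L)                               # n_scalars
  writeBin(raw(200L), con)
  writeBin(0L, con, size = 2L)                               # n_properties
  writeBin(raw(200L), con)
  writeBin(as.numeric(t(vox_to_ras)), con, size = 4L)
  writeBin(raw(444L), con)
  writeBin(c(charToRaw("LPS"), as.raw(0L)), con)             # voxel_order
  writeBin(raw(4L + 24L + 2L + 6L), con)
  writeBin(length(fibers), con, size = 4L)
  writeBin(2L, con, size = 4L)                               # version
  writeBin(1000L, con, size = 4L)
  inv <- solve(vox_to_ras)
  for (f in fibers) {
    vox <- t(inv %*% rbind(t(f), 1))[, 1:3, drop = FALSE] + 0.5
    pts <- sweep(vox, 2L, voxel_size, "*")
    writeBin(nrow(f), con, size = 4L)
    writeBin(as.numeric(t(pts)), con, size = 4L)
  }
}

## ---- TCK (MRtrix) ----------------------------------------------------------

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, 1L)
  if (!identical(trimws(first), "mrtrix tracks"))
    stop("not a TCK file (bad magic at byte offset 0): ", path)
  datatype <- "Float32LE"
  data_offset <- NA_integer_
  repeat {
    line <- readLines(con, 1L)
    if (!length(line)) stop("TCK header has no END line: ", path)
    if (identical(trimws(line), "END")) break
    kv <- strsplit(line, ":", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = ":"))
    if (key == "datatype") datatype <- val
    if (key == "file")
      data_offset <- as.integer(utils::tail(strsplit(val, "\\s+")[[1L]], 1L))
  }
  if (!identical(datatype, "Float32LE"))
    stop("unsupported TCK datatype: ", datatype)
  if (is.na(data_offset)) stop("TCK header lacks a file offset field")
  seek(con, data_offset)
  vals <- readBin(con, "double", file.size(path), size = 4L)
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  fibers <- list()
  start <- 1L
  for (r in seq_len(nrow(pts))) {
    if (!all(is.finite(pts[r, ]))) {
      if (r > start)
        fibers[[length(fibers) + 1L]] <- pts[start:(r - 1L), , drop = FALSE]
      start <- r + 1L
      if (all(is.infinite(pts[r, ]))) break
    }
  }
  fibers
}

write_tck <- function(fibers, path) {
  head1 <- c("mrtrix tracks", "datatype: Float32LE",
             sprintf("count: %d", length(fibers)))
  # the file offset field must state the total header length, including
  # itself and the END line; fixed-width formatting makes that a one-pass job
  stub <- paste0(paste(head1, collapse = "\n"), "\nfile: . ")
  offset <- nchar(stub, type = "bytes") + 15L + 1L + 4L      # %15d + \n + END\n
  header <- paste0(stub, formatC(offset, width = 15L), "\nEND\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  for (f in fibers) {
    writeBin(as.numeric(t(f)), con, size = 4L)
    writeBin(rep(NaN, 3L), con, size = 4L)
  }
  writeBin(rep(Inf, 3L), con, size = 4L)
}

## ---- affines and label volumes ---------------------------------------------

#' Read or write a 4x4 affine as whitespace-separated text
#' @param path file path.
#' @return `read_affine` returns a 4x4 matrix.
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(4L, 4L))) stop("affine file must hold a 4x4 matrix")
  m
}

#' @rdname read_affine
#' @param m a 4x4 matrix.
#' @export
write_affine <- function(m, path) {
  utils::write.table(format(m, digits = 17L), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a parcellation label volume from NIfTI
#'
#' @param path NIfTI file with integer labels (0 = background).
#' @param label_table data frame with columns `label` and `abbrev`; defaults
#'   to the bundled Desikan-Killiany table ([desikan_table()]).
#' @return A [parcellation_volume()].
#' @export
read_parcellation <- function(path, label_table = desikan_table()) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  parcellation_volume(array(as.integer(round(img)), dim = dim(img)),
                      voxel_to_mm = matrix(as.numeric(aff), 4L, 4L),
                      label_table = label_table)
}

#' Write a parcellation label volume to NIfTI
#' @param pv a [parcellation_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_parcellation <- function(pv, path) {
  img <- RNifti::asNifti(pv$labels)
  RNifti::pixdim(img) <- sqrt(colSums(pv$voxel_to_mm[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(pv$voxel_to_mm, code = 2L)
  RNifti::sform(img) <- structure(pv$voxel_to_mm, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
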