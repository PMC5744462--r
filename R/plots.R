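#' Plot atlas bundles as a 2-D projection
#'
#' Projects every bundle's fibers onto a coordinate plane and draws them
#' with one color per bundle — the quick visual check that clusters are
#' compact and distinct.
#'
#' @param a an [atlas()] (or list of [bundle()] objects).
#' @param plane `"yz"` (sagittal, default), `"xz"` or `"xy"`.
#' @return A ggplot object.
#' @export
plot_bundles <- function(a, plane = c("yz", "xz", "xy")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_bundles needs the ggplot2 package")
  plane <- match.arg(plane)
  ax <- switch(plane, yz = c(2L, 3L), xz = c(1L, 3L), xy = c(1L, 2L))
  bundles <- if (inherits(a, "atlas")) a$bundles else a
  df <- do.call(rbind, lapply(bundles, function(b) {
    do.call(rbind, lapply(seq_along(b$fibers), function(k) {
      f <- b$fibers[[k]]
      data.frame(h = f[, ax[1L]], v = f[, ax[2L]],
                 fiber = paste(b$id, k), bundle = b$label %||% b$id)
    }))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v,
                                   group = .data$fiber,
                                   color = .data$bundle)) +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = toupper(substr(plane, 1L, 1L)),
                  y = toupper(substr(plane, 2L, 2L)),
                  color = "bundle") +
    ggplot2::theme_minimal()
}
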