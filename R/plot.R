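#' Plot a lattice field
#'
#' @param field Numeric matrix.
#' @param title Optional plot title.
#' @param limits Optional fixed fill range.
#' @return A ggplot object (raster of the field, row 1 at the bottom).
#' @export
plot_field <- function(field, title = NULL, limits = NULL) {
  df <- tidyr::expand_grid(row = seq_len(nrow(field)),
                           col = seq_len(ncol(field)))
  df$value <- as.vector(t(field))[ (df$row - 1) * ncol(field) + df$col ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = limits) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = title, x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fhn_media <- function(object, ...) {
  plot_field(object$u, title = sprintf("u at t = %g", object$t), ...)
}

#' @export
autoplot.fhn_run <- function(object, which = c("snapshots", "series"), ...) {
  which <- match.arg(which)
  if (which == "series") {
    df <- object$series
    df$node <- sprintf("(%d,%d)", df$row, df$col)
    return(ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$u,
                                            colour = .data$node)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "t", y = "membrane potential u") +
             ggplot2::theme_minimal())
  }
  states <- object$snapshots
  if (length(states) == 0) states <- list(final = object$final)
  df <- purrr::map_dfr(states, function(s) {
    d <- tidyr::expand_grid(row = seq_len(nrow(s$u)),
                            col = seq_len(ncol(s$u)))
    d$value <- s$u[cbind(d$row, d$col)]
    d$t <- s$t
    d
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::facet_wrap(~t, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fhn_bifurcation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$peak_value)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::labs(x = unique(df$param), y = "peak membrane potential") +
    ggplot2::theme_minimal()
}

#' Write a field snapshot as a PNG image
#'
#' Renders a field as a raster whose pixel dimensions equal the grid
#' dimensions, for quick visual inspection of runs. Images are a viewing
#' aid only; no analysis reads them back.
#'
#' @param field Numeric matrix.
#' @param path Output PNG path.
#' @param range Value range mapped to the color scale (defaults to the
#'   field's own range; a constant field renders uniform).
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(field, path, range = NULL) {
  nr <- nrow(field); nc <- ncol(field)
  rng <- range %||% base::range(field)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  grDevices::png(path, width = nc, height = nr)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::image(t(field), zlim = rng, useRaster = TRUE, axes = FALSE,
                  col = grDevices::hcl.colors(256, "viridis"))
  invisible(path)
}
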