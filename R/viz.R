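#' Drawing table for a mosaic plot
#'
#' Everything a mosaic ideogram draws, as a plain tibble -- segment
#' intervals, origin, colour, and the angular extent each segment would
#' occupy on a circular plot -- so figures can be tested and reproduced
#' without touching pixels.
#'
#' @param segments Segment tibble (from [merge_runs()]) tiling one genome.
#' @param colors Named character vector mapping origin labels to colours;
#'   unlisted origins get defaults (recipient-like cyan, donor-like orange,
#'   grey for unassigned).
#' @return `segments` with columns `color`, `frac` (fraction of the genome),
#'   `theta_start`, `theta_end` (radians on a circular layout) appended.
#' @export
mosaic_drawing_table <- function(segments, colors = NULL) {
  segments <- dplyr::arrange(segments, .data$start)
  L <- max(segments$end)
  if (segments$start[1] != 0 ||
      (nrow(segments) > 1 && any(segments$start[-1] != segments$end[-nrow(segments)]))) {
    stop("overlap/gap: segments must tile the genome")
  }
  default_cols <- c(recipient = "#4FC3F7", donor = "#FB8C00",
                    unassigned = "grey70", marker = "grey30")
  pal <- default_cols
  if (!is.null(colors)) pal[names(colors)] <- colors
  origins <- unique(segments$origin)
  missing_cols <- setdiff(origins, names(pal))
  if (length(missing_cols)) {
    extra <- grDevices::hcl.colors(length(missing_cols), "Dark 3")
    names(extra) <- missing_cols
    pal <- c(pal, extra)
  }
  segments$color <- unname(pal[segments$origin])
  segments$frac <- segments$length_bp / L
  segments$theta_start <- 2 * pi * segments$start / L
  segments$theta_end <- 2 * pi * segments$end / L
  segments
}

#' Plot a mosaic genome
#'
#' Linear or circular ideogram of a painted (or ground-truth) genome, with
#' segments coloured by parental origin and unassigned windows rendered
#' distinctly.
#'
#' @param segments Segment tibble tiling one genome.
#' @param style `"linear"` or `"circular"`.
#' @param colors Optional named origin-to-colour map.
#' @param title Plot title (defaults to the genome name).
#' @return A ggplot object. The data behind it is
#'   [mosaic_drawing_table()] output.
#' @export
plot_mosaic <- function(segments, style = c("linear", "circular"),
                        colors = NULL, title = NULL) {
  style <- match.arg(style)
  tab <- mosaic_drawing_table(segments, colors)
  pal <- stats::setNames(unique(tab$color), unique(tab$origin))
  title <- title %||% tab$genome[1]
  p <- ggplot2::ggplot(tab) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = 0.6, ymax = 1, fill = .data$origin
    )) +
    ggplot2::scale_fill_manual(values = pal, name = "origin") +
    ggplot2::labs(title = title, x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
  if (style == "circular") {
    p <- p + ggplot2::coord_polar(theta = "x") +
      ggplot2::ylim(0, 1) +
      ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                     panel.grid = ggplot2::element_blank())
  }
  p
}

#' Autoplot a painted genome
#'
#' @param object A `dct_paint` object.
#' @param style `"linear"` or `"circular"`.
#' @param ... Passed to [plot_mosaic()].
#' @return A ggplot object with the parent percentages in the subtitle.
#' @method autoplot dct_paint
#' @export
autoplot.dct_paint <- function(object, style = "linear", ...) {
  r <- object$report
  plot_mosaic(object$segments, style = style, ...) +
    ggplot2::labs(subtitle = sprintf(
      "%s %.2f%% | %s %.2f%% | unassigned %.2f%%",
      r$recipient, r$pct_recipient, r$donor, r$pct_donor, r$pct_unassigned
    ))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a windowed SNV-density track
#'
#' @param track Tibble from [snv_density_track()].
#' @return A ggplot bar track of SNV counts along the genome.
#' @export
plot_snv_density <- function(track) {
  ggplot2::ggplot(track) +
    ggplot2::geom_col(ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$count),
                      width = track$end - track$start, fill = "#6A1B9A") +
    ggplot2::labs(x = "position (bp)", y = "SNVs per window") +
    ggplot2::theme_minimal()
}
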