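#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_rect geom_col labs theme_minimal
#' @export
ggplot2::autoplot

#' @export
autoplot.ld_curve <- function(object, ...) {
  half <- attr(object, "half_decay_distance")
  p <- ggplot(object[!is.na(object$mean_r2), ],
              aes(x = .data$bin_mid / 1000, y = .data$mean_r2)) +
    geom_line(colour = "steelblue") +
    labs(x = "Distance (kb)", y = expression(mean ~ r^2),
         title = "LD decay") +
    theme_minimal()
  if (!is.na(half)) {
    p <- p + ggplot2::geom_vline(xintercept = half / 1000,
                                 linetype = "dashed")
  }
  p
}

#' @export
autoplot.clr_scan <- function(object, threshold = NULL, ...) {
  p <- ggplot(object, aes(x = .data$pos / 1e6, y = .data$clr)) +
    geom_point(size = 0.3, colour = "grey30") +
    labs(x = "Position (Mb)", y = "CLR", title = "Composite likelihood ratio scan") +
    theme_minimal()
  if (!is.null(threshold)) {
    p <- p + geom_hline(yintercept = threshold, colour = "firebrick",
                        linetype = "dashed")
  }
  p
}

#' @export
autoplot.sweep_scan_result <- function(object, ...) {
  p <- autoplot(object$grid, threshold = object$threshold)
  if (nrow(object$regions)) {
    p <- p + geom_rect(
      data = object$regions,
      aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
          ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15)
  }
  p
}

#' Plot a window-statistic table
#'
#' Line plot of any windowed statistic produced by the package
#' (heterozygosity, pi, Tajima's D, Fst) against window midpoint.
#'
#' @param windows Tibble with `chrom`, `start`, `end`, `value`.
#' @param ylab Axis label for the statistic.
#' @return A ggplot object, faceted by chromosome when several are
#'   present.
#' @export
plot_windows <- function(windows, ylab = "value") {
  p <- ggplot(windows,
              aes(x = (.data$start + .data$end) / 2e6, y = .data$value)) +
    geom_line(colour = "steelblue") +
    labs(x = "Window midpoint (Mb)", y = ylab) +
    theme_minimal()
  if (length(unique(windows$chrom)) > 1) {
    p <- p + ggplot2::facet_wrap(~chrom)
  }
  p
}

#' @export
autoplot.teapop_sfs <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$derived_count, y = .data$count)) +
    geom_col(fill = "steelblue") +
    labs(x = "Derived allele count", y = "Sites",
         title = "Site frequency spectrum") +
    theme_minimal()
}
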