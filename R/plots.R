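#' Plot an RFD scan
#'
#' Per-region RFD along the genome with the empirical top-quantile
#' threshold; selected regions are highlighted.
#'
#' @param object An `rfd_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rfd_scan
#' @export
autoplot.rfd_scan <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$rfd, colour = .data$selected)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (Mb)", y = "relative frequency difference",
                  title = "CNV relative-frequency-difference scan") +
    ggplot2::theme_minimal()
}

#' Plot a normalized depth track
#'
#' Normalized window read depth for one accession, with the deletion and
#' duplication thresholds drawn; flagged windows are coloured.
#'
#' @param depth Flagged depth tibble (see [flag_windows()]).
#' @param accession Accession to plot.
#' @param del_thresh,dup_thresh Thresholds to draw (defaults 0.25 / 1.75).
#' @return A ggplot object.
#' @export
plot_depth_track <- function(depth, accession, del_thresh = 0.25, dup_thresh = 1.75) {
  d <- depth[depth$accession == accession, , drop = FALSE]
  if (nrow(d) == 0) abort(paste0("no windows for accession ", accession))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window_start / 1e6, y = .data$norm_depth,
                                  colour = .data$flag)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::geom_hline(yintercept = c(del_thresh, dup_thresh), linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, scales = "free_x", ncol = 1) +
    ggplot2::scale_colour_manual(values = c(DEL = "firebrick", DUP = "steelblue"),
                                 na.value = "grey70") +
    ggplot2::labs(x = "position (Mb)", y = "normalized depth", title = accession) +
    ggplot2::theme_minimal()
}

#' Plot per-accession divergent-site ratios
#'
#' Windowed divergent-site ratio for one accession with candidate windows
#' highlighted — the introgression detector's raw view.
#'
#' @param flagged Flagged window tibble from [z_flag()].
#' @param accession Accession to plot.
#' @return A ggplot object.
#' @export
plot_divergence_track <- function(flagged, accession) {
  d <- flagged[flagged$accession == accession, , drop = FALSE]
  if (nrow(d) == 0) abort(paste0("no windows for accession ", accession))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window_start / 1e6, y = .data$ratio,
                                  colour = .data$candidate)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::facet_wrap(~chrom, scales = "free_x", ncol = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                                 na.value = "grey85") +
    ggplot2::labs(x = "position (Mb)", y = "divergent-site ratio", title = accession) +
    ggplot2::theme_minimal()
}
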