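#' Plot a chromatogram with optional detected peaks
#'
#' @param chrom Chromatogram tibble.
#' @param peaks Optional peak tibble from [detect_peaks()]; apexes and
#'   integration boundaries are marked.
#' @return A ggplot object.
#' @export
plot_chromatogram <- function(chrom, peaks = NULL) {
  check_chromatogram(chrom)
  p <- ggplot2::ggplot(chrom,
                       ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retention time (min)", y = "intensity (counts)")
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p +
      ggplot2::geom_vline(data = peaks,
                          ggplot2::aes(xintercept = .data$apex_rt),
                          linetype = "dashed", colour = "firebrick") +
      ggplot2::geom_rect(
        data = peaks, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$start_rt, xmax = .data$end_rt,
                     ymin = 0, ymax = .data$height),
        alpha = 0.15, fill = "firebrick"
      )
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.ms_chromatogram <- function(object, ...) {
  plot_chromatogram(object, ...)
}

#' TIC overview of a run
#'
#' Positive and negative total-ion chromatograms, faceted by polarity.
#'
#' @param object An `ms_run` with full scans.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ms_run <- function(object, ...) {
  pos <- extract_tic(object, "positive") %>% mutate(polarity = "positive")
  neg <- extract_tic(object, "negative") %>% mutate(polarity = "negative")
  bind_rows(pos, neg) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~polarity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "retention time (min)", y = "TIC (counts)")
}

#' Bar-style mass spectrum plot
#'
#' @param spectrum Tibble `(mz, intensity)` from [average_spectrum()].
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$mz, xend = .data$mz,
                               y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    ggplot2::labs(x = "m/z (Da)", y = "intensity (counts)")
}
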