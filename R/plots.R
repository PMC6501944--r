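#' Plot ERD/ERS time courses
#'
#' One line per class, faceted by channel; the reference window averages to
#' zero by construction.
#'
#' @param object an `erd_ers` tibble from [erd_ers()].
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.erd_ers <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$erd_pct,
                                       colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "time (ms)", y = "band power change (%)",
                  colour = NULL,
                  title = sprintf("ERD/ERS, %g-%g Hz",
                                  attr(object, "band_hz")[1],
                                  attr(object, "band_hz")[2])) +
    ggplot2::theme_minimal()
}

#' Plot Welch power spectral densities
#'
#' @param object an `eeg_psd` tibble from [psd_welch()].
#' @param log_power plot 10*log10 power (default TRUE).
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.eeg_psd <- function(object, log_power = TRUE, ...) {
  df <- dplyr::mutate(object,
                      value = if (log_power) 10 * log10(.data$psd) else
                        .data$psd)
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_hz, .data$value,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)",
                  y = if (log_power) "PSD (dB/Hz)" else "PSD (uV^2/Hz)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of signed r-squared discriminability
#'
#' @param object a `signed_r2` matrix from [signed_r2()].
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.signed_r2 <- function(object, ...) {
  df <- tibble::tibble(
    channel = rep(rownames(object), ncol(object)),
    time_ms = rep(attr(object, "time_ms"), each = nrow(object)),
    value = as.vector(unclass(object)))
  df$channel <- factor(df$channel, levels = rev(rownames(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$channel,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "time (ms)", y = NULL, fill = "signed r^2") +
    ggplot2::theme_minimal()
}

#' Grand-average ERP curves per class
#'
#' Averages epochs within class for the requested channels; the standard
#' target vs non-target visualization (P300 at centro-parietal sites).
#'
#' @param ep an [epoch_set()].
#' @param channels channels to show (default `c("Cz", "Oz")` intersected
#'   with what is present).
#' @return A ggplot.
#' @export
plot_erp_average <- function(ep, channels = c("Cz", "Oz")) {
  channels <- intersect(channels, ep$channel_names)
  if (!length(channels)) channels <- ep$channel_names[1]
  rows <- list()
  for (cls in seq_along(ep$labels$y_class)) {
    tr <- which(ep$labels$y_dec == cls)
    for (ch in channels) {
      ci <- match(ch, ep$channel_names)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        class = ep$labels$y_class[cls], channel = ch,
        time_ms = ep$time_ms,
        amplitude = colMeans(ep$data[tr, ci, , drop = FALSE][, 1, ]))
    }
  }
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$amplitude,
                                   colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "time (ms)", y = "amplitude (uV)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Speller accuracy and ITR across accumulated sequences
#'
#' @param report the tibble returned by the ERP pipeline (columns `n_seq`,
#'   `accuracy`, optionally `itr_bits_min`).
#' @return A ggplot.
#' @export
plot_sequence_accuracy <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(.data$n_seq, .data$accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "accumulated sequences", y = "selection accuracy") +
    ggplot2::theme_minimal()
}
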