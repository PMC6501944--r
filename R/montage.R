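#' Packaged 10-20 montage table
#'
#' The full recording montage: 62 EEG electrodes of the international 10-20
#' (extended) system plus 4 EMG channels (forearm flexors, both arms). The
#' approximate 2-d scalp coordinates (x: left -1 .. right +1; y: front +1 ..
#' back -1) drive the synthetic generator's spatial forward model; they make
#' no anatomical claim beyond relative electrode adjacency.
#'
#' @return A tibble with columns `channel`, `kind` ("EEG"/"EMG"), `x`, `y`.
#' @export
montage_table <- function() {
  rows <- list(
    Fp  = list(y = 0.95, ch = c("Fp1", "Fp2"),        xs = c(-0.18, 0.18)),
    AF  = list(y = 0.75, ch = c("AF7", "AF3", "AF4", "AF8"),
               xs = c(-0.62, -0.30, 0.30, 0.62)),
    F   = list(y = 0.55,
               ch = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
               xs = c(-0.85, -0.62, -0.40, -0.18, 0, 0.18, 0.40, 0.62, 0.85)),
    FC  = list(y = 0.28,
               ch = c("FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8"),
               xs = c(-0.90, -0.66, -0.42, -0.18, 0.18, 0.42, 0.66, 0.90)),
    C   = list(y = 0,
               ch = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
               xs = c(-0.95, -0.70, -0.45, -0.20, 0, 0.20, 0.45, 0.70, 0.95)),
    CP  = list(y = -0.28,
               ch = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
               xs = c(-0.90, -0.66, -0.42, -0.18, 0, 0.18, 0.42, 0.66, 0.90)),
    TP9 = list(y = -0.35, ch = c("TP9", "TP10"), xs = c(-1.05, 1.05)),
    P   = list(y = -0.55,
               ch = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
               xs = c(-0.85, -0.62, -0.40, -0.18, 0, 0.18, 0.40, 0.62, 0.85)),
    PO  = list(y = -0.75,
               ch = c("PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10"),
               xs = c(-0.95, -0.62, -0.30, 0, 0.30, 0.62, 0.95)),
    O   = list(y = -0.95, ch = c("O1", "Oz", "O2"), xs = c(-0.25, 0, 0.25))
  )
  eeg <- purrr::map_dfr(rows, function(r) {
    tibble::tibble(channel = r$ch, kind = "EEG", x = r$xs, y = r$y)
  })
  emg <- tibble::tibble(channel = paste0("EMG", 1:4), kind = "EMG",
                        x = c(-2, -2.2, 2, 2.2), y = -3)
  dplyr::bind_rows(eeg, emg)
}

#' Paradigm-specific channel subsets
#'
#' The analysis montages: `"ERP32"` -- the broad 32-channel set used for the
#' ERP speller; `"MI20"` -- 20 sensorimotor electrodes (FC/C/CP rows) for
#' motor imagery; `"SSVEP10"` -- 10 occipito-parietal electrodes for SSVEP;
#' `"ALL62"` -- every EEG channel of the montage (EMG excluded).
#'
#' @param name one of `"ERP32"`, `"MI20"`, `"SSVEP10"`, `"ALL62"`.
#' @return Character vector of channel labels in preset order.
#' @export
montage_preset <- function(name = c("ERP32", "MI20", "SSVEP10", "ALL62")) {
  name <- match.arg(name)
  switch(name,
    ERP32 = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "FC5", "FC1", "FC2", "FC6", "T7", "T8", "C3", "Cz", "C4",
              "TP9", "TP10", "CP5", "CP1", "CP2", "CP6",
              "P7", "P3", "Pz", "P4", "P8", "PO9", "PO10", "O1", "Oz", "O2"),
    MI20 = c("FC5", "FC3", "FC1", "FC2", "FC4", "FC6",
             "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
             "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6"),
    SSVEP10 = c("P7", "P3", "Pz", "P4", "P8", "PO9", "PO10", "O1", "Oz", "O2"),
    ALL62 = {
      tab <- montage_table()
      tab$channel[tab$kind == "EEG"]
    })
}

#' Restrict a recording or epoch set to a channel subset
#'
#' @param x a `continuous_eeg` or `epoch_set`.
#' @param channels a preset name accepted by [montage_preset()] or an explicit
#'   character vector of labels. Output channel order follows this argument.
#' @return Object of the same class with the requested channels, in order.
#' @export
select_channels <- function(x, channels) {
  if (is.character(channels) && length(channels) == 1L &&
      channels %in% c("ERP32", "MI20", "SSVEP10", "ALL62")) {
    channels <- montage_preset(channels)
  }
  have <- if (inherits(x, "continuous_eeg")) x$channel_names else x$channel_names
  missing_ch <- setdiff(channels, have)
  if (length(missing_ch)) {
    stop("channel(s) not present in data: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  idx <- match(channels, have)
  if (inherits(x, "continuous_eeg")) {
    continuous_eeg(x$signal[, idx, drop = FALSE], x$fs, x$markers,
                   channels, x$channel_kinds[idx], x$meta)
  } else if (inherits(x, "epoch_set")) {
    epoch_set(x$data[, idx, , drop = FALSE], x$time_ms, x$labels, x$fs,
              channels)
  } else {
    stop("select_channels() expects a continuous_eeg or epoch_set.",
         call. = FALSE)
  }
}
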