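#' Butterworth band-pass filter
#'
#' Band-pass filtering as used by every pipeline: a 5th-order Butterworth by
#' default (0.5--40 Hz for ERP, 8--30 Hz for motor imagery). Offline mode is
#' zero-phase (forward-backward, which squares the magnitude response);
#' online mode is a causal single pass, matching the simulated online loop
#' that filters a sliding buffer as it arrives.
#'
#' @param x a [continuous_eeg()] or [epoch_set()].
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order filter order (default 5).
#' @param mode `"offline"` (zero-phase, default) or `"online"` (causal).
#' @return Object of the same class, same shape, filtered per channel.
#' @export
bandpass_filter <- function(x, low_hz, high_hz, order = 5,
                            mode = c("offline", "online")) {
  mode <- match.arg(mode)
  fs <- x$fs
  check_band(low_hz, high_hz, fs, order)
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  padlen <- round(3 * fs / low_hz)  # covers the low-edge transient
  apply_channelwise(x, function(v) filt1(v, bf, mode, padlen))
}

check_band <- function(low_hz, high_hz, fs, order = 5) {
  if (order < 1) stop("filter order must be >= 1.", call. = FALSE)
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("band edges must satisfy 0 < low_hz < high_hz.", call. = FALSE)
  }
  if (high_hz >= fs / 2) {
    stop("high band edge (", high_hz, " Hz) must be below the Nyquist rate (",
         fs / 2, " Hz).", call. = FALSE)
  }
  invisible(TRUE)
}

# zero-phase filtering with odd-reflection end padding (suppresses the
# forward-backward startup transients); causal mode is a plain single pass
filt1 <- function(v, bf, mode, padlen = 0) {
  if (mode != "offline") return(as.numeric(signal::filter(bf, v)))
  n <- length(v)
  pl <- min(n - 1L, padlen)
  if (pl > 0) {
    head_pad <- 2 * v[1] - v[(pl + 1L):2L]
    tail_pad <- 2 * v[n] - v[(n - 1L):(n - pl)]
    out <- signal::filtfilt(bf, c(head_pad, v, tail_pad))
    as.numeric(out[(pl + 1L):(pl + n)])
  } else {
    as.numeric(signal::filtfilt(bf, v))
  }
}

# apply a vector->vector function along time for each channel (and trial)
apply_channelwise <- function(x, f) {
  if (inherits(x, "continuous_eeg")) {
    out <- apply(x$signal, 2, f)
    continuous_eeg(out, x$fs, x$markers, x$channel_names, x$channel_kinds,
                   x$meta)
  } else if (inherits(x, "epoch_set")) {
    d <- dim(x$data)
    out <- x$data
    for (tr in seq_len(d[1])) {
      for (ch in seq_len(d[2])) {
        out[tr, ch, ] <- f(x$data[tr, ch, ])
      }
    }
    epoch_set(out, x$time_ms, x$labels, x$fs, x$channel_names)
  } else {
    stop("expected a continuous_eeg or epoch_set.", call. = FALSE)
  }
}

#' Down-sample a recording
#'
#' Anti-alias low-pass (8th-order Butterworth at 0.8 x the new Nyquist,
#' zero-phase) followed by decimation by the integer ratio `fs / target_fs`.
#' Markers are remapped onto the decimated grid by the same ratio (floor).
#' The common post-acquisition step is 1,000 Hz to 100 Hz.
#'
#' @param rec a [continuous_eeg()].
#' @param target_fs target sampling rate; `rec$fs` must be an integer
#'   multiple of it.
#' @param antialias apply the anti-alias filter first (default `TRUE`).
#' @return A decimated [continuous_eeg()].
#' @export
downsample <- function(rec, target_fs, antialias = TRUE) {
  stopifnot(inherits(rec, "continuous_eeg"))
  r <- rec$fs / target_fs
  if (abs(r - round(r)) > 1e-9) {
    stop("fs (", rec$fs, ") must be an integer multiple of target_fs (",
         target_fs, ").", call. = FALSE)
  }
  r <- as.integer(round(r))
  if (r == 1L) return(rec)
  sig <- rec$signal
  if (antialias) {
    bf <- signal::butter(8, 0.8 * target_fs / rec$fs, type = "low")
    padlen <- round(3 * rec$fs / (0.4 * target_fs))
    sig <- apply(sig, 2, function(v) filt1(v, bf, "offline", padlen))
  }
  keep <- seq(1L, nrow(sig), by = r)
  new_markers <- rec$markers
  new_markers$sample <- as.integer(floor((new_markers$sample - 1L) / r) + 1L)
  continuous_eeg(sig[keep, , drop = FALSE], target_fs, new_markers,
                 rec$channel_names, rec$channel_kinds, rec$meta)
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' Segments `[start, end)` ms relative to each marker, half-open on the right
#' with 0-based sample offsets, so the printed epoch lengths are exact: at
#' 100 Hz, `[-200, 800)` gives 100 samples, `[1000, 3500)` gives 250 and
#' `[0, 4000)` gives 400.
#'
#' @param rec a [continuous_eeg()] with one marker per trial.
#' @param labels a [label_block()] aligned with the markers; if `NULL`,
#'   marker codes are used as class indices.
#' @param ival_ms numeric `c(start, end)` in ms relative to stimulus onset.
#' @return An [epoch_set()], trials x channels x samples.
#' @export
segment_epochs <- function(rec, labels = NULL, ival_ms) {
  stopifnot(inherits(rec, "continuous_eeg"), length(ival_ms) == 2L)
  fs <- rec$fs
  off0 <- round(ival_ms[1] / 1000 * fs)
  n_smp <- round((ival_ms[2] - ival_ms[1]) / 1000 * fs)
  if (n_smp < 1) stop("empty epoch interval.", call. = FALSE)
  onsets <- rec$markers$sample
  first <- onsets + off0
  last <- first + n_smp - 1L
  bad <- first < 1L | last > nrow(rec$signal)
  if (any(bad)) {
    stop("epoch interval exceeds recording bounds for marker(s) at sample(s): ",
         paste(onsets[bad], collapse = ", "), call. = FALSE)
  }
  if (is.null(labels)) {
    codes <- rec$markers$code
    cls <- sort(unique(codes))
    labels <- label_block(match(codes, cls), as.character(cls))
  }
  if (length(labels) != length(onsets)) {
    stop("labels length must equal marker count.", call. = FALSE)
  }
  n_tr <- length(onsets)
  n_ch <- ncol(rec$signal)
  dat <- array(0, c(n_tr, n_ch, n_smp))
  for (i in seq_len(n_tr)) {
    dat[i, , ] <- t(rec$signal[first[i]:last[i], , drop = FALSE])
  }
  time_ms <- ival_ms[1] + (0:(n_smp - 1L)) * 1000 / fs
  epoch_set(dat, time_ms, labels, fs, rec$channel_names)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over a pre-stimulus
#' reference window (the ERP pipeline uses `[-200, 0)` ms). Idempotent.
#'
#' @param ep an [epoch_set()].
#' @param ref_ms `c(start, end)` ms reference window inside the epoch.
#' @return The corrected [epoch_set()].
#' @export
baseline_correct <- function(ep, ref_ms) {
  stopifnot(inherits(ep, "epoch_set"))
  idx <- which(ep$time_ms >= ref_ms[1] & ep$time_ms < ref_ms[2])
  if (!length(idx)) {
    stop("reference interval [", ref_ms[1], ", ", ref_ms[2],
         ") ms lies outside the epoch time axis.", call. = FALSE)
  }
  base <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  out <- sweep(ep$data, c(1, 2), base, "-")
  epoch_set(out, ep$time_ms, ep$labels, ep$fs, ep$channel_names)
}
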