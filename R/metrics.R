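#' Event-related (de)synchronization of band power
#'
#' The classic ERD/ERS measure: epochs are band-pass filtered (zero-phase),
#' squared sample-wise (instantaneous band power), averaged over trials
#' within each class, smoothed with a centered 100 ms moving mean, and
#' expressed as percent change relative to the mean power in a reference
#' window:
#' \deqn{ERD\%(t) = 100 \cdot (P(t) - P_{ref}) / P_{ref}.}
#' Negative values are desynchronization (power loss, e.g. contralateral mu
#' suppression during hand imagery); the curve averages to zero over the
#' reference window by construction.
#'
#' @param ep an [epoch_set()] (broadband; filtering is done here).
#' @param band_hz analysis band, default `c(8, 12)` (mu rhythm).
#' @param ref_ms reference window, default `c(-500, 0)` ms.
#' @param smooth_ms moving-mean length (default 100 ms).
#' @param channels channels to report (default all).
#' @return Tibble `(class, channel, time_ms, power, erd_pct)` of class
#'   `erd_ers`.
#' @export
erd_ers <- function(ep, band_hz = c(8, 12), ref_ms = c(-500, 0),
                    smooth_ms = 100, channels = NULL) {
  stopifnot(inherits(ep, "epoch_set"))
  if (is.null(channels)) channels <- ep$channel_names
  epf <- bandpass_filter(select_channels(ep, channels),
                         band_hz[1], band_hz[2], order = 5)
  ref_idx <- which(epf$time_ms >= ref_ms[1] & epf$time_ms < ref_ms[2])
  if (!length(ref_idx)) {
    stop("reference window outside the epoch time axis.", call. = FALSE)
  }
  win <- max(1L, round(smooth_ms / 1000 * ep$fs))
  kern <- rep(1 / win, win)
  rows <- list()
  for (cls in seq_along(ep$labels$y_class)) {
    tr <- which(epf$labels$y_dec == cls)
    pow <- apply(epf$data[tr, , , drop = FALSE]^2, c(2, 3), mean)
    for (ch in seq_along(channels)) {
      p <- as.numeric(stats::filter(pow[ch, ], kern, sides = 2))
      p[is.na(p)] <- pow[ch, ][is.na(p)]   # edges: fall back to raw power
      p_ref <- mean(p[ref_idx])
      if (p_ref <= 0) stop("zero reference-window power.", call. = FALSE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        class = ep$labels$y_class[cls], channel = channels[ch],
        time_ms = epf$time_ms, power = p,
        erd_pct = 100 * (p - p_ref) / p_ref)
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("erd_ers", class(out)),
            band_hz = band_hz, ref_ms = ref_ms)
}

#' Signed r-squared class discriminability
#'
#' Per channel and time point, the point-biserial correlation r between the
#' instantaneous amplitude and the binary class label, reported as
#' \eqn{\mathrm{sign}(r)\, r^2}. The standard map for locating where two
#' conditions (e.g. target vs non-target, or left vs right imagery) differ.
#'
#' @param ep a two-class [epoch_set()].
#' @return Numeric matrix channels x samples with channel/time dimnames,
#'   class `signed_r2`.
#' @export
signed_r2 <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  if (length(ep$labels$y_class) != 2L) {
    stop("signed r-squared needs exactly two classes.", call. = FALSE)
  }
  y <- ep$labels$y_dec
  if (length(unique(y)) < 2L) stop("both classes must be present.",
                                   call. = FALSE)
  d <- dim(ep$data)
  out <- matrix(NA_real_, d[2], d[3],
                dimnames = list(ep$channel_names,
                                formatC(ep$time_ms, format = "g")))
  for (ch in seq_len(d[2])) {
    r <- suppressWarnings(stats::cor(ep$data[, ch, ], y))
    out[ch, ] <- sign(r) * r^2
  }
  out[is.na(out)] <- 0
  structure(out, class = c("signed_r2", class(out)), time_ms = ep$time_ms)
}

#' Welch power spectral density
#'
#' One-sided Welch estimate with 1 s Hann windows at 50% overlap (density
#' scaling, so the integrated PSD recovers the signal variance). Segments
#' shorter than one window fall back, with a warning, to a single
#' non-windowed periodogram of the whole segment.
#'
#' @param x a [continuous_eeg()], an [epoch_set()] (trials are treated as
#'   extra segments), or a numeric vector with `fs` supplied.
#' @param range_hz frequency range to keep, default `c(1, 25)`.
#' @param fs sampling rate, required when `x` is a bare vector.
#' @param window_s Welch window length in seconds (default 1).
#' @param channels channels to report (default all).
#' @return Tibble `(channel, freq_hz, psd)` of class `eeg_psd`; `psd` in
#'   signal-units squared per Hz.
#' @export
psd_welch <- function(x, range_hz = c(1, 25), fs = NULL, window_s = 1,
                      channels = NULL) {
  if (is.numeric(x) && is.null(dim(x))) {
    stopifnot(!is.null(fs))
    ch_names <- "ch1"
    sig_list <- list(matrix(x, ncol = 1))
    fs_use <- fs
  } else if (inherits(x, "continuous_eeg")) {
    ch_names <- x$channel_names
    sig_list <- list(x$signal)
    fs_use <- x$fs
  } else if (inherits(x, "epoch_set")) {
    ch_names <- x$channel_names
    n_tr <- dim(x$data)[1]
    sig_list <- lapply(seq_len(n_tr), function(i) t(x$data[i, , , drop = TRUE]))
    if (dim(x$data)[2] == 1L) sig_list <- lapply(sig_list, function(m) matrix(m, ncol = 1))
    fs_use <- x$fs
  } else {
    stop("unsupported input to psd_welch().", call. = FALSE)
  }
  if (is.null(channels)) channels <- ch_names
  ch_idx <- match(channels, ch_names)
  if (anyNA(ch_idx)) stop("unknown channel(s) requested.", call. = FALSE)

  nwin <- round(window_s * fs_use)
  rows <- list()
  for (k in seq_along(ch_idx)) {
    acc <- NULL; n_seg <- 0L; nfft <- NULL
    for (sig in sig_list) {
      v <- sig[, ch_idx[k]]
      ps <- welch_segments(v, fs_use, nwin)
      if (is.null(acc)) {
        acc <- as.numeric(ps$p) * ps$n
        nfft <- attr(ps$p, "nfft")
      } else {
        acc <- acc + as.numeric(ps$p) * ps$n
      }
      n_seg <- n_seg + ps$n
    }
    p <- acc / n_seg
    f <- (seq_along(p) - 1) * fs_use / nfft
    keep <- f >= range_hz[1] & f <= range_hz[2]
    rows[[k]] <- tibble::tibble(channel = channels[k], freq_hz = f[keep],
                                psd = p[keep])
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("eeg_psd", class(out)), fs = fs_use,
            range_hz = range_hz)
}

# average one-sided periodograms over Hann windows with 50% overlap;
# returns density-scaled PSD (units^2 / Hz) and the number of windows used
welch_segments <- function(v, fs, nwin) {
  n <- length(v)
  if (n < nwin) {
    warning("segment shorter than the Welch window; using one unwindowed ",
            "periodogram.")
    w <- rep(1, n)
    starts <- 1L
    nwin <- n
  } else {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))  # Hann
    step <- floor(nwin / 2)
    starts <- seq(1L, n - nwin + 1L, by = step)
  }
  nfft <- nwin
  u <- sum(w^2)
  half <- floor(nfft / 2) + 1L
  acc <- numeric(half)
  for (s0 in starts) {
    seg <- v[s0:(s0 + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(half)])^2 / (fs * u)
    # one-sided: double everything except DC (and Nyquist when nfft even)
    sc <- rep(2, half); sc[1] <- 1
    if (nfft %% 2 == 0) sc[half] <- 1
    acc <- acc + sp * sc
  }
  p <- acc / length(starts)
  attr(p, "nfft") <- nfft
  list(p = p, n = length(starts))
}

#' Resting-state alpha band power in dB
#'
#' `10 log10` of the mean Welch PSD in the alpha band (8--12 Hz), per
#' channel; the summary used to track arousal/workload drift across resting
#' runs.
#'
#' @param rec a [continuous_eeg()] resting segment (>= 10 s advisable).
#' @param band_hz band, default `c(8, 12)`.
#' @return Tibble `(channel, power_db)`.
#' @export
alpha_power <- function(rec, band_hz = c(8, 12)) {
  p <- psd_welch(rec, range_hz = band_hz)
  dplyr::summarise(dplyr::group_by(p, .data$channel),
                   power_db = 10 * log10(mean(.data$psd)), .groups = "drop")
}
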