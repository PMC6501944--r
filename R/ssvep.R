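#' Sinusoidal reference set for SSVEP frequency recognition
#'
#' For each stimulation frequency \eqn{f_i} builds the 4 x T reference
#' \deqn{Y_i = [\sin 2\pi f_i t;\ \cos 2\pi f_i t;\ \sin 2\pi(2f_i)t;\
#'       \cos 2\pi(2f_i)t], \quad t = 1/S, 2/S, \dots, T/S,}
#' i.e. the fundamental plus its second harmonic. The recorded paradigm uses
#' f = 12, 8.57, 6.67 and 5.45 Hz.
#'
#' @param freqs target frequencies in Hz.
#' @param n_samples epoch length T in samples.
#' @param fs sampling rate S in Hz; every `2 * freqs` must lie below
#'   Nyquist.
#' @param n_harmonics harmonics included (default 2 = fundamental + second).
#' @return Object of class `cca_reference`: list with `freqs`, `fs`,
#'   `n_samples` and `matrices` (one `(2*n_harmonics) x T` matrix per
#'   frequency).
#' @export
ssvep_reference <- function(freqs = c(12, 8.57, 6.67, 5.45), n_samples,
                            fs, n_harmonics = 2) {
  if (any(n_harmonics * freqs >= fs / 2)) {
    stop("harmonic frequency at or above Nyquist (", fs / 2, " Hz).",
         call. = FALSE)
  }
  t <- seq_len(n_samples) / fs
  mats <- lapply(freqs, function(f) {
    do.call(rbind, lapply(seq_len(n_harmonics), function(h) {
      rbind(sin(2 * pi * h * f * t), cos(2 * pi * h * f * t))
    }))
  })
  names(mats) <- as.character(freqs)
  structure(list(freqs = freqs, fs = fs, n_samples = n_samples,
                 n_harmonics = n_harmonics, matrices = mats),
            class = "cca_reference")
}

#' @export
print.cca_reference <- function(x, ...) {
  cat(sprintf("<cca_reference> %d frequencies (%s Hz), %d x %d each @ %g Hz\n",
              length(x$freqs), paste(x$freqs, collapse = ", "),
              2 * x$n_harmonics, x$n_samples, x$fs))
  invisible(x)
}

#' Largest canonical correlation between an epoch and a reference
#'
#' The maximal correlation achievable between any linear combination of the
#' (centered) EEG channels and any linear combination of the reference rows.
#' Computed via thin QR of both centered data matrices and an SVD of
#' \eqn{Q_X^\top Q_Y}, which avoids explicit covariance inversion; rank
#' deficiency is handled by dropping negligible QR directions.
#'
#' @param X numeric matrix, channels x samples (a single trial).
#' @param Y numeric reference matrix, components x samples (same sample
#'   count).
#' @return The largest canonical correlation in \[0, 1\]; 0 (with a warning)
#'   for a zero-variance epoch.
#' @export
cca_max_correlation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) {
    stop("X and Y must have the same number of samples.", call. = FALSE)
  }
  Xc <- t(X - rowMeans(X))            # samples x channels
  Yc <- t(Y - rowMeans(Y))
  if (all(abs(Xc) < 1e-300)) {
    warning("zero-variance epoch; canonical correlation set to 0.")
    return(0)
  }
  qx <- qr(Xc); qy <- qr(Yc)
  Qx <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(qy$rank), drop = FALSE]
  s <- svd(crossprod(Qx, Qy), nu = 0, nv = 0)$d
  min(max(s[1], 0), 1)
}

#' Classify SSVEP epochs by canonical correlation
#'
#' For every trial, computes the largest canonical correlation against each
#' frequency's reference and selects the frequency with the highest
#' correlation. Calibration-free. Exact ties (rare in float) go to the
#' lower-index (first-listed) frequency.
#'
#' @param ep an [epoch_set()] whose epoch length equals the reference's
#'   `n_samples`.
#' @param ref a [ssvep_reference()].
#' @return Tibble with one row per trial: `trial`, per-frequency
#'   correlations (`rho_<freq>`), `predicted` (frequency index) and
#'   `predicted_freq`.
#' @export
classify_ssvep <- function(ep, ref) {
  stopifnot(inherits(ep, "epoch_set"), inherits(ref, "cca_reference"))
  if (dim(ep$data)[3] != ref$n_samples) {
    stop("epoch length (", dim(ep$data)[3], ") must equal reference length (",
         ref$n_samples, ").", call. = FALSE)
  }
  n_tr <- dim(ep$data)[1]
  rho <- matrix(NA_real_, n_tr, length(ref$freqs))
  for (i in seq_len(n_tr)) {
    X <- ep$data[i, , , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    rho[i, ] <- purrr::map_dbl(ref$matrices, ~ cca_max_correlation(X, .x))
  }
  pred <- apply(rho, 1, which.max)    # first max -> lower frequency index
  out <- tibble::as_tibble(as.data.frame(rho))
  names(out) <- paste0("rho_", ref$freqs)
  dplyr::bind_cols(tibble::tibble(trial = seq_len(n_tr)), out,
                   tibble::tibble(predicted = pred,
                                  predicted_freq = ref$freqs[pred]))
}

#' SSVEP decoding accuracy and confusion matrix
#'
#' Convenience wrapper: classifies every epoch and scores against the epoch
#' labels (class i = frequency `ref$freqs[i]`).
#'
#' @param ep labeled [epoch_set()].
#' @param ref a [ssvep_reference()].
#' @return List with `accuracy`, `confusion` (true x predicted counts) and
#'   the per-trial `predictions` tibble.
#' @export
evaluate_ssvep <- function(ep, ref) {
  pred <- classify_ssvep(ep, ref)
  truth <- ep$labels$y_dec
  k <- length(ref$freqs)
  confusion <- table(factor(truth, levels = seq_len(k)),
                     factor(pred$predicted, levels = seq_len(k)))
  dimnames(confusion) <- list(true = ref$freqs, predicted = ref$freqs)
  list(accuracy = mean(pred$predicted == truth), confusion = confusion,
       predictions = dplyr::mutate(pred, true = truth))
}
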