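#' Continuous multichannel EEG recording
#'
#' The unit of file I/O: a continuous signal matrix plus event markers and
#' channel metadata. Trials are always stored continuous-with-markers;
#' epoching is an explicit, separate step (see [segment_epochs()]).
#'
#' @param signal numeric matrix, samples x channels, amplitudes in microvolts.
#' @param fs sampling rate in Hz (positive scalar).
#' @param markers data frame with integer columns `sample` (1-based sample
#'   index of each event onset) and `code` (integer event code). May have
#'   zero rows.
#' @param channel_names character vector of unique channel labels
#'   (10-20 system for EEG channels), one per signal column.
#' @param channel_kinds character vector, `"EEG"` or `"EMG"` per channel.
#'   Defaults to all-EEG.
#' @param meta named list of free-form metadata (subject, session, paradigm,
#'   phase, simulation ground truth, ...).
#'
#' @return An object of class `continuous_eeg`.
#' @seealso [label_block()], [epoch_set()], [read_recording()]
#' @export
continuous_eeg <- function(signal, fs, markers = NULL,
                           channel_names = NULL,
                           channel_kinds = NULL,
                           meta = list()) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  dimnames(signal) <- NULL
  n_ch <- ncol(signal)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(n_ch))
  }
  if (is.null(channel_kinds)) channel_kinds <- rep("EEG", n_ch)
  if (is.null(markers)) {
    markers <- tibble::tibble(sample = integer(), code = integer())
  } else {
    markers <- tibble::as_tibble(markers)
    markers$sample <- as.integer(markers$sample)
    markers$code <- as.integer(markers$code)
  }
  x <- structure(
    list(signal = signal, fs = as.numeric(fs), markers = markers,
         channel_names = as.character(channel_names),
         channel_kinds = as.character(channel_kinds), meta = meta),
    class = "continuous_eeg")
  validate_continuous_eeg(x)
  x
}

validate_continuous_eeg <- function(x) {
  stopifnot(inherits(x, "continuous_eeg"))
  if (!is.numeric(x$fs) || length(x$fs) != 1L || x$fs <= 0) {
    stop("`fs` must be a positive scalar sampling rate.", call. = FALSE)
  }
  if (length(x$channel_names) != ncol(x$signal)) {
    stop("length(channel_names) must equal the number of signal columns.",
         call. = FALSE)
  }
  if (anyDuplicated(x$channel_names)) {
    stop("channel_names must be unique.", call. = FALSE)
  }
  if (length(x$channel_kinds) != ncol(x$signal)) {
    stop("length(channel_kinds) must equal the number of channels.",
         call. = FALSE)
  }
  if (nrow(x$markers) > 0) {
    bad <- x$markers$sample < 1L | x$markers$sample > nrow(x$signal)
    if (any(bad)) {
      stop("marker sample indices out of range: ",
           paste(x$markers$sample[bad], collapse = ", "), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("<continuous_eeg> %d samples x %d channels @ %g Hz (%.1f s), %d markers\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              nrow(x$signal) / x$fs, nrow(x$markers)))
  if (length(x$meta)) {
    keys <- intersect(c("subject", "session", "paradigm", "phase"), names(x$meta))
    if (length(keys)) {
      cat("  meta:", paste(sprintf("%s=%s", keys, unlist(x$meta[keys])),
                           collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Per-trial class labels
#'
#' Labels in the dataset's three redundant encodings: integer class per trial
#' (`y_dec`), a one-hot logical matrix classes x trials (`y_logic`), and the
#' ordered class-name list (`y_class`). `y_logic` is derived from `y_dec`
#' when omitted; supplying both cross-checks consistency.
#'
#' @param y_dec integer vector of 1-based class indices, one per trial.
#' @param y_class character vector of class names (length = number of classes).
#' @param y_logic optional logical/0-1 matrix, classes x trials, one-hot.
#'
#' @return An object of class `label_block`.
#' @export
label_block <- function(y_dec, y_class, y_logic = NULL) {
  y_dec <- as.integer(y_dec)
  y_class <- as.character(y_class)
  n_cls <- length(y_class)
  if (length(y_dec) && (any(y_dec < 1L) || any(y_dec > n_cls))) {
    stop("y_dec values must index into y_class (1..", n_cls, ").", call. = FALSE)
  }
  if (is.null(y_logic)) {
    y_logic <- matrix(0L, n_cls, length(y_dec))
    if (length(y_dec)) y_logic[cbind(y_dec, seq_along(y_dec))] <- 1L
  } else {
    y_logic <- matrix(as.integer(y_logic != 0), nrow = nrow(y_logic))
  }
  x <- structure(list(y_dec = y_dec, y_logic = y_logic, y_class = y_class),
                 class = "label_block")
  validate_label_block(x)
  x
}

validate_label_block <- function(x) {
  stopifnot(inherits(x, "label_block"))
  if (nrow(x$y_logic) != length(x$y_class)) {
    stop("y_logic must have one row per class in y_class.", call. = FALSE)
  }
  if (ncol(x$y_logic) != length(x$y_dec)) {
    stop("y_logic must have one column per trial in y_dec.", call. = FALSE)
  }
  cs <- colSums(x$y_logic)
  if (length(cs) && any(cs != 1L)) {
    stop("y_logic columns must be one-hot (each trial in exactly one class).",
         call. = FALSE)
  }
  if (length(x$y_dec) &&
      any(apply(x$y_logic, 2, which.max) != x$y_dec)) {
    stop("y_dec inconsistent with argmax of y_logic.", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.label_block <- function(x, ...) {
  cat(sprintf("<label_block> %d trials, classes: %s\n", length(x$y_dec),
              paste(x$y_class, collapse = ", ")))
  invisible(x)
}

#' @export
length.label_block <- function(x) length(x$y_dec)

# subset a label block to trial indices i
subset_labels <- function(labels, i) {
  label_block(labels$y_dec[i], labels$y_class)
}

#' Epoched EEG trials
#'
#' A trials x channels x samples tensor cut stimulus-locked from a continuous
#' recording, with its relative time axis and labels.
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param time_ms numeric vector of sample times in ms relative to stimulus
#'   onset; strictly increasing, length = samples.
#' @param labels a [label_block()] with one entry per trial.
#' @param fs sampling rate in Hz.
#' @param channel_names channel labels, length = channels.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, labels, fs, channel_names) {
  x <- structure(
    list(data = data, time_ms = as.numeric(time_ms), labels = labels,
         fs = as.numeric(fs), channel_names = as.character(channel_names)),
    class = "epoch_set")
  validate_epoch_set(x)
  x
}

validate_epoch_set <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$data)
  if (length(d) != 3L) stop("epoch data must be a 3-d array.", call. = FALSE)
  if (length(x$time_ms) != d[3]) {
    stop("time_ms length must equal the number of samples per epoch.",
         call. = FALSE)
  }
  if (any(diff(x$time_ms) <= 0)) {
    stop("time_ms must be strictly increasing.", call. = FALSE)
  }
  if (length(x$labels) != d[1]) {
    stop("labels length must equal the number of trials.", call. = FALSE)
  }
  if (length(x$channel_names) != d[2]) {
    stop("channel_names length must equal the number of channels.", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, [%g, %g) ms\n",
              d[1], d[2], d[3], x$fs, x$time_ms[1],
              x$time_ms[length(x$time_ms)] + 1000 / x$fs))
  cat("  classes:", paste(sprintf("%s (n=%d)", x$labels$y_class,
                                  tabulate(x$labels$y_dec,
                                           length(x$labels$y_class))),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

# subset an epoch_set to trial indices i (keeps channels/time)
subset_epochs <- function(ep, i) {
  epoch_set(ep$data[i, , , drop = FALSE], ep$time_ms,
            subset_labels(ep$labels, i), ep$fs, ep$channel_names)
}
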