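#' 6x6 row-column speller layout
#'
#' The standard 36-symbol matrix speller (A--Z, 1--9, `_`), filled row-major.
#' One sequence is a full pass of 12 flashes: the six rows and the six
#' columns, so every cell is highlighted exactly twice per sequence.
#'
#' @return Object of class `speller_layout`: list with `grid` (6x6 character
#'   matrix), `symbols` (length 36), `groups` (list of 12 cell-index sets:
#'   rows 1--6 then columns 1--6) and `sequence_len = 12`.
#' @export
speller_layout <- function() {
  symbols <- c(LETTERS, as.character(1:9), "_")
  grid <- matrix(symbols, nrow = 6, ncol = 6, byrow = TRUE)
  groups <- c(
    lapply(1:6, function(r) which(matrix(row(grid) == r, 6, 6))),
    lapply(1:6, function(cc) which(matrix(col(grid) == cc, 6, 6)))
  )
  # cell indices are column-major positions in the 6x6 matrix
  structure(list(grid = grid, symbols = symbols, groups = groups,
                 sequence_len = 12L),
            class = "speller_layout")
}

#' @export
print.speller_layout <- function(x, ...) {
  cat("<speller_layout> 6x6, 36 symbols, 12 flash groups per sequence\n")
  print(x$grid, quote = FALSE)
  invisible(x)
}

# cell index (column-major in the 6x6 grid) of a symbol
symbol_cell <- function(layout, symbol) {
  idx <- which(layout$grid == symbol)
  if (!length(idx)) stop("symbol not in layout: ", symbol, call. = FALSE)
  idx[1]
}

# the two group ids (row, column) containing a symbol's cell
symbol_groups <- function(layout, symbol) {
  cell <- symbol_cell(layout, symbol)
  which(purrr::map_lgl(layout$groups, ~ cell %in% .x))
}

#' Select discriminant time intervals for mean-amplitude features
#'
#' Slides a 50 ms window in 10 ms steps over the post-stimulus range and
#' scores each position by the channel-maximum |signed r-squared| between the
#' window-mean amplitude and the target/non-target label, then greedily keeps
#' the top `n` non-overlapping windows. This makes the "discriminant
#' intervals" subject-dependent and fully deterministic given the data.
#'
#' @param ep a baseline-corrected two-class (target/non-target)
#'   [epoch_set()] whose time axis covers `search_ms`.
#' @param n number of intervals (default 10).
#' @param window_ms,step_ms sliding-window geometry (defaults 50 / 10 ms).
#' @param search_ms search range, default `c(0, 800)` ms.
#' @return Object of class `interval_spec`: tibble of intervals
#'   (`start_ms`, `end_ms`, `score`) sorted by start, with the channel set
#'   as an attribute.
#' @export
select_discriminant_intervals <- function(ep, n = 10, window_ms = 50,
                                          step_ms = 10,
                                          search_ms = c(0, 800)) {
  stopifnot(inherits(ep, "epoch_set"))
  starts <- seq(search_ms[1], search_ms[2] - window_ms, by = step_ms)
  y <- ep$labels$y_dec
  score <- purrr::map_dbl(starts, function(s0) {
    idx <- which(ep$time_ms >= s0 & ep$time_ms < s0 + window_ms)
    wm <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean) # trials x ch
    r <- suppressWarnings(stats::cor(wm, y))
    max(abs(sign(r) * r^2), na.rm = TRUE)
  })
  ord <- order(score, decreasing = TRUE)
  chosen <- integer(0)
  for (i in ord) {
    s0 <- starts[i]
    overlap <- any(abs(starts[chosen] - s0) < window_ms)
    if (!overlap) chosen <- c(chosen, i)
    if (length(chosen) == n) break
  }
  if (length(chosen) < n) {
    stop("fewer than ", n, " non-overlapping windows fit the search range.",
         call. = FALSE)
  }
  out <- tibble::tibble(start_ms = starts[chosen],
                        end_ms = starts[chosen] + window_ms,
                        score = score[chosen])
  out <- dplyr::arrange(out, .data$start_ms)
  structure(out, class = c("interval_spec", class(out)),
            channels = ep$channel_names)
}

#' Mean-amplitude features over discriminant intervals
#'
#' One feature per (channel, interval): the mean amplitude of the epoch in
#' that window. With the 32-channel ERP montage and 10 intervals this gives
#' the canonical 320-dimensional spatio-temporal feature vector.
#'
#' @param ep an [epoch_set()] on the channel set the spec was derived from.
#' @param spec an `interval_spec` from [select_discriminant_intervals()].
#' @return Numeric matrix, trials x (channels * intervals).
#' @export
ma_features <- function(ep, spec) {
  stopifnot(inherits(ep, "epoch_set"), inherits(spec, "interval_spec"))
  n_tr <- dim(ep$data)[1]; n_ch <- dim(ep$data)[2]
  n_int <- nrow(spec)
  out <- matrix(NA_real_, n_tr, n_ch * n_int)
  for (k in seq_len(n_int)) {
    idx <- which(ep$time_ms >= spec$start_ms[k] & ep$time_ms < spec$end_ms[k])
    if (!length(idx)) {
      stop("interval [", spec$start_ms[k], ", ", spec$end_ms[k],
           ") ms lies outside the epoch.", call. = FALSE)
    }
    out[, (k - 1L) * n_ch + seq_len(n_ch)] <-
      apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  }
  colnames(out) <- paste0(rep(ep$channel_names, n_int), "_iv",
                          rep(seq_len(n_int), each = n_ch))
  out
}

#' Train the ERP speller classifier
#'
#' Interval selection + mean-amplitude features + shrinkage LDA on
#' target/non-target flash epochs. Class order must put "target" second so
#' that positive decision values vote target.
#'
#' @param ep baseline-corrected flash [epoch_set()] with classes
#'   `(nontarget, target)`.
#' @param n_intervals discriminant intervals (default 10).
#' @param shrinkage LDA shrinkage; `"auto"` (default) is advisable for the
#'   320-dimensional feature space.
#' @return Object of class `erp_model` with `spec` and `lda`.
#' @export
train_erp <- function(ep, n_intervals = 10, shrinkage = "auto") {
  spec <- select_discriminant_intervals(ep, n = n_intervals)
  X <- ma_features(ep, spec)
  lda <- fit_lda(X, ep$labels$y_dec, shrinkage)
  structure(list(spec = spec, lda = lda, classes = ep$labels$y_class),
            class = "erp_model")
}

#' @export
print.erp_model <- function(x, ...) {
  cat(sprintf("<erp_model> %d intervals x %d channels, shrinkage %.3f\n",
              nrow(x$spec), length(attr(x$spec, "channels")),
              x$lda$shrinkage))
  invisible(x)
}

#' Per-flash target scores from a trained ERP model
#'
#' @param object an `erp_model`.
#' @param ep flash epochs.
#' @param ... unused.
#' @return Numeric decision values (higher = more target-like).
#' @export
predict.erp_model <- function(object, ep, ...) {
  predict(object$lda, ma_features(ep, object$spec), type = "decision")
}

#' Accumulate flash scores into a symbol decision
#'
#' For each cell, averages the classifier scores of all flashes whose group
#' contains that cell, over the first `n_seq` sequences only, and predicts
#' the argmax cell. Under a linear classifier this equals classifying the
#' sequence-averaged epochs. Ties go to the lowest cell in (row, column)
#' order.
#'
#' @param flash_scores numeric vector of per-flash classifier outputs in
#'   presentation order (12 flashes per sequence).
#' @param flash_groups integer vector of group ids (1--6 rows, 7--12
#'   columns) aligned with `flash_scores`, or a list of cell-index vectors.
#' @param layout a [speller_layout()].
#' @param n_seq number of sequences to use (1--5 typically).
#' @return The predicted symbol (length-1 character).
#' @export
decode_speller <- function(flash_scores, flash_groups,
                           layout = speller_layout(), n_seq = 5) {
  n_use <- n_seq * layout$sequence_len
  if (length(flash_scores) < n_use || length(flash_groups) < n_use) {
    stop("need ", n_use, " flash scores/groups for ", n_seq,
         " sequence(s); got ", length(flash_scores), ".", call. = FALSE)
  }
  flash_scores <- flash_scores[seq_len(n_use)]
  flash_groups <- flash_groups[seq_len(n_use)]
  cells <- if (is.list(flash_groups)) flash_groups else
    layout$groups[as.integer(flash_groups)]
  n_cells <- length(layout$symbols)
  tot <- numeric(n_cells); cnt <- numeric(n_cells)
  for (j in seq_along(flash_scores)) {
    cs <- cells[[j]]
    tot[cs] <- tot[cs] + flash_scores[j]
    cnt[cs] <- cnt[cs] + 1
  }
  if (any(cnt == 0)) {
    stop("cell(s) never flashed in the first ", n_seq, " sequence(s): ",
         paste(which(cnt == 0), collapse = ", "), call. = FALSE)
  }
  avg <- tot / cnt
  best <- which(avg == max(avg))
  if (length(best) > 1L) {
    # ties -> lowest (row, column) position in the grid
    rr <- ((best - 1L) %% 6L) + 1L
    cc <- ((best - 1L) %/% 6L) + 1L
    best <- best[order(rr, cc)][1L]
  }
  layout$grid[best]
}

#' Speller accuracy as sequences accumulate
#'
#' Decodes every character using 1 up to `max_seq` accumulated sequences and
#' reports the per-sequence accuracy against the true sentence.
#'
#' @param truth character vector of true symbols (one per speller selection).
#' @param score_list list (one element per character) of per-flash score
#'   vectors, `max_seq * 12` each, in presentation order.
#' @param group_list list of per-flash group-id vectors aligned with
#'   `score_list`.
#' @param layout a [speller_layout()].
#' @param max_seq maximum sequences (default 5).
#' @return Tibble with `n_seq`, `n_correct`, `accuracy`.
#' @export
accuracy_by_sequence <- function(truth, score_list, group_list,
                                 layout = speller_layout(), max_seq = 5) {
  stopifnot(length(truth) == length(score_list),
            length(truth) == length(group_list))
  purrr::map_dfr(seq_len(max_seq), function(ns) {
    pred <- purrr::map_chr(seq_along(truth), function(i) {
      decode_speller(score_list[[i]], group_list[[i]], layout, n_seq = ns)
    })
    tibble::tibble(n_seq = ns, n_correct = sum(pred == truth),
                   accuracy = mean(pred == truth))
  })
}

#' Information transfer rate (bits/min)
#'
#' The Wolpaw ITR for an N-choice selection with accuracy P at M selections
#' per minute:
#' \deqn{ITR = M \left( \log_2 N + P \log_2 P +
#'       (1-P)\log_2\frac{1-P}{N-1} \right)}
#' with \eqn{x \log_2 x \to 0} as \eqn{x \to 0}. For the 36-symbol speller
#' at the recorded stimulation timing, one selection takes
#' 60 flashes x 0.215 s + 0.8 s final epoch = 13.7 s (gaze-shifting time
#' excluded), so `selections_per_min = 60 / 13.7` and a perfect speller
#' reaches 22.6 bits/min.
#'
#' @param p selection accuracy in \[0, 1\].
#' @param n_classes number of alternatives N (>= 2), default 36.
#' @param selections_per_min commands per minute M, default `60 / 13.7`.
#' @return ITR in bits per minute.
#' @export
compute_itr <- function(p, n_classes = 36, selections_per_min = 60 / 13.7) {
  if (n_classes < 2) stop("n_classes must be >= 2.", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1].", call. = FALSE)
  if (selections_per_min <= 0) {
    stop("selections_per_min must be positive.", call. = FALSE)
  }
  xlog2 <- function(x) ifelse(x > 0, x * log2(x), 0)
  bits <- log2(n_classes) + xlog2(p) +
    ifelse(p < 1, (1 - p) * log2((1 - p) / (n_classes - 1)), 0)
  selections_per_min * bits
}
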