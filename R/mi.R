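#' Motor-imagery method configuration
#'
#' Bundles the decoding method and its hyperparameters. Defaults follow the
#' standard binary MI pipeline: 8--30 Hz band, `[1000, 3500)` ms epochs,
#' m = 2 filter pairs. FBCSP defaults to nine 4 Hz bands spanning 4--40 Hz
#' with k = 4 features kept by mutual information; the particle-based band
#' optimizer (BSSFO-style) defaults to 30 particles x 10 iterations with
#' 1 Hz Gaussian jitter.
#'
#' @param method one of `"csp"`, `"cssp"`, `"fbcsp"`, `"bssfo"`.
#' @param n_pairs filter pairs m (default 2).
#' @param band_hz analysis band for CSP/CSSP (default `c(8, 30)`).
#' @param ival_ms epoch interval in ms (default `c(1000, 3500)`).
#' @param delay_grid CSSP delay candidates in samples (default `1:10`).
#' @param fb_bands FBCSP band matrix (rows `lo, hi`); default 4--40 Hz in
#'   4 Hz steps.
#' @param k FBCSP features retained (default 4).
#' @param n_particles,n_iter,jitter_sd particle-scheme controls.
#' @param shrinkage LDA shrinkage (default 0; MI features are 2m-dimensional).
#' @return A list of class `mi_config`.
#' @export
mi_config <- function(method = c("csp", "cssp", "fbcsp", "bssfo"),
                      n_pairs = 2, band_hz = c(8, 30),
                      ival_ms = c(1000, 3500), delay_grid = 1:10,
                      fb_bands = cbind(lo = seq(4, 36, by = 4),
                                       hi = seq(8, 40, by = 4)),
                      k = 4, n_particles = 30, n_iter = 10, jitter_sd = 1,
                      shrinkage = 0) {
  method <- match.arg(method)
  stopifnot(n_pairs >= 1)
  structure(list(method = method, n_pairs = n_pairs, band_hz = band_hz,
                 ival_ms = ival_ms, delay_grid = delay_grid,
                 fb_bands = fb_bands, k = k, n_particles = n_particles,
                 n_iter = n_iter, jitter_sd = jitter_sd,
                 shrinkage = shrinkage),
            class = "mi_config")
}

#' Train a motor-imagery decoder
#'
#' Dispatches on `cfg$method`. Input epochs are expected band-limited already
#' for `"csp"`/`"cssp"` (the pipeline filters 8--30 Hz first); `"fbcsp"` and
#' `"bssfo"` filter internally and should receive broadband epochs.
#'
#' @param ep a two-class [epoch_set()].
#' @param cfg an [mi_config()].
#' @param seed integer seed for the stochastic band optimizer (ignored by
#'   deterministic methods).
#' @return An object of class `mi_model`.
#' @export
train_mi <- function(ep, cfg = mi_config(), seed = 1L) {
  fit <- switch(cfg$method,
    csp = {
      bank <- fit_csp(ep, cfg$n_pairs)
      X <- logvar_features(ep, bank)
      list(bank = bank, lda = fit_lda(X, ep$labels$y_dec, cfg$shrinkage))
    },
    cssp = fit_cssp(ep, cfg$n_pairs, cfg$delay_grid,
                    shrinkage = cfg$shrinkage),
    fbcsp = fit_fbcsp(ep, cfg$fb_bands, cfg$n_pairs, cfg$k,
                      shrinkage = cfg$shrinkage),
    bssfo = fit_bssfo(ep, cfg$n_particles, cfg$n_iter, seed = seed,
                      m = cfg$n_pairs, jitter_sd = cfg$jitter_sd,
                      shrinkage = cfg$shrinkage))
  structure(c(fit, list(method = cfg$method, cfg = cfg,
                        classes = ep$labels$y_class)),
            class = "mi_model")
}

#' @export
print.mi_model <- function(x, ...) {
  cat(sprintf("<mi_model> method = %s, classes: %s vs %s\n", x$method,
              x$classes[1], x$classes[2]))
  invisible(x)
}

# features for a fitted mi_model on new epochs
mi_features <- function(model, ep) {
  switch(model$method,
    csp = logvar_features(ep, model$bank),
    cssp = logvar_features(delay_embed(ep, model$tau), model$bank),
    fbcsp = fbcsp_features(model, ep),
    bssfo = {
      epf <- bandpass_filter(ep, model$band[1], model$band[2], order = 4)
      logvar_features(epf, model$bank)
    })
}

#' Predict motor-imagery classes or decision values
#'
#' @param object a fitted `mi_model`.
#' @param ep an [epoch_set()] on the same channel set.
#' @param type `"class"` (default) or `"decision"`.
#' @param ... unused.
#' @export
predict.mi_model <- function(object, ep, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  X <- mi_features(object, ep)
  dv <- predict(object$lda, X, type = "decision")
  if (type == "decision") return(dv)
  object$classes[ifelse(dv > 0, 2L, 1L)]
}

# ---- CSSP ------------------------------------------------------------------

# concatenate a tau-delayed copy of every channel; trims tau samples
delay_embed <- function(ep, tau) {
  d <- dim(ep$data)
  if (tau >= d[3]) stop("delay (", tau, ") must be below the epoch length (",
                        d[3], " samples).", call. = FALSE)
  keep <- (tau + 1L):d[3]
  aug <- array(0, c(d[1], 2L * d[2], length(keep)))
  aug[, seq_len(d[2]), ] <- ep$data[, , keep, drop = FALSE]
  aug[, d[2] + seq_len(d[2]), ] <- ep$data[, , keep - tau, drop = FALSE]
  epoch_set(aug, ep$time_ms[keep], ep$labels, ep$fs,
            c(ep$channel_names, paste0(ep$channel_names, "_dly")))
}

#' Common spatio-spectral patterns (CSSP)
#'
#' CSP on the channel set augmented with a tau-delayed copy of itself, which
#' gives each spatial filter an embedded two-tap frequency response. The
#' delay tau is chosen from `delay_grid` by cross-validated training
#' accuracy (5-fold, deterministic stratified folds); ties go to the
#' smallest delay.
#'
#' @param ep a two-class [epoch_set()].
#' @param m filter pairs.
#' @param delay_grid candidate delays in samples (>= 1).
#' @param shrinkage LDA shrinkage.
#' @return List with `bank` (over augmented channels), `lda`, `tau` and the
#'   per-delay CV table `delay_scores`.
#' @export
fit_cssp <- function(ep, m = 2, delay_grid = 1:10, shrinkage = 0) {
  stopifnot(all(delay_grid >= 1))
  scores <- purrr::map_dbl(delay_grid, function(tau) {
    cv_accuracy_csp(delay_embed(ep, tau), m, folds = 5, shrinkage = shrinkage)
  })
  tau <- delay_grid[which.max(scores)]   # which.max -> first max: smallest tau
  aug <- delay_embed(ep, tau)
  bank <- fit_csp(aug, m)
  X <- logvar_features(aug, bank)
  list(bank = bank, lda = fit_lda(X, ep$labels$y_dec, shrinkage),
       tau = tau,
       delay_scores = tibble::tibble(tau = delay_grid, cv_accuracy = scores))
}

# deterministic stratified k-fold CSP+LDA accuracy (used for model selection)
cv_accuracy_csp <- function(ep, m, folds = 5, shrinkage = 0) {
  y <- ep$labels$y_dec
  fold_id <- integer(length(y))
  for (cls in 1:2) {
    idx <- which(y == cls)
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  acc <- purrr::map_dbl(seq_len(folds), function(f) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    bank <- fit_csp(subset_epochs(ep, tr), m)
    lda <- fit_lda(logvar_features(subset_epochs(ep, tr), bank), y[tr],
                   shrinkage)
    pred <- ifelse(predict(lda, logvar_features(subset_epochs(ep, te), bank)) >
                     0, 2L, 1L)
    mean(pred == y[te])
  })
  mean(acc)
}

# ---- FBCSP -----------------------------------------------------------------

#' Filter-bank CSP (FBCSP)
#'
#' Per-band CSP + log-variance over a bank of Butterworth band-pass filters,
#' mutual-information feature selection (4-bin equal-frequency
#' discretization) and LDA on the retained features.
#'
#' @param ep a two-class broadband [epoch_set()].
#' @param bands two-column matrix of band edges in Hz (default from
#'   [mi_config()]: nine 4 Hz bands over 4--40 Hz).
#' @param m filter pairs per band.
#' @param k features kept (`k <= 2m * n_bands`).
#' @param shrinkage LDA shrinkage.
#' @return List with `banks` (per band), `bands`, `selected` (tibble of kept
#'   features with their MI scores) and `lda`.
#' @export
fit_fbcsp <- function(ep, bands = cbind(seq(4, 36, 4), seq(8, 40, 4)),
                      m = 2, k = 4, shrinkage = 0) {
  bands <- as.matrix(bands)
  n_b <- nrow(bands)
  if (n_b < 2) stop("FBCSP needs at least two bands.", call. = FALSE)
  if (k > 2 * m * n_b) {
    stop("k (", k, ") exceeds available features (", 2 * m * n_b, ").",
         call. = FALSE)
  }
  banks <- vector("list", n_b)
  feats <- vector("list", n_b)
  for (b in seq_len(n_b)) {
    epf <- bandpass_filter(ep, bands[b, 1], bands[b, 2], order = 4)
    banks[[b]] <- fit_csp(epf, m)
    feats[[b]] <- logvar_features(epf, banks[[b]])
  }
  X <- do.call(cbind, feats)
  band_of <- rep(seq_len(n_b), each = 2 * m)
  mi <- apply(X, 2, mutual_information_binned, y = ep$labels$y_dec)
  keep <- order(mi, decreasing = TRUE)[seq_len(k)]
  sel <- tibble::tibble(feature = keep, band = band_of[keep],
                        lo_hz = bands[band_of[keep], 1],
                        hi_hz = bands[band_of[keep], 2],
                        mi_bits = mi[keep])
  lda <- fit_lda(X[, keep, drop = FALSE], ep$labels$y_dec, shrinkage)
  list(banks = banks, bands = bands, m = m, selected = sel, lda = lda)
}

fbcsp_features <- function(model, ep) {
  need <- sort(unique(model$selected$band))
  n_feat_band <- 2 * model$m
  cols <- list()
  for (b in need) {
    epf <- bandpass_filter(ep, model$bands[b, 1], model$bands[b, 2],
                           order = 4)
    cols[[as.character(b)]] <- logvar_features(epf, model$banks[[b]])
  }
  X <- matrix(0, dim(ep$data)[1], length(model$selected$feature))
  for (j in seq_along(model$selected$feature)) {
    b <- model$selected$band[j]
    within <- model$selected$feature[j] - (b - 1L) * n_feat_band
    X[, j] <- cols[[as.character(b)]][, within]
  }
  X
}

#' Mutual information between a feature and a binary label
#'
#' Plug-in estimate on a 4-bin equal-frequency discretization of the
#' feature, in bits.
#'
#' @param f numeric feature vector.
#' @param y class labels.
#' @param n_bins number of equal-frequency bins (default 4).
#' @return Scalar MI estimate in bits.
#' @export
mutual_information_binned <- function(f, y, n_bins = 4) {
  br <- unique(stats::quantile(f, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(0)
  fb <- cut(f, breaks = br, include.lowest = TRUE)
  tab <- table(fb, y)
  p <- tab / sum(tab)
  pf <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_along(pf)) for (j in seq_along(py)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (pf[i] * py[j]))
  }
  mi
}

# ---- particle-based spectral band optimization (BSSFO-style) ---------------

#' Particle-based discriminative frequency-band search
#'
#' A simplified importance-sampling scheme over candidate band-pass edges
#' (lo, hi): particles start uniform in 4--40 Hz, each is scored by
#' cross-validated CSP+LDA accuracy on band-filtered epochs, and the cloud is
#' importance-resampled with Gaussian jitter each iteration. This follows
#' the spirit of Bayesian spatio-spectral filter optimization but is not the
#' reference MCMC algorithm; it trades sampling fidelity for a small, fully
#' reproducible search.
#'
#' @param ep a two-class broadband [epoch_set()].
#' @param n_particles particles (>= 2).
#' @param n_iter iterations.
#' @param seed integer seed; fixes the whole search.
#' @param m filter pairs.
#' @param jitter_sd Gaussian jitter sd in Hz.
#' @param shrinkage LDA shrinkage.
#' @return List with the selected `band`, fitted `bank` and `lda` on that
#'   band, the per-iteration `history` tibble, and `score` (CV accuracy of
#'   the selected band).
#' @export
fit_bssfo <- function(ep, n_particles = 30, n_iter = 10, seed = 1L, m = 2,
                      jitter_sd = 1, shrinkage = 0) {
  stopifnot(n_particles >= 2, n_iter >= 1)
  nyq <- ep$fs / 2
  lo_min <- 4; hi_max <- min(40, nyq - 1)
  withr::local_seed(as.integer(seed))
  draw_prior <- function(n) {
    lo <- stats::runif(n, lo_min, hi_max)
    hi <- stats::runif(n, lo_min, hi_max)
    swap <- lo > hi
    tmp <- lo[swap]; lo[swap] <- hi[swap]; hi[swap] <- tmp
    narrow <- (hi - lo) < 1
    if (any(narrow)) {
      hi[narrow] <- pmin(lo[narrow] + 1 + stats::runif(sum(narrow), 0, 4),
                         hi_max)
      lo[narrow] <- pmax(hi[narrow] - 1 - stats::runif(sum(narrow), 0, 4),
                         lo_min)
    }
    cbind(lo = lo, hi = hi)
  }
  particles <- draw_prior(n_particles)
  best <- list(band = NULL, score = -Inf)
  hist_rows <- list()
  for (it in seq_len(n_iter)) {
    scores <- purrr::map_dbl(seq_len(n_particles), function(i) {
      band <- particles[i, ]
      epf <- bandpass_filter(ep, band[1], band[2], order = 4)
      cv_accuracy_csp(epf, m, folds = 4, shrinkage = shrinkage)
    })
    i_best <- which.max(scores)
    if (scores[i_best] > best$score) {
      best <- list(band = particles[i_best, ], score = scores[i_best])
    }
    hist_rows[[it]] <- tibble::tibble(
      iter = it, best_lo = particles[i_best, 1], best_hi = particles[i_best, 2],
      best_cv = scores[i_best], mean_cv = mean(scores))
    if (it == n_iter) break
    wgt <- exp((scores - max(scores)) / 0.05)
    idx <- sample.int(n_particles, n_particles, replace = TRUE,
                      prob = wgt / sum(wgt))
    particles <- particles[idx, , drop = FALSE] +
      matrix(stats::rnorm(2 * n_particles, 0, jitter_sd), ncol = 2)
    particles[, 1] <- pmin(pmax(particles[, 1], lo_min), hi_max - 1)
    particles[, 2] <- pmin(pmax(particles[, 2], lo_min + 1), hi_max)
    degen <- particles[, 2] - particles[, 1] < 1
    if (any(degen)) particles[degen, ] <- draw_prior(sum(degen))
  }
  band <- as.numeric(best$band)
  epf <- bandpass_filter(ep, band[1], band[2], order = 4)
  bank <- fit_csp(epf, m)
  lda <- fit_lda(logvar_features(epf, bank), ep$labels$y_dec, shrinkage)
  list(band = band, bank = bank, lda = lda, score = best$score,
       history = dplyr::bind_rows(hist_rows))
}

# ---- cross-validation and online decoding ----------------------------------

#' Repeated stratified cross-validation of an MI decoder
#'
#' The offline benchmark: 10 repetitions of stratified 10-fold
#' cross-validation with all model fitting (spatial filters and LDA) inside
#' the training folds only.
#'
#' @param ep a two-class [epoch_set()] (band-limited as required by the
#'   method, see [train_mi()]).
#' @param cfg an [mi_config()].
#' @param folds,repeats cross-validation controls (defaults 10 x 10).
#' @param seed integer seed for the fold shuffles.
#' @return Object of class `mi_cv`: tibble of per-fold accuracies with
#'   attributes; see [glance.mi_cv()].
#' @export
crossvalidate_mi <- function(ep, cfg = mi_config(), folds = 10, repeats = 10,
                             seed = 1L) {
  y <- ep$labels$y_dec
  if (length(y) < folds) stop("need at least `folds` trials.", call. = FALSE)
  withr::local_seed(as.integer(seed))
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    fold_id <- integer(length(y))
    for (cls in 1:2) {                 # stratified: shuffle within class
      idx <- sample(which(y == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f); te <- which(fold_id == f)
      model <- train_mi(subset_epochs(ep, tr), cfg,
                        seed = sample.int(2^30, 1))
      pred <- predict(model, subset_epochs(ep, te))
      acc <- mean(pred == ep$labels$y_class[y[te]])
      rows[[length(rows) + 1L]] <- tibble::tibble(repeat_i = rep_i, fold = f,
                                                  accuracy = acc)
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("mi_cv", class(out)),
            method = cfg$method, folds = folds, repeats = repeats)
}

#' @rdname crossvalidate_mi
#' @param x an `mi_cv` result.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.mi_cv <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"),
                 accuracy = mean(x$accuracy), sd = stats::sd(x$accuracy),
                 folds = attr(x, "folds"), repeats = attr(x, "repeats"))
}

#' Simulated online sliding-window MI decoding
#'
#' Replays a continuous recording through the online loop: a sliding buffer
#' (1.5 s window, 0.5 s steps) is causally band-pass filtered, projected
#' through the trained spatial filters, classified with the trained LDA, and
#' the decision value is squashed to a horizontal feedback coordinate in
#' \[-1, 1\] via `tanh(dv / dv_sd)` with `dv_sd` the training decision-value
#' spread.
#'
#' @param stream a [continuous_eeg()] on the model's channel set.
#' @param model a fitted `mi_model` (methods with a single analysis band).
#' @param band_hz analysis band for the causal buffer filter; defaults to
#'   the model's training band.
#' @param window_s,step_s buffer length and step in seconds.
#' @return Tibble with `t_s` (window end time), `decision`, `coord`, `class`.
#' @export
online_decode_mi <- function(stream, model, band_hz = NULL, window_s = 1.5,
                             step_s = 0.5) {
  stopifnot(inherits(stream, "continuous_eeg"), inherits(model, "mi_model"))
  if (is.null(band_hz)) {
    band_hz <- if (model$method == "bssfo") model$band else model$cfg$band_hz
  }
  fs <- stream$fs
  wlen <- round(window_s * fs); step <- round(step_s * fs)
  n <- nrow(stream$signal)
  if (n < wlen) stop("stream shorter than one window.", call. = FALSE)
  starts <- seq(1L, n - wlen + 1L, by = step)
  bf <- signal::butter(5, band_hz / (fs / 2), type = "pass")
  Wsel <- model$bank$W[, model$bank$selected, drop = FALSE]
  dvs <- purrr::map_dbl(starts, function(s0) {
    buf <- stream$signal[s0:(s0 + wlen - 1L), , drop = FALSE]
    buf <- apply(buf, 2, function(v) as.numeric(signal::filter(bf, v)))
    if (model$method == "cssp") {
      tau <- model$tau
      buf <- cbind(buf[(tau + 1):nrow(buf), , drop = FALSE],
                   buf[1:(nrow(buf) - tau), , drop = FALSE])
    }
    P <- crossprod(Wsel, t(buf))
    v <- pmax(apply(P, 1, stats::var), .Machine$double.eps)
    sum(model$lda$w * log(v)) + model$lda$b
  })
  sdv <- model$lda$dv_sd
  if (!is.finite(sdv) || sdv <= 0) sdv <- 1
  tibble::tibble(t_s = (starts + wlen - 1L) / fs,
                 decision = dvs,
                 coord = tanh(dvs / sdv),
                 class = model$classes[ifelse(dvs > 0, 2L, 1L)])
}
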