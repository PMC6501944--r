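# shared fixtures, built in code at test time

# small random continuous recording with labeled markers
random_recording <- function(n_samples = 500, n_ch = 4, fs = 100,
                             n_markers = 6, n_classes = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sig <- matrix(rnorm(n_samples * n_ch), n_samples, n_ch)
  smp <- sort(sample(seq(10, n_samples - 10), n_markers))
  y <- sample(rep_len(seq_len(n_classes), n_markers))
  rec <- continuous_eeg(sig, fs,
                        tibble::tibble(sample = smp, code = y),
                        paste0("ch", seq_len(n_ch)),
                        meta = list(subject = "s1", phase = "train"))
  list(rec = rec,
       labels = label_block(y, paste0("class", seq_len(n_classes))))
}

# epochs with class-dependent variance structure: class 1 loud on channel 1,
# class 2 loud on channel 2, unit white noise elsewhere
variance_contrast_epochs <- function(n_per_class = 20, n_ch = 2, n_s = 200,
                                     loud_sd = sqrt(10), seed = 1) {
  set.seed(seed)
  n_tr <- 2 * n_per_class
  d <- array(rnorm(n_tr * n_ch * n_s), c(n_tr, n_ch, n_s))
  d[seq_len(n_per_class), 1, ] <- d[seq_len(n_per_class), 1, ] * loud_sd
  d[n_per_class + seq_len(n_per_class), 2, ] <-
    d[n_per_class + seq_len(n_per_class), 2, ] * loud_sd
  epoch_set(d, seq(0, by = 10, length.out = n_s),
            label_block(rep(1:2, each = n_per_class), c("a", "b")),
            100, paste0("ch", seq_len(n_ch)))
}

# generic random two-class epochs (optionally linearly mixed within class 1)
random_epochs <- function(n_tr = 40, n_ch = 6, n_s = 50, fs = 100,
                          mix_class1 = TRUE, seed = 1) {
  set.seed(seed)
  d <- array(rnorm(n_tr * n_ch * n_s), c(n_tr, n_ch, n_s))
  if (mix_class1) {
    A <- matrix(rnorm(n_ch^2), n_ch)
    for (i in seq_len(n_tr / 2)) d[i, , ] <- A %*% d[i, , ]
  }
  epoch_set(d, seq(0, by = 1000 / fs, length.out = n_s),
            label_block(rep(1:2, each = n_tr / 2), c("a", "b")),
            fs, paste0("ch", seq_len(n_ch)))
}

# synthetic P300-style flash epochs: Gaussian bump on targets
p300_epochs <- function(n_target = 60, n_nontarget = 120, n_ch = 8,
                        fs = 100, amp = 4, latency_ms = 350, width_ms = 60,
                        noise_sd = 2, seed = 1) {
  set.seed(seed)
  time_ms <- seq(-200, 800 - 1000 / fs, by = 1000 / fs)
  n_s <- length(time_ms)
  n_tr <- n_target + n_nontarget
  y <- c(rep(2L, n_target), rep(1L, n_nontarget))
  d <- array(rnorm(n_tr * n_ch * n_s, 0, noise_sd), c(n_tr, n_ch, n_s))
  bump <- amp * exp(-(time_ms - latency_ms)^2 / (2 * width_ms^2))
  chan_w <- exp(-((seq_len(n_ch) - n_ch / 2)^2) / 8)  # centro-parietal-ish
  for (i in which(y == 2L)) {
    d[i, , ] <- d[i, , ] + outer(chan_w, bump)
  }
  perm <- sample(n_tr)
  epoch_set(d[perm, , , drop = FALSE], time_ms,
            label_block(y[perm], c("nontarget", "target")),
            fs, paste0("ch", seq_len(n_ch)))
}

# independent brute-force oracle for the largest canonical correlation:
# explicit whitening of both covariance blocks + SVD of the coherence matrix
cca_oracle <- function(X, Y) {
  Xc <- X - rowMeans(X); Yc <- Y - rowMeans(Y)
  n <- ncol(X)
  Sxx <- tcrossprod(Xc) / (n - 1)
  Syy <- tcrossprod(Yc) / (n - 1)
  Sxy <- Xc %*% t(Yc) / (n - 1)
  inv_sqrt <- function(M) {
    e <- eigen(M, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nrow(M)) %*% t(e$vectors)
  }
  max(svd(inv_sqrt(Sxx) %*% Sxy %*% inv_sqrt(Syy))$d)
}

# independent CSP eigenvalue oracle: non-symmetric generalized eigenproblem
csp_eig_oracle <- function(S1, S2) {
  ev <- eigen(solve(S1 + S2) %*% S1, only.values = TRUE)$values
  sort(Re(ev), decreasing = TRUE)
}
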