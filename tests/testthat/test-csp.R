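test_that("CSP recovers the analytic filters of a 2-channel contrast", {
  ep <- variance_contrast_epochs(n_per_class = 30, n_s = 400)
  bank <- fit_csp(ep, m = 1)
  # class 1 is loud on channel 1: top filter aligns with the channel-1 axis
  top <- bank$W[, 1] / sqrt(sum(bank$W[, 1]^2))
  angle <- acos(min(1, abs(top[1]))) * 180 / pi
  expect_lt(angle, 2)
  bottom <- bank$W[, 2] / sqrt(sum(bank$W[, 2]^2))
  expect_lt(acos(min(1, abs(bottom[2]))) * 180 / pi, 2)
  # eigenvalues straddle 0.5
  expect_gt(bank$eigvals[1], 0.8)
  expect_lt(bank$eigvals[2], 0.2)
})

test_that("identical class covariances give eigenvalues of one half", {
  set.seed(5)
  d <- array(rnorm(20 * 3 * 100), c(20, 3, 100))
  d[11:20, , ] <- d[1:10, , ]        # class 2 duplicates class 1
  ep <- epoch_set(d, seq(0, 990, 10),
                  label_block(rep(1:2, each = 10), c("a", "b")),
                  100, c("c1", "c2", "c3"))
  bank <- fit_csp(ep, 1)
  expect_equal(bank$eigvals, rep(0.5, 3), tolerance = 1e-10)
})

test_that("CSP eigenvalues match a brute-force generalized-eigen oracle", {
  for (seed in 1:5) {
    ep <- random_epochs(n_tr = 40, n_ch = 6, n_s = 50, seed = seed)
    bank <- fit_csp(ep, 2)
    S1 <- eegbci:::class_cov(ep, 1L)
    S2 <- eegbci:::class_cov(ep, 2L)
    expect_equal(bank$eigvals, csp_eig_oracle(S1, S2), tolerance = 1e-8)
    # normalization w' (S1+S2) w = 1 for every filter
    expect_equal(diag(t(bank$W) %*% (S1 + S2) %*% bank$W),
                 rep(1, 6), tolerance = 1e-8)
  }
})

test_that("swapping the class roles reflects the eigenvalue spectrum", {
  ep <- random_epochs(seed = 7)
  S1 <- eegbci:::class_cov(ep, 1L)
  S2 <- eegbci:::class_cov(ep, 2L)
  b12 <- eegbci:::fit_csp_from_cov(S1, S2, 2, ep$channel_names)
  b21 <- eegbci:::fit_csp_from_cov(S2, S1, 2, ep$channel_names)
  expect_equal(b12$eigvals, rev(1 - b21$eigvals), tolerance = 1e-10)
})

test_that("CSP filters are invariant to invertible channel mixing", {
  ep <- random_epochs(n_ch = 4, n_tr = 60, n_s = 80, seed = 3)
  set.seed(33)
  M <- matrix(rnorm(16), 4)            # invertible mixing
  mixed <- ep
  for (i in seq_len(dim(ep)[1])) mixed$data[i, , ] <- M %*% ep$data[i, , ]
  # with raw covariances the spectrum and filtered signals are exactly
  # invariant (up to filter sign/scale, which log-variance turns into an
  # additive constant)
  b1 <- fit_csp(ep, 2, normalize = "none")
  b2 <- fit_csp(mixed, 2, normalize = "none")
  expect_equal(b1$eigvals, b2$eigvals, tolerance = 1e-8)
  f1 <- logvar_features(ep, b1)
  f2 <- logvar_features(mixed, b2)
  for (j in 1:4) {
    expect_equal(stats::sd(f1[, j] - f2[, j]), 0, tolerance = 1e-6)
  }
  # per-trial trace normalization keeps the spectrum nearly invariant
  expect_equal(fit_csp(ep, 2)$eigvals, fit_csp(mixed, 2)$eigvals,
               tolerance = 0.15)
})

test_that("log-variance features behave like log of signal power", {
  # a sinusoid of amplitude a has variance a^2/2
  fs <- 100
  n_s <- 400
  t <- seq_len(n_s) / fs
  a <- 3
  d <- array(0, c(2, 2, n_s))
  d[1, 1, ] <- a * sin(2 * pi * 7 * t)
  d[1, 2, ] <- rnorm(n_s)
  d[2, 1, ] <- rnorm(n_s)
  d[2, 2, ] <- a * sin(2 * pi * 7 * t)
  ep <- epoch_set(d, t * 1000, label_block(1:2, c("a", "b")), fs,
                  c("c1", "c2"))
  bank <- structure(list(W = diag(2), eigvals = c(1, 0), selected = 1:2,
                         channel_names = c("c1", "c2"), m = 1),
                    class = "csp_filters")
  f <- logvar_features(ep, bank)
  expect_equal(unname(f[1, 1]), log(a^2 / 2), tolerance = 0.02)
  # scaling the epoch by c shifts every feature by 2 log c
  ep2 <- ep
  ep2$data <- ep$data * 5
  f2 <- logvar_features(ep2, bank)
  expect_equal(f2 - f, matrix(2 * log(5), 2, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # m = 2 yields 4 features
  ep4 <- random_epochs(n_ch = 6, seed = 2)
  expect_equal(ncol(logvar_features(ep4, fit_csp(ep4, 2))), 4L)
})

test_that("LDA matches the closed form on spherical Gaussians", {
  set.seed(21)
  n <- 4000
  X <- rbind(matrix(rnorm(n, -1, 1), n / 2, 2),
             matrix(rnorm(n, 1, 1), n / 2, 2))
  X[, 2] <- rnorm(n)                   # only dimension 1 is informative
  y <- rep(1:2, each = n / 2)
  m <- fit_lda(X, y)
  wn <- m$w / sqrt(sum(m$w^2))
  expect_lt(acos(abs(wn[1])) * 180 / pi, 2)  # within 2 degrees of x-axis
  # label swap negates weights and bias
  m2 <- fit_lda(X, 3 - y)
  expect_equal(m2$w, -m$w, tolerance = 1e-10)
  expect_equal(m2$b, -m$b, tolerance = 1e-10)
})

test_that("LDA separates a linearly separable toy and flags singularity", {
  X <- matrix(c(0, 0, 1, 0.5, 5, 0, 5.5, 1), 4, 2, byrow = TRUE)
  y <- c(1, 1, 2, 2)
  m <- fit_lda(X, y)
  expect_equal(predict(m, X, type = "class"), y)
  # a constant feature makes the pooled covariance singular at lambda = 0
  Xs <- cbind(X, 1)
  expect_error(fit_lda(Xs, y, shrinkage = 0), "shrinkage")
  expect_s3_class(fit_lda(Xs, y, shrinkage = "auto"), "lda_model")
})

test_that("tidy and glance methods expose model internals as tibbles", {
  ep <- random_epochs(seed = 10)
  bank <- fit_csp(ep, 2)
  td <- tidy(bank)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$selected), 4L)
  m <- fit_lda(logvar_features(ep, bank), ep$labels$y_dec)
  expect_equal(nrow(tidy(m)), 5L)      # 4 weights + bias
  expect_equal(glance(m)$n_features, 4L)
})
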