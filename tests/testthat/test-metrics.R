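# band-limited epochs with a known power change in the task window
erd_fixture <- function(power_ratio, n_tr = 100, fs = 100, seed = 1) {
  set.seed(seed)
  time_ms <- seq(-1000, 4000 - 1000 / fs, by = 1000 / fs)
  n_s <- length(time_ms)
  task <- time_ms >= 500 & time_ms < 3500
  d <- array(0, c(n_tr, 1, n_s))
  bf <- signal::butter(4, c(8, 12) / (fs / 2), "pass")
  for (i in seq_len(n_tr)) {
    x <- as.numeric(signal::filter(bf, rnorm(n_s + 200)))[-(1:200)]
    x[task] <- x[task] * sqrt(power_ratio)
    d[i, 1, ] <- x
  }
  epoch_set(d, time_ms, label_block(rep(1L, n_tr), "task"), fs, "C3")
}

test_that("ERD/ERS recovers generator-truth power changes", {
  # stationary noise: fluctuations around zero
  e0 <- erd_ers(erd_fixture(1, n_tr = 400), ref_ms = c(-500, 0))
  mid <- dplyr::filter(e0, .data$time_ms >= 1000, .data$time_ms < 3000)
  expect_lt(abs(mean(mid$erd_pct)), 5)
  # 50% drop and 100% rise in the task window
  e_drop <- erd_ers(erd_fixture(0.5, seed = 2), ref_ms = c(-500, 0))
  drop_mid <- dplyr::filter(e_drop, .data$time_ms >= 1000, .data$time_ms < 3000)
  expect_lt(abs(mean(drop_mid$erd_pct) + 50), 5)
  e_rise <- erd_ers(erd_fixture(2, seed = 3), ref_ms = c(-500, 0))
  rise_mid <- dplyr::filter(e_rise, .data$time_ms >= 1000, .data$time_ms < 3000)
  expect_lt(abs(mean(rise_mid$erd_pct) - 100), 10)
  # the reference window averages to zero by construction
  ref <- dplyr::filter(e_drop, .data$time_ms >= -500, .data$time_ms < 0)
  expect_lt(abs(mean(ref$erd_pct)), 1e-9)
  expect_true(all(e_drop$erd_pct >= -100))
})

test_that("signed r-squared matches a direct correlation loop and its
           symmetries", {
  # 4-trial toy, exact agreement with the textbook formula
  d <- array(rnorm(4 * 2 * 6), c(4, 2, 6))
  ep <- epoch_set(d, 1:6, label_block(c(1, 1, 2, 2), c("a", "b")), 100,
                  c("c1", "c2"))
  out <- signed_r2(ep)
  for (ch in 1:2) for (s in 1:6) {
    r <- stats::cor(d[, ch, s], c(1, 1, 2, 2))
    expect_equal(out[ch, s], sign(r) * r^2, tolerance = 1e-12)
  }
  # antisymmetry under label swap
  ep2 <- ep
  ep2$labels <- label_block(c(2, 2, 1, 1), c("a", "b"))
  expect_equal(unclass(signed_r2(ep2)), -unclass(out), tolerance = 1e-12)
  # identical class means: values near zero
  set.seed(40)
  big <- epoch_set(array(rnorm(200 * 1 * 10), c(200, 1, 10)), 1:10,
                   label_block(rep(1:2, 100), c("a", "b")), 100, "cz")
  expect_lt(max(abs(signed_r2(big))), (3 / sqrt(200))^1)
  # deterministic separation at one sample reaches +/- 1
  sep <- ep
  sep$data[, 1, 3] <- c(0, 0, 1, 1)
  expect_equal(unname(signed_r2(sep)[1, 3]), 1, tolerance = 1e-12)
  expect_error(signed_r2(epoch_set(d, 1:6,
                                   label_block(rep(1L, 4), c("a", "b")),
                                   100, c("c1", "c2"))), "both classes")
})

test_that("Welch PSD finds tones, harmonics, and satisfies Parseval", {
  fs <- 100
  t <- seq_len(30 * fs) / fs
  x <- sin(2 * pi * 12 * t)
  p <- psd_welch(x, range_hz = c(1, 25), fs = fs)
  expect_equal(p$freq_hz[which.max(p$psd)], 12)
  # 5.45 Hz stimulus with harmonics: peaks at 10.9 and 16.35 Hz too
  y <- sin(2 * pi * 5.45 * t) + 0.5 * sin(2 * pi * 10.9 * t) +
    0.25 * sin(2 * pi * 16.35 * t) + rnorm(length(t), 0, 0.1)
  py <- psd_welch(y, range_hz = c(1, 25), fs = fs, window_s = 2)
  peak_near <- function(f0, width = 1) {
    band <- dplyr::filter(py, abs(.data$freq_hz - f0) <= width)
    rest <- dplyr::filter(py, abs(.data$freq_hz - f0) > width,
                          abs(.data$freq_hz - f0) <= 3)
    max(band$psd) > 3 * max(rest$psd)
  }
  expect_true(peak_near(5.45))
  expect_true(peak_near(10.9))
  expect_true(peak_near(16.35))
  # Parseval: integrated full-band PSD approximates the variance
  set.seed(41)
  z <- rnorm(20 * fs)
  pz <- psd_welch(z, range_hz = c(0, fs / 2), fs = fs)
  df <- diff(pz$freq_hz[1:2])
  expect_lt(abs(sum(pz$psd) * df - stats::var(z)) / stats::var(z), 0.05)
  # short segments fall back with a warning
  expect_warning(psd_welch(rnorm(50), fs = fs), "shorter")
})

test_that("alpha power obeys the dB law and detects an alpha source", {
  fs <- 100
  set.seed(42)
  base <- matrix(rnorm(20 * fs * 2), ncol = 2)
  rec <- continuous_eeg(base, fs, channel_names = c("Oz", "Cz"))
  rec2 <- continuous_eeg(2 * base, fs, channel_names = c("Oz", "Cz"))
  a1 <- alpha_power(rec)
  a2 <- alpha_power(rec2)
  expect_equal(a2$power_db - a1$power_db, rep(20 * log10(2), 2),
               tolerance = 0.01)
  # adding a 10 Hz component strictly raises alpha power
  t <- seq_len(nrow(base)) / fs
  rec3 <- continuous_eeg(base + sin(2 * pi * 10 * t), fs,
                         channel_names = c("Oz", "Cz"))
  expect_true(all(alpha_power(rec3)$power_db > a1$power_db))
})

test_that("resting segments are summarized per channel in recording order", {
  cfg <- sim_config(seed = 5, fs = 200, channels = c("Fp1", "Cz", "Oz"))
  segs <- purrr::map(1:3, function(i) {
    simulate_rest(duration_s = 12, cfg = sim_config(seed = i, fs = 200,
                                                    channels = c("Fp1", "Cz",
                                                                 "Oz")))
  })
  tab <- purrr::map_dfr(seq_along(segs),
                        ~ dplyr::mutate(alpha_power(segs[[.x]]),
                                        segment = .x))
  expect_equal(nrow(tab), 9L)
  expect_equal(unique(tab$segment), 1:3)
  # the posterior alpha source makes Oz the strongest alpha channel
  oz_best <- tab |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(best = .data$channel[which.max(.data$power_db)])
  expect_true(all(oz_best$best == "Oz"))
})
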