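test_that("band-pass magnitude response matches the designed filter", {
  fs <- 1000
  t <- seq_len(4 * fs) / fs
  # 10 Hz tone inside the 8-30 Hz passband: amplitude preserved within 1%
  rec <- continuous_eeg(matrix(sin(2 * pi * 10 * t), ncol = 1), fs)
  out <- bandpass_filter(rec, 8, 30)
  mid <- (fs):(3 * fs)  # avoid edge transients
  amp <- (max(out$signal[mid, 1]) - min(out$signal[mid, 1])) / 2
  # oracle: the designed digital filter's magnitude response at 10 Hz,
  # squared for the forward-backward pass
  bf <- signal::butter(5, c(8, 30) / (fs / 2), "pass")
  z <- exp(-1i * 2 * pi * 10 / fs)
  h10 <- abs(sum(bf$b * z^(0:(length(bf$b) - 1))) /
               sum(bf$a * z^(0:(length(bf$a) - 1))))^2
  expect_lt(abs(amp - h10) / h10, 0.01)
  expect_lt(abs(amp - 1), 0.015)   # passband tone essentially preserved

  # 100 uV DC offset removed almost completely
  rec_dc <- continuous_eeg(matrix(100, 2000, 1), fs)
  out_dc <- bandpass_filter(rec_dc, 8, 30)
  expect_lt(mean(abs(out_dc$signal)), 0.1)

  # 50 Hz tone: causal single pass matches the analytic order-5 Butterworth
  # band-pass magnitude within 5% (analog prototype; prewarping negligible
  # at 50 Hz / 1 kHz)
  rec50 <- continuous_eeg(matrix(sin(2 * pi * 50 * t), ncol = 1), fs)
  out50 <- bandpass_filter(rec50, 8, 30, mode = "online")
  amp50 <- (max(out50$signal[mid, 1]) - min(out50$signal[mid, 1])) / 2
  w <- (50^2 - 8 * 30) / (50 * (30 - 8))
  h_analytic <- 1 / sqrt(1 + w^10)
  expect_lt(abs(amp50 - h_analytic) / h_analytic, 0.05)
  # offline (forward-backward) squares the magnitude response
  out50z <- bandpass_filter(rec50, 8, 30, mode = "offline")
  amp50z <- (max(out50z$signal[mid, 1]) - min(out50z$signal[mid, 1])) / 2
  expect_lt(abs(amp50z - h_analytic^2) / h_analytic^2, 0.1)
})

test_that("band-pass filtering is linear and rejects invalid bands", {
  fs <- 200
  x <- matrix(rnorm(600), ncol = 2)
  rec_a <- continuous_eeg(x[, 1, drop = FALSE], fs)
  rec_b <- continuous_eeg(x[, 2, drop = FALSE], fs)
  rec_mix <- continuous_eeg(3 * x[, 1, drop = FALSE] -
                              2 * x[, 2, drop = FALSE], fs)
  f <- function(r) bandpass_filter(r, 4, 40)$signal
  expect_equal(f(rec_mix), 3 * f(rec_a) - 2 * f(rec_b), tolerance = 1e-10)
  expect_error(bandpass_filter(rec_a, 8, 150), "Nyquist")
  expect_error(bandpass_filter(rec_a, 30, 8), "band edges")
})

test_that("downsampling decimates, remaps markers and keeps in-band tones", {
  fs <- 1000
  n <- 10000
  t <- seq_len(n) / fs
  rec <- continuous_eeg(matrix(sin(2 * pi * 30 * t), ncol = 1), fs,
                        tibble::tibble(sample = 2500L, code = 1L))
  out <- downsample(rec, 100)
  expect_equal(nrow(out$signal), 1000L)
  expect_equal(out$fs, 100)
  expect_equal(out$markers$sample, 250L)
  # 30 Hz lies below the new 50 Hz Nyquist: amplitude within 2%
  mid <- 200:800
  amp <- (max(out$signal[mid, 1]) - min(out$signal[mid, 1])) / 2
  expect_lt(abs(amp - 1), 0.02)
  expect_error(downsample(rec, 300), "integer multiple")
})

test_that("epoch segmentation reproduces the printed epoch geometries", {
  fs <- 100
  n <- 2000
  rec <- continuous_eeg(matrix(rnorm(n * 2), n, 2), fs,
                        tibble::tibble(sample = c(500L, 1000L),
                                       code = c(1L, 2L)))
  lb <- label_block(c(1, 2), c("a", "b"))
  expect_equal(dim(segment_epochs(rec, lb, c(-200, 800)))[3], 100L)
  expect_equal(dim(segment_epochs(rec, lb, c(1000, 3500)))[3], 250L)
  expect_equal(dim(segment_epochs(rec, lb, c(0, 4000)))[3], 400L)
  # epoch values are the raw samples at the half-open window
  ep <- segment_epochs(rec, lb, c(0, 100))
  expect_equal(ep$data[1, 1, ], rec$signal[500:509, 1])
  expect_equal(ep$time_ms[1], 0)
  # out-of-bounds markers are reported per trial
  expect_error(segment_epochs(rec, lb, c(0, 15000)), "1000")
})

test_that("baseline correction zeroes the reference mean and is idempotent", {
  ep <- random_epochs(n_tr = 6, n_ch = 3, n_s = 100, mix_class1 = FALSE,
                      seed = 4)
  ep$time_ms <- seq(-200, 790, by = 10)
  epc <- baseline_correct(ep, c(-200, 0))
  ref_idx <- which(epc$time_ms >= -200 & epc$time_ms < 0)
  ref_means <- apply(epc$data[, , ref_idx, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(ref_means)), 1e-9)
  # idempotent
  epc2 <- baseline_correct(epc, c(-200, 0))
  expect_equal(epc2$data, epc$data, tolerance = 1e-12)
  # constant epochs become all-zero
  ep$data[] <- 7
  expect_equal(max(abs(baseline_correct(ep, c(-200, 0))$data)), 0)
  expect_error(baseline_correct(ep, c(-900, -800)), "outside")
})

test_that("channel presets select the documented montage subsets in order", {
  chans <- montage_preset("ALL62")
  expect_length(chans, 62)
  rec <- continuous_eeg(matrix(0, 10, 62), 100, channel_names = chans)
  expect_equal(select_channels(rec, "SSVEP10")$channel_names,
               c("P7", "P3", "Pz", "P4", "P8", "PO9", "PO10",
                 "O1", "Oz", "O2"))
  expect_length(select_channels(rec, "MI20")$channel_names, 20)
  expect_length(select_channels(rec, "ERP32")$channel_names, 32)
  expect_error(select_channels(rec, c("Cz", "XX9")), "XX9")
  # order follows the preset, not the recording
  out <- select_channels(rec, c("Oz", "Cz"))
  expect_equal(out$channel_names, c("Oz", "Cz"))
})

test_that("segment-then-downsample commutes with downsample-then-segment", {
  fs <- 1000
  n <- 30000
  set.seed(9)
  sig <- matrix(rnorm(n * 2), n, 2)
  # markers on the decimation grid: the two orders agree exactly
  onsets <- c(5001L, 12001L, 20001L)
  rec <- continuous_eeg(sig, fs, tibble::tibble(sample = onsets,
                                                code = c(1L, 2L, 1L)))
  lb <- label_block(c(1, 2, 1), c("a", "b"))
  a <- segment_epochs(downsample(rec, 100, antialias = FALSE), lb, c(0, 1000))
  b_full <- segment_epochs(rec, lb, c(0, 1000))
  keep <- seq(1, dim(b_full)[3], by = 10)
  expect_equal(dim(a$data)[3], length(keep))
  expect_equal(a$data, b_full$data[, , keep], tolerance = 1e-12)
  # off-grid marker: remap snaps at most one decimated sample backwards
  rec2 <- continuous_eeg(sig, fs, tibble::tibble(sample = 5005L, code = 1L))
  ds <- downsample(rec2, 100, antialias = FALSE)
  expect_equal(ds$markers$sample, 501L)   # original sample 5001
  expect_lte(abs(5005 - (10 * (ds$markers$sample - 1L) + 1L)), 10)
})
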