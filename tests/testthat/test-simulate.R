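small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, fs = 200, channels = c("Fp1", "F7", "F8", "C3",
                                                 "Cz", "C4", "T7", "T8",
                                                 "Pz", "Oz"), ...)
}

test_that("protocol generation reproduces the recorded trial counts", {
  cfg <- sim_config(seed = 1, fs = 100)
  # training sentence: 33 characters x 5 sequences x 12 flashes
  pr_train <- generate_protocol("erp", cfg)
  expect_equal(nrow(pr_train$markers), 33L * 60L)
  expect_equal(nrow(pr_train$markers), 1980L)
  # test sentence: 36 characters -> 2,160 flashes
  cfg_test <- sim_config(seed = 1, fs = 100,
                         erp = list(sentence =
                                      "PATTERN_RECOGNITION_MACHINE_LEARNING"))
  pr_test <- generate_protocol("erp", cfg_test)
  expect_equal(nrow(pr_test$markers), 2160L)
  # every character: each group flashed once per sequence; 24 target flashes
  fl <- pr_train$flashes
  per_char <- dplyr::count(fl, .data$char_idx)
  expect_true(all(per_char$n == 60L))
  expect_true(all(dplyr::count(fl, .data$char_idx, .data$seq,
                               .data$group)$n == 1L))
  expect_equal(sum(fl$is_target), 33L * 5L * 2L)
  # flash spacing equals the SOA
  d <- diff(fl$sample[fl$char_idx == 1])
  expect_true(all(abs(d - 0.215 * cfg$fs) <= 1))

  # MI: balanced classes
  pr_mi <- generate_protocol("mi", small_cfg())
  expect_equal(unname(tabulate(pr_mi$labels$y_dec)), c(50L, 50L))
  # SSVEP: 100 trials, 25 per class
  pr_ss <- generate_protocol("ssvep", small_cfg())
  expect_equal(nrow(pr_ss$markers), 100L)
  expect_equal(unname(tabulate(pr_ss$labels$y_dec)), rep(25L, 4))
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 9, mi = list(n_trials = 6, fixation_s = 1,
                                       blank_s = 1, blank_jitter_s = 0.2))
  a <- simulate_mi(cfg)
  b <- simulate_mi(cfg)
  expect_identical(a$rec$signal, b$rec$signal)
  expect_identical(a$rec$markers, b$rec$markers)
  c2 <- simulate_artifact("blink", duration_s = 3, cfg = small_cfg(2))
  c3 <- simulate_artifact("blink", duration_s = 3, cfg = small_cfg(2))
  expect_identical(c2$signal, c3$signal)
  # different seed changes the data
  d2 <- simulate_mi(small_cfg(seed = 10, mi = list(n_trials = 6,
                                                   fixation_s = 1,
                                                   blank_s = 1,
                                                   blank_jitter_s = 0.2)))
  expect_false(identical(a$rec$signal, d2$rec$signal))
})

test_that("simulated recordings round-trip through the HDF5 container", {
  path <- withr::local_tempfile(fileext = ".h5")
  cfg <- small_cfg(seed = 4, ssvep = list(trials_per_class = 2, isi_s = 0.5,
                                          stim_s = 1))
  sim <- simulate_ssvep(cfg)
  write_recording(sim$rec, path, "EEG_SSVEP_train", sim$labels)
  back <- read_recording(path, "EEG_SSVEP_train")
  expect_equal(back$rec$signal, sim$rec$signal)
  expect_equal(back$labels$y_dec, sim$labels$y_dec)
  expect_equal(back$rec$meta$paradigm, "ssvep")
})

test_that("left-hand imagery desynchronizes the contralateral mu rhythm", {
  cfg <- sim_config(seed = 21, fs = 200,
                    channels = c("C3", "Cz", "C4", "F3", "F4"),
                    mi = list(n_trials = 40, fixation_s = 1, blank_s = 1,
                              blank_jitter_s = 0.3))
  sim <- simulate_mi(cfg)
  ep <- segment_epochs(sim$rec, sim$labels, c(-1000, 4000))
  e <- erd_ers(ep, band_hz = c(8, 12), ref_ms = c(-1000, 0),
               channels = c("C3", "C4"))
  task <- dplyr::filter(e, .data$time_ms >= 500, .data$time_ms < 3500)
  # left-hand trials: ERD at the right hemisphere (C4), not at C3
  left_c4 <- mean(task$erd_pct[task$class == "left" & task$channel == "C4"])
  left_c3 <- mean(task$erd_pct[task$class == "left" & task$channel == "C3"])
  expect_lt(left_c4, -20)
  expect_gt(left_c3, -15)
  # and antagonistically for right-hand trials
  right_c3 <- mean(task$erd_pct[task$class == "right" & task$channel == "C3"])
  expect_lt(right_c3, -20)
})

test_that("the simulated P300 peaks where the generator puts it", {
  cfg <- sim_config(seed = 22, fs = 200,
                    channels = c("Fz", "Cz", "Pz", "Oz"),
                    erp = list(sentence = "ABCDE", inter_char_s = 0.5,
                               p300_amp_uv = 6))
  sim <- simulate_erp(cfg)
  ep <- baseline_correct(
    segment_epochs(bandpass_filter(sim$rec, 0.5, 40), sim$labels,
                   c(-200, 800)),
    c(-200, 0))
  cz <- match("Cz", ep$channel_names)
  tgt <- ep$labels$y_dec == 2L
  diff_wave <- colMeans(ep$data[tgt, cz, ]) - colMeans(ep$data[!tgt, cz, ])
  peak_ms <- ep$time_ms[which.max(diff_wave)]
  expect_gte(peak_ms, 300)
  expect_lte(peak_ms, 400)
})

test_that("SSVEP trials show fundamental plus harmonic structure", {
  cfg <- sim_config(seed = 23, fs = 200, channels = c("Pz", "Oz", "O1"),
                    ssvep = list(trials_per_class = 4, isi_s = 0.5))
  sim <- simulate_ssvep(cfg)
  ep <- segment_epochs(sim$rec, sim$labels, c(0, 4000))
  cls545 <- which(sim$labels$y_class == "5.45")
  idx <- which(sim$labels$y_dec == cls545)
  p <- psd_welch(eegbci:::subset_epochs(ep, idx), range_hz = c(2, 25),
                 window_s = 4, channels = "Oz")
  peak_rank <- function(f0) {
    near <- which(abs(p$freq_hz - f0) <= 0.3)
    max(p$psd[near]) / stats::median(p$psd)
  }
  expect_gt(peak_rank(5.45), 5)
  expect_gt(peak_rank(10.9), 5)
  expect_gt(peak_rank(16.35), 5)
})

test_that("artifact kinds have their stereotyped signatures", {
  cfg <- small_cfg(seed = 6)
  blink <- simulate_artifact("blink", duration_s = 10, cfg = cfg)
  expect_equal(nrow(blink$signal), 10L * cfg$fs)
  # blink: frontal low-frequency power dwarfs occipital
  lf_power <- function(rec, ch) {
    p <- psd_welch(rec, range_hz = c(0.5, 4), channels = ch)
    mean(p$psd)
  }
  expect_gt(lf_power(blink, "Fp1") / lf_power(blink, "Oz"), 10)
  # five kinds yield five distinct channel-by-band fingerprints
  kinds <- c("blink", "h_eye", "v_eye", "teeth", "arms")
  fp <- purrr::map(kinds, function(k) {
    rec <- simulate_artifact(k, duration_s = 5, cfg = small_cfg(seed = 6))
    p <- psd_welch(rec, range_hz = c(0.5, 60))
    bands <- cut(p$freq_hz, c(0, 4, 12, 30, 60))
    v <- tapply(p$psd, list(p$channel, bands), mean)
    as.vector(v / sum(v))
  })
  for (i in 1:4) for (j in (i + 1):5) {
    expect_gt(sqrt(sum((fp[[i]] - fp[[j]])^2)), 0.02)
  }
  expect_error(simulate_artifact("cough", cfg = cfg), "arg")
})
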