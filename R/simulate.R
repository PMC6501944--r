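#' Synthetic-EEG simulation settings
#'
#' One seeded configuration object drives every generator. Defaults follow
#' the recorded study conditions: 1,000 Hz sampling over the 62-channel EEG
#' montage; 100 balanced left/right motor-imagery trials per phase (3 s
#' fixation, 4 s task, 6 +/- 1.5 s blank); ERP speller flashes at 215 ms
#' stimulus-onset asynchrony (80 ms stimulus + 135 ms gap), five 12-flash
#' sequences per character and a 4.5 s inter-character pause; SSVEP flicker
#' at 12/8.57/6.67/5.45 Hz for 4 s with a 6 s inter-stimulus interval, 25
#' trials per class. Amplitudes are in microvolts, calibrated to put resting
#' alpha-range power near the physiological range; decoding tests rely only
#' on relative quantities.
#'
#' @param seed integer; fixes all randomness of a generator call.
#' @param fs sampling rate in Hz.
#' @param channels channel labels to materialize (default the full
#'   62-channel EEG montage). Reduced subsets speed up simulation without
#'   changing the per-channel statistics.
#' @param noise_pink_uv pink (1/f) background amplitude (sd, microvolts).
#' @param noise_white_uv white sensor-noise floor (sd, microvolts).
#' @param spatial_spread Gaussian spatial-mixing kernel width in montage
#'   coordinate units; gives realistic cross-channel correlation.
#' @param mi,erp,ssvep named lists overriding per-paradigm defaults (see
#'   Details above); partial lists are merged over the defaults.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, fs = 1000, channels = montage_preset("ALL62"),
                       noise_pink_uv = 8, noise_white_uv = 1,
                       spatial_spread = 0.4,
                       mi = list(), erp = list(), ssvep = list()) {
  mi_def <- list(erd_depth = 0.8, mu_hz = 10, mu_amp_uv = 6, n_trials = 100,
                 fixation_s = 3, task_s = 4, blank_s = 6, blank_jitter_s = 1.5)
  erp_def <- list(p300_amp_uv = 5, p300_latency_ms = 350,
                  p300_latency_jitter_ms = 20, p300_width_ms = 60,
                  soa_ms = 215, n_seq = 5,
                  sentence = "NEURAL_NETWORKS_AND_DEEP_LEARNING",
                  inter_char_s = 4.5)
  ssvep_def <- list(snr = 1, stim_s = 4, isi_s = 6, trials_per_class = 25,
                    freqs = c(12, 8.57, 6.67, 5.45),
                    harmonic_amps = c(1, 0.5, 0.25))
  structure(list(seed = as.integer(seed), fs = fs, channels = channels,
                 noise_pink_uv = noise_pink_uv,
                 noise_white_uv = noise_white_uv,
                 spatial_spread = spatial_spread,
                 mi = utils::modifyList(mi_def, mi),
                 erp = utils::modifyList(erp_def, erp),
                 ssvep = utils::modifyList(ssvep_def, ssvep)),
            class = "sim_config")
}

# ---- primitives ------------------------------------------------------------

# unit-sd pink (1/f amplitude) noise via spectral shaping; the FFT length is
# padded to a highly composite size so the transform stays O(n log n)
pink_noise <- function(n) {
  nfft <- stats::nextn(n, factors = c(2, 3, 5))
  half <- nfft / 2
  mag <- c(0, 1 / sqrt(seq_len(half)))           # DC zeroed
  ph <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = c(0, ph))
  full <- c(spec, Conj(rev(spec[2:half])))
  v <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  v / stats::sd(v)
}

# Gaussian spatial mixing kernel over montage coordinates, rows normalized
spatial_kernel <- function(channels, spread) {
  tab <- montage_table()
  idx <- match(channels, tab$channel)
  if (anyNA(idx)) {
    stop("channel(s) not in the packaged montage: ",
         paste(channels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  xy <- cbind(tab$x[idx], tab$y[idx])
  d2 <- as.matrix(stats::dist(xy))^2
  K <- exp(-d2 / (2 * spread^2))
  K / rowSums(K)
}

# mixed pink + white background, samples x channels
sim_background <- function(n, cfg) {
  n_ch <- length(cfg$channels)
  src <- matrix(0, n, n_ch)
  for (ch in seq_len(n_ch)) src[, ch] <- pink_noise(n)
  K <- spatial_kernel(cfg$channels, cfg$spatial_spread)
  bg <- (src %*% t(K)) * cfg$noise_pink_uv
  bg + matrix(stats::rnorm(n * n_ch, 0, cfg$noise_white_uv), n, n_ch)
}

# spatial profile (length n_ch, max 1) of a source at a montage location
source_profile <- function(channels, at_channel, spread) {
  tab <- montage_table()
  idx <- match(c(channels, at_channel), tab$channel)
  xy <- cbind(tab$x[idx], tab$y[idx])
  n <- length(channels)
  d2 <- colSums((t(xy[seq_len(n), , drop = FALSE]) - xy[n + 1L, ])^2)
  exp(-d2 / (2 * spread^2))
}

# ---- protocol timelines ----------------------------------------------------

#' Generate a paradigm protocol timeline
#'
#' Builds the marker stream and labels of one experimental phase without
#' synthesizing any signal: MI (fixation + task + jittered blank, balanced
#' classes), ERP (per character, `n_seq` sequences of 12 flashes at the
#' configured SOA, then the inter-character pause; flash order within each
#' sequence is a seeded permutation of the 6 row + 6 column groups) or SSVEP
#' (stimulation + inter-stimulus interval, `trials_per_class` per
#' frequency, shuffled).
#'
#' @param paradigm `"mi"`, `"erp"` or `"ssvep"`.
#' @param cfg a [sim_config()].
#' @return List with `markers` (tibble `sample`, `code`), `labels`
#'   ([label_block()]), `n_samples` (timeline length) and, for ERP,
#'   `flashes` (tibble: `char_idx`, `target`, `seq`, `flash`, `group`,
#'   `sample`, `is_target`).
#' @export
generate_protocol <- function(paradigm = c("mi", "erp", "ssvep"), cfg) {
  paradigm <- match.arg(paradigm)
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed)
  fs <- cfg$fs
  switch(paradigm,
    mi = {
      p <- cfg$mi
      stopifnot(p$n_trials %% 2 == 0)
      y <- sample(rep(1:2, p$n_trials / 2))
      onset <- numeric(p$n_trials)
      t0 <- 1                               # 1 s lead-in
      for (i in seq_len(p$n_trials)) {
        t0 <- t0 + p$fixation_s
        onset[i] <- t0
        t0 <- t0 + p$task_s +
          p$blank_s + stats::runif(1, -p$blank_jitter_s, p$blank_jitter_s)
      }
      n_samples <- ceiling((t0 + 1) * fs)
      list(markers = tibble::tibble(sample = as.integer(round(onset * fs)) + 1L,
                                    code = y),
           labels = label_block(y, c("left", "right")),
           n_samples = n_samples)
    },
    erp = {
      p <- cfg$erp
      layout <- speller_layout()
      chars <- strsplit(p$sentence, "")[[1]]
      soa_s <- p$soa_ms / 1000
      rows <- list()
      t0 <- 1
      for (ci in seq_along(chars)) {
        tgt_groups <- symbol_groups(layout, chars[ci])
        for (sq in seq_len(p$n_seq)) {
          order12 <- sample(12L)
          for (fl in seq_len(layout$sequence_len)) {
            g <- order12[fl]
            rows[[length(rows) + 1L]] <- tibble::tibble(
              char_idx = ci, target = chars[ci], seq = sq, flash = fl,
              group = g, sample = as.integer(round(t0 * fs)) + 1L,
              is_target = g %in% tgt_groups)
            t0 <- t0 + soa_s
          }
        }
        t0 <- t0 + p$inter_char_s
      }
      flashes <- dplyr::bind_rows(rows)
      y <- ifelse(flashes$is_target, 2L, 1L)
      list(markers = tibble::tibble(sample = flashes$sample, code = y),
           labels = label_block(y, c("nontarget", "target")),
           n_samples = ceiling((t0 + 1) * fs),
           flashes = flashes)
    },
    ssvep = {
      p <- cfg$ssvep
      k <- length(p$freqs)
      y <- sample(rep(seq_len(k), p$trials_per_class))
      onset <- 1 + (seq_along(y) - 1) * (p$stim_s + p$isi_s)
      n_samples <- ceiling((onset[length(onset)] + p$stim_s + 1) * fs)
      list(markers = tibble::tibble(sample = as.integer(round(onset * fs)) + 1L,
                                    code = y),
           labels = label_block(y, as.character(p$freqs)),
           n_samples = n_samples)
    })
}

# ---- paradigm simulators ---------------------------------------------------

#' Simulate a motor-imagery recording
#'
#' Pink-noise background with realistic cross-channel correlation plus
#' 10 Hz mu-rhythm sources over the left and right motor cortex (C3, C4).
#' During the 4 s task window the source contralateral to the cued hand is
#' attenuated in amplitude by \eqn{\sqrt{1 - d}} (so its band power drops by
#' the event-related desynchronization depth `d`); the ipsilateral source is
#' untouched. `d = 0` yields a null recording with no class information.
#'
#' @param cfg a [sim_config()]; `cfg$mi` holds the paradigm parameters and
#'   the ground-truth depth `erd_depth`.
#' @return List with `rec` (a [continuous_eeg()], ground truth in `meta`)
#'   and `labels`.
#' @export
simulate_mi <- function(cfg = sim_config()) {
  proto <- generate_protocol("mi", cfg)
  withr::local_seed(cfg$seed + 1L)
  p <- cfg$mi
  fs <- cfg$fs
  n <- proto$n_samples
  sig <- sim_background(n, cfg)
  tt <- seq_len(n) / fs
  prof <- list(C3 = source_profile(cfg$channels, "C3", cfg$spatial_spread),
               C4 = source_profile(cfg$channels, "C4", cfg$spatial_spread))
  task_len <- round(p$task_s * fs)
  for (side in c("C3", "C4")) {
    env <- rep(p$mu_amp_uv, n)
    # ERD: left-hand imagery suppresses the right hemisphere (C4) and
    # vice versa
    suppressed_class <- if (side == "C4") 1L else 2L
    for (i in seq_len(nrow(proto$markers))) {
      if (proto$labels$y_dec[i] == suppressed_class) {
        s0 <- proto$markers$sample[i]
        idx <- s0:min(s0 + task_len - 1L, n)
        env[idx] <- p$mu_amp_uv * sqrt(1 - p$erd_depth)
      }
    }
    osc <- env * sin(2 * pi * p$mu_hz * tt + stats::runif(1, 0, 2 * pi))
    sig <- sig + outer(osc, prof[[side]])
  }
  rec <- continuous_eeg(sig, fs, proto$markers, cfg$channels,
                        meta = list(paradigm = "mi", seed = cfg$seed,
                                    erd_depth = p$erd_depth,
                                    mu_hz = p$mu_hz))
  list(rec = rec, labels = proto$labels)
}

#' Simulate an ERP speller recording
#'
#' Every target flash adds a positive centro-parietal deflection (a Gaussian
#' bump, default peak 350 ms +/- 20 ms jitter, sd 60 ms, largest at Cz/Pz)
#' on top of the spatially mixed pink-noise background; overlapping
#' responses from the rapid 215 ms flash train sum linearly. Non-target
#' flashes add nothing. The spelled sentence and per-flash group orders are
#' recoverable from the recording metadata.
#'
#' @param cfg a [sim_config()]; `cfg$erp$p300_amp_uv = 0` gives a null
#'   recording.
#' @return List with `rec`, `labels` and the per-flash `flashes` table from
#'   [generate_protocol()].
#' @export
simulate_erp <- function(cfg = sim_config()) {
  proto <- generate_protocol("erp", cfg)
  withr::local_seed(cfg$seed + 2L)
  p <- cfg$erp
  fs <- cfg$fs
  n <- proto$n_samples
  sig <- sim_background(n, cfg)
  prof <- (source_profile(cfg$channels, "Cz", cfg$spatial_spread) +
             source_profile(cfg$channels, "Pz", cfg$spatial_spread)) / 2
  bump_support_ms <- 4 * p$p300_width_ms
  tgt <- which(proto$flashes$is_target)
  for (i in tgt) {
    lat <- p$p300_latency_ms +
      stats::rnorm(1, 0, p$p300_latency_jitter_ms)
    t_ms <- seq(-bump_support_ms, bump_support_ms, by = 1000 / fs) + lat
    idx0 <- proto$flashes$sample[i] + round((lat - bump_support_ms) / 1000 * fs)
    idx <- idx0:(idx0 + length(t_ms) - 1L)
    ok <- idx >= 1 & idx <= n
    bump <- p$p300_amp_uv *
      exp(-((t_ms - lat)^2) / (2 * p$p300_width_ms^2))
    sig[idx[ok], ] <- sig[idx[ok], ] + outer(bump[ok], prof)
  }
  groups <- split(proto$flashes$group, proto$flashes$char_idx)
  rec <- continuous_eeg(sig, fs, proto$markers, cfg$channels,
                        meta = list(paradigm = "erp", seed = cfg$seed,
                                    sentence = p$sentence,
                                    p300_amp_uv = p$p300_amp_uv,
                                    groups = unname(groups)))
  list(rec = rec, labels = proto$labels, flashes = proto$flashes)
}

#' Simulate an SSVEP recording
#'
#' During each 4 s stimulation window the occipito-parietal channels receive
#' the flicker frequency plus its second and third harmonics (amplitude
#' ratios 1 : 0.5 : 0.25 by default), spatially weighted around Oz, over the
#' pink-noise background. `snr` scales the fundamental's amplitude relative
#' to the pink-noise amplitude.
#'
#' @param cfg a [sim_config()].
#' @return List with `rec` (truth class per trial in `labels` and `meta`)
#'   and `labels`.
#' @export
simulate_ssvep <- function(cfg = sim_config()) {
  proto <- generate_protocol("ssvep", cfg)
  withr::local_seed(cfg$seed + 3L)
  p <- cfg$ssvep
  fs <- cfg$fs
  n <- proto$n_samples
  sig <- sim_background(n, cfg)
  prof <- source_profile(cfg$channels, "Oz", cfg$spatial_spread)
  stim_len <- round(p$stim_s * fs)
  amp0 <- p$snr * cfg$noise_pink_uv
  for (i in seq_len(nrow(proto$markers))) {
    f <- p$freqs[proto$labels$y_dec[i]]
    s0 <- proto$markers$sample[i]
    idx <- s0:min(s0 + stim_len - 1L, n)
    tt <- (idx - s0 + 1) / fs
    ph <- stats::runif(length(p$harmonic_amps), 0, 2 * pi)
    wave <- 0
    for (h in seq_along(p$harmonic_amps)) {
      if (h * f < fs / 2) {
        wave <- wave + amp0 * p$harmonic_amps[h] *
          sin(2 * pi * h * f * tt + ph[h])
      }
    }
    sig[idx, ] <- sig[idx, ] + outer(wave, prof)
  }
  rec <- continuous_eeg(sig, fs, proto$markers, cfg$channels,
                        meta = list(paradigm = "ssvep", seed = cfg$seed,
                                    freqs = p$freqs, snr = p$snr))
  list(rec = rec, labels = proto$labels)
}

#' Simulate a stereotyped artifact segment
#'
#' Ten-second artifact recordings of the five stereotyped kinds collected
#' before the main experiment: eye blinks (large slow frontal transients),
#' repetitive horizontal / vertical eye movements (step-like frontal
#' potentials, laterally antisymmetric for horizontal), teeth clenching
#' (broadband high-frequency temporal bursts) and arm flexing (sustained
#' broadband activity over lateral/central channels).
#'
#' @param kind one of `"blink"`, `"h_eye"`, `"v_eye"`, `"teeth"`, `"arms"`.
#' @param duration_s segment length (default 10 s).
#' @param cfg a [sim_config()].
#' @return A [continuous_eeg()] with one marker at segment start whose code
#'   identifies the kind (1--5 in the order above).
#' @export
simulate_artifact <- function(kind = c("blink", "h_eye", "v_eye", "teeth",
                                       "arms"),
                              duration_s = 10, cfg = sim_config()) {
  kind <- match.arg(kind)
  withr::local_seed(cfg$seed + 10L + match(kind, c("blink", "h_eye", "v_eye",
                                                   "teeth", "arms")))
  fs <- cfg$fs
  n <- round(duration_s * fs)
  sig <- sim_background(n, cfg)
  ch <- cfg$channels
  front <- source_profile(ch, "Fp1", cfg$spatial_spread) +
    source_profile(ch, "Fp2", cfg$spatial_spread)
  tt <- seq_len(n) / fs
  add <- switch(kind,
    blink = {
      onsets <- seq(0.7, duration_s - 0.7, by = 1.1)
      v <- numeric(n)
      for (o in onsets) {
        v <- v + 150 * exp(-((tt - o)^2) / (2 * 0.08^2))
      }
      outer(v, front)
    },
    h_eye = {
      steps <- 50 * sign(sin(2 * pi * 0.5 * tt))   # saccade-like square wave
      lr <- source_profile(ch, "F7", cfg$spatial_spread) -
        source_profile(ch, "F8", cfg$spatial_spread)
      outer(steps, lr)
    },
    v_eye = {
      steps <- 60 * sign(sin(2 * pi * 0.4 * tt + pi / 3))
      outer(steps, front)
    },
    teeth = {
      burst_env <- as.numeric(sin(2 * pi * 0.5 * tt) > 0.2)
      hf <- stats::rnorm(n) * burst_env * 40
      bf <- signal::butter(4, c(25, min(95, fs / 2 - 1)) / (fs / 2), "pass")
      hf <- as.numeric(signal::filter(bf, hf))
      lat <- source_profile(ch, "T7", cfg$spatial_spread) +
        source_profile(ch, "T8", cfg$spatial_spread)
      outer(hf, lat)
    },
    arms = {
      hf <- stats::rnorm(n) * 25
      bf <- signal::butter(4, c(15, min(60, fs / 2 - 1)) / (fs / 2), "pass")
      hf <- as.numeric(signal::filter(bf, hf))
      cen <- source_profile(ch, "C5", cfg$spatial_spread) +
        source_profile(ch, "C6", cfg$spatial_spread)
      outer(hf, cen)
    })
  code <- match(kind, c("blink", "h_eye", "v_eye", "teeth", "arms"))
  continuous_eeg(sig + add, fs,
                 tibble::tibble(sample = 1L, code = code),
                 ch, meta = list(paradigm = "artifact", kind = kind,
                                 seed = cfg$seed))
}

#' Simulate a resting-state segment
#'
#' Eyes-open-style background with a posterior alpha source: pink noise plus
#' a 10 Hz oscillation weighted around Oz.
#'
#' @param duration_s segment length in seconds (default 60).
#' @param alpha_amp_uv alpha source amplitude (default 4).
#' @param cfg a [sim_config()].
#' @return A [continuous_eeg()].
#' @export
simulate_rest <- function(duration_s = 60, alpha_amp_uv = 4,
                          cfg = sim_config()) {
  withr::local_seed(cfg$seed + 20L)
  fs <- cfg$fs
  n <- round(duration_s * fs)
  sig <- sim_background(n, cfg)
  prof <- source_profile(cfg$channels, "Oz", cfg$spatial_spread)
  tt <- seq_len(n) / fs
  osc <- alpha_amp_uv * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi))
  continuous_eeg(sig + outer(osc, prof), fs, NULL, cfg$channels,
                 meta = list(paradigm = "rest", seed = cfg$seed))
}
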