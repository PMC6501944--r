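#' End-to-end pipeline configuration
#'
#' Mirrors the recorded train/test flow: derive classifier parameters from
#' the training phase, validate on the test phase (the SSVEP pipeline is
#' calibration-free and evaluates all supplied data). Inputs are either
#' in-memory simulator outputs (lists with `rec`, `labels`, and for ERP
#' `flashes`) or `list(path =, struct =)` references into an HDF5 container.
#'
#' @param paradigm `"mi"`, `"erp"` or `"ssvep"`.
#' @param train,test input recordings (see above); `test` may be `NULL` for
#'   SSVEP.
#' @param method MI method (ignored otherwise), see [mi_config()].
#' @param downsample_to common analysis rate (default 100 Hz).
#' @param montage channel preset; defaults to the paradigm's standard
#'   subset.
#' @param n_seq ERP sequences evaluated (default 5).
#' @param out_dir optional output directory for CSV/JSON reports.
#' @param seed integer seed recorded in, and used by, the run.
#' @param mi_cfg optional [mi_config()] overriding `method` defaults.
#' @return A list of class `run_config`.
#' @export
run_config <- function(paradigm = c("mi", "erp", "ssvep"), train, test = NULL,
                       method = "csp", downsample_to = 100, montage = NULL,
                       n_seq = 5, out_dir = NULL, seed = 1L, mi_cfg = NULL) {
  paradigm <- match.arg(paradigm)
  if (is.null(montage)) {
    montage <- switch(paradigm, mi = "MI20", erp = "ERP32", ssvep = "SSVEP10")
  }
  structure(list(paradigm = paradigm, train = train, test = test,
                 method = method, downsample_to = downsample_to,
                 montage = montage, n_seq = n_seq, out_dir = out_dir,
                 seed = as.integer(seed), mi_cfg = mi_cfg),
            class = "run_config")
}

# resolve an input spec to list(rec, labels, flashes?)
resolve_input <- function(input) {
  if (is.list(input) && !is.null(input$rec)) return(input)
  if (is.list(input) && !is.null(input$path)) {
    out <- read_recording(input$path, input$struct)
    meta <- out$rec$meta
    if (!is.null(meta$groups)) {
      groups <- meta$groups
      # JSON round-trips a list of equal-length vectors as a matrix
      if (is.matrix(groups)) {
        groups <- lapply(seq_len(nrow(groups)), function(i) groups[i, ])
      }
      n_seq <- length(groups[[1]]) / 12L
      chars <- strsplit(meta$sentence, "")[[1]]
      layout <- speller_layout()
      out$flashes <- purrr::map_dfr(seq_along(groups), function(ci) {
        g <- as.integer(groups[[ci]])
        tibble::tibble(char_idx = ci, target = chars[ci],
                       seq = rep(seq_len(n_seq), each = 12L),
                       flash = rep(1:12, n_seq), group = g,
                       is_target = g %in% symbol_groups(layout, chars[ci]))
      })
      out$flashes$sample <- out$rec$markers$sample
    }
    return(out)
  }
  stop("input must be a simulator output or list(path =, struct =).",
       call. = FALSE)
}

#' Run a full train/test decoding pipeline
#'
#' Applies the paradigm's standard preprocessing (band-pass, decimation to
#' the common analysis rate, montage subset, epoching), trains on the
#' training phase, evaluates on the test phase, and returns a report with a
#' provenance block (seed, configuration hash, package version). With
#' `cfg$out_dir` set, writes `report.json` and per-trial `predictions.csv`.
#'
#' @param cfg a [run_config()].
#' @return A list of class `pipeline_result` with `paradigm`, `report`
#'   (tibble), `predictions` (tibble), `model` and `provenance`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  res <- switch(cfg$paradigm,
                mi = pipeline_mi(cfg),
                erp = pipeline_erp(cfg),
                ssvep = pipeline_ssvep(cfg))
  prov <- list(seed = cfg$seed,
               config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
               package_version = as.character(utils::packageVersion("eegbci")),
               timestamp = format(Sys.time(), tz = "UTC"))
  out <- structure(c(res, list(provenance = prov, paradigm = cfg$paradigm)),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(paradigm = cfg$paradigm, report = out$report, provenance = prov),
      file.path(cfg$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.csv(out$predictions,
                     file.path(cfg$out_dir, "predictions.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> paradigm = %s\n", x$paradigm))
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

# shared preprocessing: band-pass, decimate, montage subset, epoch
preprocess_phase <- function(input, band, target_fs, montage, ival_ms,
                             baseline_ms = NULL) {
  rec <- input$rec
  if (!is.null(band)) rec <- bandpass_filter(rec, band[1], band[2], order = 5)
  if (!is.null(target_fs) && target_fs != rec$fs) {
    rec <- downsample(rec, target_fs)
  }
  rec <- select_channels(rec, montage)
  ep <- segment_epochs(rec, input$labels, ival_ms)
  if (!is.null(baseline_ms)) ep <- baseline_correct(ep, baseline_ms)
  ep
}

pipeline_mi <- function(cfg) {
  mcfg <- cfg$mi_cfg %||% mi_config(cfg$method)
  band <- if (mcfg$method %in% c("csp", "cssp")) mcfg$band_hz else NULL
  ep_tr <- preprocess_phase(resolve_input(cfg$train), band,
                            cfg$downsample_to, cfg$montage, mcfg$ival_ms)
  ep_te <- preprocess_phase(resolve_input(cfg$test), band,
                            cfg$downsample_to, cfg$montage, mcfg$ival_ms)
  model <- train_mi(ep_tr, mcfg, seed = cfg$seed)
  feats <- mi_features(model, ep_te)
  dv <- predict(model$lda, feats, type = "decision")
  pred <- model$classes[ifelse(dv > 0, 2L, 1L)]
  truth <- ep_te$labels$y_class[ep_te$labels$y_dec]
  preds <- tibble::tibble(trial = seq_along(dv), decision = dv,
                          predicted = pred, true = truth)
  preds <- dplyr::bind_cols(preds, tibble::as_tibble(feats))
  list(report = tibble::tibble(method = mcfg$method,
                               accuracy = mean(pred == truth),
                               n_test = length(pred)),
       predictions = preds, model = model)
}

pipeline_erp <- function(cfg) {
  tr <- resolve_input(cfg$train)
  te <- resolve_input(cfg$test)
  ep_tr <- preprocess_phase(tr, c(0.5, 40), cfg$downsample_to, cfg$montage,
                            c(-200, 800), baseline_ms = c(-200, 0))
  ep_te <- preprocess_phase(te, c(0.5, 40), cfg$downsample_to, cfg$montage,
                            c(-200, 800), baseline_ms = c(-200, 0))
  model <- train_erp(ep_tr)
  scores <- predict(model, ep_te)
  fl <- te$flashes
  if (is.null(fl)) stop("ERP test input lacks a per-flash group table.",
                        call. = FALSE)
  truth <- purrr::map_chr(split(fl$target, fl$char_idx), 1)
  score_list <- split(scores, fl$char_idx)
  group_list <- split(fl$group, fl$char_idx)
  acc <- accuracy_by_sequence(truth, score_list, group_list,
                              max_seq = cfg$n_seq)
  soa_s <- 0.215
  acc$itr_bits_min <- purrr::map2_dbl(acc$accuracy, acc$n_seq, function(p, ns) {
    compute_itr(p, 36, 60 / (ns * 12 * soa_s + 0.8))
  })
  pred5 <- purrr::map_chr(seq_along(truth), function(i) {
    decode_speller(score_list[[i]], group_list[[i]], n_seq = cfg$n_seq)
  })
  list(report = acc,
       predictions = tibble::tibble(char_idx = seq_along(truth),
                                    true = truth, predicted = pred5),
       model = model)
}

pipeline_ssvep <- function(cfg) {
  inputs <- list(resolve_input(cfg$train))
  if (!is.null(cfg$test)) inputs <- c(inputs, list(resolve_input(cfg$test)))
  eval_one <- function(input) {
    ep <- preprocess_phase(input, NULL, cfg$downsample_to, cfg$montage,
                           c(0, 4000))
    freqs <- as.numeric(input$labels$y_class)
    ref <- ssvep_reference(freqs, dim(ep$data)[3], ep$fs)
    evaluate_ssvep(ep, ref)
  }
  evals <- lapply(inputs, eval_one)
  report <- purrr::map_dfr(seq_along(evals), function(i) {
    tibble::tibble(phase = i, method = "cca",
                   accuracy = evals[[i]]$accuracy,
                   n_trials = nrow(evals[[i]]$predictions))
  })
  preds <- purrr::map_dfr(seq_along(evals),
                          ~ dplyr::mutate(evals[[.x]]$predictions,
                                          phase = .x))
  list(report = report, predictions = preds,
       model = list(confusions = lapply(evals, `[[`, "confusion")))
}
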