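#' Literacy thresholds per paradigm
#'
#' The categorization thresholds: 70% decoding accuracy for motor imagery
#' and 90% for the ERP and SSVEP paradigms. The MI criterion accuracy is the
#' plain CSP test accuracy. An accuracy exactly equal to the threshold
#' counts as literate (the `>=` rule) -- this boundary convention changes
#' headline rates and is applied uniformly here.
#'
#' @param mi,erp,ssvep thresholds in (0, 1).
#' @param mi_criterion_method method whose accuracy decides MI literacy.
#' @return A list of class `literacy_thresholds`.
#' @export
literacy_thresholds <- function(mi = 0.70, erp = 0.90, ssvep = 0.90,
                                mi_criterion_method = "csp") {
  th <- c(mi = mi, erp = erp, ssvep = ssvep)
  if (any(th <= 0 | th >= 1)) stop("thresholds must lie in (0, 1).",
                                   call. = FALSE)
  structure(list(mi = mi, erp = erp, ssvep = ssvep,
                 mi_criterion_method = mi_criterion_method),
            class = "literacy_thresholds")
}

# keep only the criterion method's rows for MI; other paradigms keep all
criterion_rows <- function(acc, th) {
  acc <- tibble::as_tibble(acc)
  needed <- c("subject", "session", "paradigm", "accuracy")
  miss <- setdiff(needed, names(acc))
  if (length(miss)) {
    stop("accuracy table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(acc$accuracy < 0 | acc$accuracy > 1)) {
    stop("accuracies must lie in [0, 1].", call. = FALSE)
  }
  acc$paradigm <- tolower(acc$paradigm)
  if ("method" %in% names(acc)) {
    acc <- dplyr::filter(acc, .data$paradigm != "mi" |
                           tolower(.data$method) ==
                             tolower(th$mi_criterion_method))
  }
  acc
}

#' Categorize subjects by cross-paradigm BCI literacy
#'
#' A subject is literate in a paradigm iff the criterion accuracy meets the
#' threshold (>=) in *every* session present. Categories over the three
#' paradigms: universally literate (all 3), partially literate (1--2),
#' universally illiterate (0).
#'
#' @param acc tibble with columns `subject`, `session`, `paradigm`
#'   (`"mi"`, `"erp"`, `"ssvep"`), optional `method`, and `accuracy` in
#'   \[0, 1\].
#' @param th a [literacy_thresholds()].
#' @return Tibble: one row per subject with per-paradigm literacy flags,
#'   `n_literate` and `category`.
#' @export
categorize_subjects <- function(acc, th = literacy_thresholds()) {
  acc <- criterion_rows(acc, th)
  th_vec <- c(mi = th$mi, erp = th$erp, ssvep = th$ssvep)
  by_subj <- dplyr::group_by(acc, .data$subject)
  missing_par <- dplyr::summarise(
    by_subj, miss = paste(setdiff(names(th_vec), unique(.data$paradigm)),
                          collapse = ", "), .groups = "drop")
  bad <- missing_par$miss != ""
  if (any(bad)) {
    stop("subject(s) missing paradigm accuracies: ",
         paste(sprintf("%s (%s)", missing_par$subject[bad],
                       missing_par$miss[bad]), collapse = "; "),
         call. = FALSE)
  }
  lit <- acc |>
    dplyr::group_by(.data$subject, .data$paradigm) |>
    dplyr::summarise(literate = all(.data$accuracy >=
                                      th_vec[unique(.data$paradigm)]),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "paradigm", values_from = "literate",
                       names_prefix = "literate_")
  lit |>
    dplyr::mutate(
      n_literate = .data$literate_mi + .data$literate_erp +
        .data$literate_ssvep,
      category = dplyr::case_when(
        .data$n_literate == 3L ~ "universally literate",
        .data$n_literate >= 1L ~ "partially literate",
        TRUE ~ "universally illiterate"))
}

#' Per-paradigm, per-session illiteracy rates and category counts
#'
#' Illiteracy rate = share of subjects strictly below the paradigm threshold
#' in that session; the report also emits the across-session mean rate per
#' paradigm and the literacy-category counts from [categorize_subjects()].
#'
#' @inheritParams categorize_subjects
#' @return List of class `illiteracy_report`: `rates` (paradigm x session
#'   tibble with `n_illiterate`, `n_subjects`, `rate`), `mean_rates`
#'   (per paradigm), `categories` (per subject) and `category_counts`.
#' @export
illiteracy_rates <- function(acc, th = literacy_thresholds()) {
  accf <- criterion_rows(acc, th)
  if (!nrow(accf)) stop("empty accuracy table.", call. = FALSE)
  th_vec <- c(mi = th$mi, erp = th$erp, ssvep = th$ssvep)
  rates <- accf |>
    dplyr::group_by(.data$paradigm, .data$session) |>
    dplyr::summarise(
      n_illiterate = sum(.data$accuracy < th_vec[unique(.data$paradigm)]),
      n_subjects = dplyr::n_distinct(.data$subject),
      rate = .data$n_illiterate / .data$n_subjects, .groups = "drop")
  mean_rates <- rates |>
    dplyr::group_by(.data$paradigm) |>
    dplyr::summarise(mean_rate = mean(.data$rate), .groups = "drop")
  cats <- categorize_subjects(acc, th)
  counts <- dplyr::count(cats, .data$category, name = "n")
  structure(list(rates = rates, mean_rates = mean_rates, categories = cats,
                 category_counts = counts, thresholds = th),
            class = "illiteracy_report")
}

#' @export
print.illiteracy_report <- function(x, ...) {
  cat("<illiteracy_report>\n")
  cat("  per-session illiteracy rates:\n")
  print(as.data.frame(x$rates), row.names = FALSE)
  cat("  categories:\n")
  print(as.data.frame(x$category_counts), row.names = FALSE)
  invisible(x)
}

#' Between-paradigm accuracy correlations
#'
#' Pearson correlation of session-averaged criterion accuracies per subject
#' for each paradigm pair. Pairs with zero variance are reported as `NA`.
#'
#' @inheritParams categorize_subjects
#' @return Tibble `(pair, r, n)`.
#' @export
paradigm_correlations <- function(acc, th = literacy_thresholds()) {
  accf <- criterion_rows(acc, th)
  wide <- accf |>
    dplyr::group_by(.data$subject, .data$paradigm) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "paradigm", values_from = "accuracy")
  if (nrow(wide) < 3) stop("need at least 3 subjects.", call. = FALSE)
  pairs <- list(c("mi", "erp"), c("mi", "ssvep"), c("ssvep", "erp"))
  purrr::map_dfr(pairs, function(pr) {
    a <- wide[[pr[1]]]; b <- wide[[pr[2]]]
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
      stats::cor(a, b)
    tibble::tibble(pair = paste(pr, collapse = "-"), r = r, n = length(a))
  })
}
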