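#' Fit common spatial patterns (CSP)
#'
#' Spatial filters for binary-class oscillatory decoding. With per-class
#' average covariances \eqn{\Sigma_1, \Sigma_2} (trial-wise sample
#' covariances, trace-normalized per trial, then averaged within class), the
#' filters solve the generalized eigenproblem
#' \deqn{\Sigma_1 w = \lambda (\Sigma_1 + \Sigma_2) w,}
#' so eigenvalues lie in \[0, 1\] and measure the share of class-1 variance
#' captured by each filter. The `m` largest and `m` smallest eigenvalues give
#' the retained filter pair set (the "top and bottom rows" of the projection
#' matrix); every filter satisfies \eqn{w^\top(\Sigma_1+\Sigma_2)w = 1}.
#'
#' @param ep an [epoch_set()] with exactly two classes and at least two
#'   trials per class.
#' @param m filter pairs to retain (default 2, giving 4 filters).
#' @param normalize `"trace"` (default) normalizes each trial covariance by
#'   its trace before averaging, the standard robustness device against
#'   amplitude outliers; `"none"` uses raw averaged covariances, which makes
#'   the filters exactly invariant to invertible channel mixing.
#' @return An object of class `csp_filters`: list with `W` (channels x
#'   channels, filters in columns, eigenvalue-descending), `eigvals`,
#'   `selected` (indices of the 2m retained columns) and `channel_names`.
#' @export
fit_csp <- function(ep, m = 2, normalize = c("trace", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(ep, "epoch_set"))
  n_cls <- length(ep$labels$y_class)
  if (n_cls != 2L) {
    stop("CSP supports exactly 2 classes; got ", n_cls, ".", call. = FALSE)
  }
  counts <- tabulate(ep$labels$y_dec, 2)
  if (any(counts < 2L)) stop("need >= 2 trials per class.", call. = FALSE)
  n_ch <- dim(ep$data)[2]
  if (n_ch < 2 * m) stop("need at least 2*m channels.", call. = FALSE)
  S1 <- class_cov(ep, 1L, normalize)
  S2 <- class_cov(ep, 2L, normalize)
  fit_csp_from_cov(S1, S2, m, ep$channel_names)
}

# class-average covariance with per-trial trace normalization
class_cov <- function(ep, cls, normalize = "trace") {
  idx <- which(ep$labels$y_dec == cls)
  n_ch <- dim(ep$data)[2]
  S <- matrix(0, n_ch, n_ch)
  for (i in idx) {
    X <- ep$data[i, , ]                      # channels x samples
    X <- X - rowMeans(X)
    C <- tcrossprod(X) / (ncol(X) - 1)
    S <- S + if (normalize == "trace") C / sum(diag(C)) else C
  }
  S / length(idx)
}

# core eigensolver shared by CSP and CSSP: whiten the composite covariance,
# then diagonalize the whitened class-1 covariance; ridge when ill-conditioned
fit_csp_from_cov <- function(S1, S2, m, channel_names) {
  Sc <- S1 + S2
  e <- eigen(Sc, symmetric = TRUE)
  tol <- 1e-10 * max(e$values)
  if (min(e$values) < tol) {
    warning("composite covariance is rank-deficient; ridge applied.")
    Sc <- Sc + diag(1e-8 * sum(diag(Sc)), nrow(Sc))
    e <- eigen(Sc, symmetric = TRUE)
  }
  Wht <- e$vectors %*% diag(1 / sqrt(e$values)) # whitening: Wht' Sc Wht = I
  Sw <- crossprod(Wht, S1 %*% Wht)
  Sw <- (Sw + t(Sw)) / 2
  ew <- eigen(Sw, symmetric = TRUE)             # eigvals descending
  W <- Wht %*% ew$vectors
  eigvals <- pmin(pmax(ew$values, 0), 1)
  n_ch <- nrow(W)
  selected <- c(seq_len(m), seq.int(n_ch - m + 1L, n_ch))
  structure(list(W = W, eigvals = eigvals, selected = selected,
                 channel_names = channel_names, m = m),
            class = "csp_filters")
}

#' @export
print.csp_filters <- function(x, ...) {
  cat(sprintf("<csp_filters> %d channels, %d retained filters (m=%d)\n",
              nrow(x$W), length(x$selected), x$m))
  cat("  retained eigenvalues:",
      paste(sprintf("%.3f", x$eigvals[x$selected]), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_csp
#' @param x a fitted `csp_filters` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.csp_filters <- function(x, ...) {
  tibble::tibble(filter = seq_along(x$eigvals),
                 eigenvalue = x$eigvals,
                 selected = seq_along(x$eigvals) %in% x$selected)
}

#' Log-variance features from spatially filtered epochs
#'
#' Projects each epoch through the retained CSP filters and takes the log of
#' the per-filter variance over time: the standard feature for oscillatory
#' power decoding. Unnormalized (no division by total variance); the LDA
#' stage absorbs affine scaling.
#'
#' @param ep an [epoch_set()] on the channel set the bank was fitted on.
#' @param bank a `csp_filters` object from [fit_csp()].
#' @return Numeric matrix, trials x `length(bank$selected)`.
#' @export
logvar_features <- function(ep, bank) {
  stopifnot(inherits(ep, "epoch_set"), inherits(bank, "csp_filters"))
  Wsel <- bank$W[, bank$selected, drop = FALSE]
  n_tr <- dim(ep$data)[1]
  out <- matrix(NA_real_, n_tr, ncol(Wsel))
  for (i in seq_len(n_tr)) {
    P <- crossprod(Wsel, ep$data[i, , ])     # filters x samples
    v <- apply(P, 1, stats::var)
    if (any(v <= 0)) {
      warning("zero-variance projection; floored at machine epsilon.")
      v <- pmax(v, .Machine$double.eps)
    }
    out[i, ] <- log(v)
  }
  colnames(out) <- paste0("csp", bank$selected)
  out
}

#' Fisher linear discriminant with optional covariance shrinkage
#'
#' Binary LDA on feature vectors: \eqn{w \propto \Sigma^{-1}(\mu_2-\mu_1)}
#' with the pooled within-class covariance \eqn{\Sigma}, bias set so the
#' decision value is zero at the midpoint of the class means. Positive
#' decision values vote for class 2. Shrinkage replaces \eqn{\Sigma} by
#' \eqn{(1-\lambda)\Sigma + \lambda \nu I} with \eqn{\nu} the average
#' eigenvalue; `shrinkage = "auto"` uses the Ledoit-Wolf analytic estimate,
#' the stabilizer of choice for high-dimensional mean-amplitude features.
#'
#' @param X numeric feature matrix, trials x features.
#' @param y class labels with exactly two levels (integer 1/2, factor, or
#'   character); class order follows `sort(unique(y))`.
#' @param shrinkage `0` (plain LDA), a value in \[0,1\], or `"auto"`.
#' @return An object of class `lda_model` with `w`, `b`, `shrinkage`,
#'   `classes` and training decision-value spread `dv_sd`.
#' @export
fit_lda <- function(X, y, shrinkage = 0) {
  X <- as.matrix(X)
  cls <- sort(unique(y))
  if (length(cls) != 2L) stop("LDA needs exactly two classes.", call. = FALSE)
  i1 <- which(y == cls[1]); i2 <- which(y == cls[2])
  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu2 <- colMeans(X[i2, , drop = FALSE])
  X1 <- sweep(X[i1, , drop = FALSE], 2, mu1)
  X2 <- sweep(X[i2, , drop = FALSE], 2, mu2)
  n <- nrow(X)
  S <- (crossprod(X1) + crossprod(X2)) / (n - 2)
  lambda <- if (identical(shrinkage, "auto")) {
    ledoit_wolf_lambda(rbind(X1, X2)) } else as.numeric(shrinkage)
  if (lambda < 0 || lambda > 1) stop("shrinkage must lie in [0,1].", call. = FALSE)
  p <- ncol(X)
  nu <- sum(diag(S)) / p
  St <- (1 - lambda) * S + lambda * nu * diag(p)
  w <- tryCatch(solve(St, mu2 - mu1), error = function(e) {
    stop("singular pooled covariance; refit with shrinkage > 0 ",
         "(e.g. shrinkage = \"auto\").", call. = FALSE)
  })
  b <- -sum(w * (mu1 + mu2) / 2)
  dv <- as.numeric(X %*% w + b)
  structure(list(w = as.numeric(w), b = b, shrinkage = lambda,
                 classes = cls, dv_sd = stats::sd(dv),
                 feature_names = colnames(X)),
            class = "lda_model")
}

# Ledoit-Wolf analytic shrinkage intensity toward nu*I, on centered data
ledoit_wolf_lambda <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  nu <- sum(diag(S)) / p
  d2 <- sum((S - nu * diag(p))^2)
  b2 <- 0
  for (i in seq_len(n)) {
    xi <- Xc[i, ]
    b2 <- b2 + sum((tcrossprod(xi) - S)^2)
  }
  b2 <- min(b2 / n^2, d2)
  if (d2 <= 0) return(0)
  min(1, max(0, b2 / d2))
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d features, shrinkage lambda = %.3f, classes: %s vs %s\n",
              length(x$w), x$shrinkage, x$classes[1], x$classes[2]))
  invisible(x)
}

#' Decision values / class predictions from a fitted LDA
#'
#' @param object an `lda_model`.
#' @param newdata feature matrix, trials x features.
#' @param type `"decision"` for raw decision values (positive = class 2),
#'   `"class"` for hard labels.
#' @param ... unused.
#' @return Numeric vector of decision values, or a vector of class labels.
#' @export
predict.lda_model <- function(object, newdata, type = c("decision", "class"),
                              ...) {
  type <- match.arg(type)
  dv <- as.numeric(as.matrix(newdata) %*% object$w + object$b)
  if (type == "decision") return(dv)
  object$classes[ifelse(dv > 0, 2L, 1L)]
}

#' @rdname fit_lda
#' @param x a fitted `lda_model`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.lda_model <- function(x, ...) {
  nm <- x$feature_names %||% paste0("f", seq_along(x$w))
  tibble::tibble(term = c(nm, "(bias)"), estimate = c(x$w, x$b))
}

#' @rdname fit_lda
#' @exportS3Method generics::glance
glance.lda_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$w), shrinkage = x$shrinkage,
                 dv_sd = x$dv_sd)
}
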