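#' ROC analysis with Youden-index cut-off
#'
#' Computes the area under the ROC curve by the rank (Mann-Whitney)
#' statistic with midranks for ties, then scans every observed marker value
#' as a candidate cut-off with the orientation "marker >= cut-off calls an
#' event" (high marker = high risk). The returned cut-off maximises the
#' Youden index J = sensitivity + specificity - 1; ties are broken toward
#' the smallest cut-off.
#'
#' @param marker numeric per-patient marker values.
#' @param event 0/1 (or logical) event indicators; both classes must be
#'   present.
#' @return An object of class `roc_result`: `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `youden`, and `curve` (a data frame with one row per
#'   candidate cut-off: `threshold`, `sensitivity`, `specificity`).
#' @examples
#' r <- roc_youden(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' c(r$auc, r$cutoff)  # perfect separation: AUC 1 at cut-off 3
#' @export
roc_youden <- function(marker, event) {
  marker <- as.numeric(marker)
  event <- as.integer(as.logical(event))
  if (length(marker) != length(event))
    stop("'marker' and 'event' lengths differ", call. = FALSE)
  if (anyNA(marker) || anyNA(event))
    stop("missing values are not allowed", call. = FALSE)
  n1 <- sum(event == 1L); n0 <- sum(event == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("degenerate input: both event classes must be present",
         call. = FALSE)

  r <- rank(marker)                          # midranks for ties
  auc <- (sum(r[event == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  cuts <- sort(unique(marker))
  sens <- vapply(cuts, function(cc) mean(marker[event == 1L] >= cc),
                 numeric(1L))
  spec <- vapply(cuts, function(cc) mean(marker[event == 0L] < cc),
                 numeric(1L))
  J <- sens + spec - 1
  # ties (including float-level ones) resolve to the smallest cut-off;
  # cuts are ascending so the first qualifying index wins
  best <- which(J >= max(J) - 1e-12)[1L]
  structure(list(auc = auc, cutoff = cuts[best],
                 sensitivity = sens[best], specificity = spec[best],
                 youden = J[best],
                 curve = data.frame(threshold = cuts, sensitivity = sens,
                                    specificity = spec)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f; Youden cut-off %.4g (sens %.1f%%, spec %.1f%%)\n",
    x$auc, x$cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Validates the inputs (n >= 3, non-zero variances) and returns the
#' standard product-moment coefficient.
#'
#' @param x,y numeric vectors of equal length.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("at least 3 observations required", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: a variable has zero variance",
         call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' Variance inflation factors
#'
#' For each column j, VIF_j = 1 / (1 - R^2_j) where R^2_j comes from the
#' least-squares regression of column j on all other columns plus an
#' intercept. Exact collinearity yields `Inf`, not an error.
#'
#' @param x numeric data frame or matrix with at least two non-constant
#'   columns and more rows than columns.
#' @return Named numeric vector of VIFs (always >= 1, up to rounding).
#' @examples
#' set.seed(1)
#' vif(data.frame(a = rnorm(50), b = rnorm(50)))
#' @export
vif <- function(x) {
  X <- as.data.frame(x)
  X[] <- lapply(X, as.numeric)
  p <- ncol(X); n <- nrow(X)
  if (p < 2L) stop("at least two columns required", call. = FALSE)
  if (n <= p) stop("need more rows than columns", call. = FALSE)
  if (any(vapply(X, stats::sd, numeric(1L)) == 0))
    stop("constant column(s) present", call. = FALSE)
  v <- vapply(seq_len(p), function(j) {
    fit <- stats::lm(X[[j]] ~ ., data = X[, -j, drop = FALSE])
    # an exactly collinear column triggers a perfect-fit warning; the VIF
    # contract maps that case to Inf
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  stats::setNames(v, colnames(X))
}

#' Intraclass correlation, two-way random, absolute agreement, single
#' measures
#'
#' ICC(2,1) from the two-way ANOVA decomposition for an n-subjects by
#' k-raters complete table:
#' (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n),
#' where MSR, MSC and MSE are the subject, rater and residual mean squares.
#' Systematic rater offsets therefore lower the coefficient (absolute
#' agreement, not consistency).
#'
#' @param ratings numeric matrix or data frame, n subjects x k raters
#'   (k >= 2), complete (no missing cells), n >= 3.
#' @return The ICC(2,1) estimate.
#' @examples
#' set.seed(1); a <- rnorm(20, 10, 3)
#' icc_agreement(cbind(a, a + rnorm(20, 0, 0.1)))
#' @export
icc_agreement <- function(ratings) {
  M <- as.matrix(ratings)
  storage.mode(M) <- "double"
  n <- nrow(M); k <- ncol(M)
  if (k < 2L) stop("at least two raters required", call. = FALSE)
  if (n < 3L) stop("at least three subjects required", call. = FALSE)
  if (anyNA(M))
    stop("incomplete design: every subject needs a rating from every rater",
         call. = FALSE)
  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
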