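#' Bland-Altman agreement analysis
#'
#' Bias (mean of paired differences a - b) and limits of agreement
#' bias +/- 1.96 * SD of the differences (sample SD, n - 1 denominator),
#' for intra-/inter-observer or inter-modality comparison of paired
#' measurements.
#'
#' @param a,b equal-length numeric vectors of paired measurements.
#' @return A list of class `bland_altman` with `bias`, `loa_half_width`,
#'   `loa` (lower, upper), `differences`, `means`, `n`.
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 2L || anyNA(a) || anyNA(b))
    p4d_stop("need >= 2 complete pairs of equal length", "p4d_invalid_argument")
  d <- a - b
  bias <- mean(d)
  hw <- 1.96 * sd(d)
  structure(list(bias = bias, loa_half_width = hw,
                 loa = c(lower = bias - hw, upper = bias + hw),
                 differences = d, means = (a + b) / 2, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d  bias=%.4g  LOA = bias +/- %.4g\n",
              x$n, x$bias, x$loa_half_width))
  invisible(x)
}

#' Two-way intra-class correlation coefficient
#'
#' ICC from a two-way ANOVA decomposition of a subjects x raters matrix.
#' `ICC2_1` is the two-way random-effects, absolute-agreement, single-rater
#' form (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n); `ICC3_1` is the
#' two-way mixed, consistency form (MSR - MSE) / (MSR + (k-1) MSE). An ICC
#' greater than 0.75 is flagged as good agreement.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns,
#'   no missing cells.
#' @param form `"ICC2_1"` (default) or `"ICC3_1"`.
#' @return A list of class `icc_result` with `icc`, `form`, `good_agreement`
#'   (strictly greater than 0.75) and the mean squares.
#' @export
icc_two_way <- function(ratings, form = c("ICC2_1", "ICC3_1")) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L || anyNA(ratings))
    p4d_stop("need >= 2 subjects, >= 2 raters, no missing cells",
             "p4d_invalid_argument")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  if (ss_total == 0)
    p4d_stop("zero total variance: ICC undefined", "p4d_undefined_icc")
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)              # between-subjects
  msc <- ss_cols / (k - 1)              # between-raters
  mse <- ss_err / ((n - 1) * (k - 1))   # residual
  icc <- switch(form,
    ICC2_1 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    ICC3_1 = (msr - mse) / (msr + (k - 1) * mse))
  structure(list(icc = icc, form = form, good_agreement = icc > 0.75,
                 ms = c(MSR = msr, MSC = msc, MSE = mse), n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s = %.4f (%s agreement; n=%d subjects, k=%d raters)\n",
              x$form, x$icc, if (x$good_agreement) "good" else "not good",
              x$n, x$k))
  invisible(x)
}

#' Spearman rank correlation of paired measurements
#'
#' Pearson correlation of mid-ranks (ties averaged), via
#' `stats::cor(method = "spearman")`.
#'
#' @param a,b equal-length numeric vectors, n >= 3.
#' @return Scalar correlation in [-1, 1].
#' @export
spearman_corr <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 3L)
    p4d_stop("need >= 3 pairs of equal length", "p4d_invalid_argument")
  if (sd(a) == 0 || sd(b) == 0)
    p4d_stop("constant vector: correlation undefined", "p4d_undefined_correlation")
  cor(a, b, method = "spearman")
}

#' Two-sided Welch t-test on two independent samples
#'
#' Used e.g. to compare segmentation times between post-processing methods;
#' the same test backs [pulsation_test()].
#'
#' @param sample_a,sample_b numeric vectors, n >= 2 each.
#' @return List with `t`, `p`, `mean_a`, `mean_b`, `df`.
#' @export
two_sided_ttest <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) < 2L || length(b) < 2L)
    p4d_stop("both samples must have n >= 2", "p4d_invalid_argument")
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = 0, p = if (eq) 1 else 0, mean_a = mean(a), mean_b = mean(b),
                df = NA_real_))
  }
  tt <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value, mean_a = mean(a),
       mean_b = mean(b), df = unname(tt$parameter))
}
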