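# Interrater agreement statistics: ICC(2,1) with F-based confidence
# intervals, Bland-Altman limits of agreement, Dice coefficients, and the
# paired t-test on logit-transformed Dice.

#' Two-way random-effects single-rater ICC for absolute agreement, ICC(2,1)
#'
#' Decomposes the n x k rating matrix by two-way ANOVA (rows = exams,
#' columns = raters) and returns
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)),
#' with a 95% confidence interval by the McGraw-Wong F-distribution method
#' and the conventional interpretation label: below 0.5 poor, 0.5-0.75
#' moderate, 0.75-0.9 good, above 0.9 excellent.
#'
#' @param m numeric matrix, n exams (rows, n >= 3) by k raters (k >= 2),
#'   no missing cells
#' @param conf_level confidence level (default 0.95)
#' @return list: `estimate`, `ci` (lo, hi), `label`, and the mean squares
#' @export
icc_2_1 <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L) stop("need >= 3 exams and >= 2 raters")
  if (anyNA(m)) stop("rating matrix has missing cells")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_tot <= 0) stop("no variance in ratings; ICC undefined")
  est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level
  # McGraw & Wong F-based interval for ICC(2,1)
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  label <- if (est < 0.5) "poor" else if (est <= 0.75) "moderate"
    else if (est <= 0.9) "good" else "excellent"
  list(estimate = est, ci = c(lo = lo, hi = hi), label = label,
       msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Bland-Altman difference analysis
#'
#' Mean difference of `x - y` with 95% limits of agreement
#' mean +/- 1.96 x sd (sample sd, n-1 denominator).
#'
#' @param x,y paired measurement vectors (mL), equal length >= 2
#' @return list: `mean_diff`, `loa` (lo, hi), `sd_diff`, `n`
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("need paired vectors of equal length >= 2")
  d <- x - y
  md <- mean(d)
  s <- sd(d)
  list(mean_diff = md, loa = c(lo = md - 1.96 * s, hi = md + 1.96 * s),
       sd_diff = s, n = length(d))
}

#' Dice similarity coefficient of two masks
#'
#' 2|A and B| / (|A| + |B|). Two empty masks score 1 (agreement on
#' absence), with a note attribute recording the convention.
#'
#' @param a,b logical arrays of identical shape
#' @return DSC in \[0, 1\]
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("geometry mismatch between masks")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    out <- 1
    attr(out, "note") <- "both masks empty; DSC defined as 1"
    return(out)
  }
  2 * sum(a & b) / (na + nb)
}

#' Logit transform
#'
#' ln(v / (1 - v)), mapping (0, 1) onto the real line. Values at exactly 0
#' or 1 are an error unless `clamp = TRUE`, in which case they are clamped
#' to \[eps, 1 - eps\] and a message records the clamping.
#'
#' @param v values in (0, 1)
#' @param clamp clamp boundary values instead of erroring? Default `FALSE`
#' @param eps clamp width (default 1e-6)
#' @return logit-transformed values
#' @export
logit <- function(v, clamp = FALSE, eps = 1e-6) {
  if (any(v < 0 | v > 1)) stop("logit requires values in [0, 1]")
  at_edge <- v <= 0 | v >= 1
  if (any(at_edge)) {
    if (!clamp)
      stop("logit undefined at 0 or 1; pass clamp = TRUE for an explicit ",
           "epsilon-clamp policy")
    message(sum(at_edge), " value(s) clamped to [", eps, ", ", 1 - eps,
            "] before logit")
    v <- pmin(pmax(v, eps), 1 - eps)
  }
  log(v / (1 - v))
}

#' Paired t-test on logit-transformed Dice coefficients
#'
#' Logit-transforms both per-exam DSC vectors and runs a standard two-sided
#' paired t-test (df = n - 1).
#'
#' @param dsc_method1,dsc_method2 per-exam DSC vectors in (0, 1), paired by
#'   exam, length >= 2
#' @param clamp forwarded to [logit()] for boundary values
#' @return list: `t`, `df`, `p`, `mean_diff_logit`
#' @export
paired_t_logit_dsc <- function(dsc_method1, dsc_method2, clamp = FALSE) {
  if (length(dsc_method1) != length(dsc_method2) || length(dsc_method1) < 2L)
    stop("need paired DSC vectors of equal length >= 2")
  l1 <- logit(dsc_method1, clamp = clamp)
  l2 <- logit(dsc_method2, clamp = clamp)
  d <- l1 - l2
  if (sd(d) <= 1e-10 * max(1, abs(mean(d))))
    stop("zero variance of paired logit differences; t undefined")
  tt <- t.test(l1, l2, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff_logit = unname(tt$estimate))
}

#' Aggregate agreement report
#'
#' Combines the component statistics for a set of rated exams: ICC(2,1)
#' with CI and label on the rating matrix, Bland-Altman on its two rater
#' columns, and the per-exam Dice distribution for a list of segmentation
#' mask pairs (with optional paired t on logit DSC against a second
#' method's DSC vector).
#'
#' @param ratings n x 2 matrix of per-exam secretory responses by rater
#' @param mask_pairs optional list of 2-element lists of logical masks
#'   (one pair per exam)
#' @param dsc_reference optional per-exam DSC vector of a comparison
#'   method, paired with the mask pairs, for the logit t-test
#' @return an `agreement_report` list
#' @export
build_report <- function(ratings, mask_pairs = NULL, dsc_reference = NULL) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) != 2L) stop("ratings must have exactly 2 rater columns")
  icc <- icc_2_1(ratings)
  ba <- bland_altman(ratings[, 1], ratings[, 2])
  out <- list(icc = icc, ba = ba, dsc = NULL, logit_t = NULL)
  if (!is.null(mask_pairs)) {
    dscs <- vapply(mask_pairs,
                   function(p) as.numeric(dice(p[[1]], p[[2]])), numeric(1))
    out$dsc <- list(values = dscs, mean = mean(dscs), sd = sd(dscs))
    if (!is.null(dsc_reference))
      out$logit_t <- paired_t_logit_dsc(dscs, dsc_reference, clamp = TRUE)
  }
  structure(out, class = "agreement_report")
}
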