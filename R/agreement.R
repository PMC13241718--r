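# Repeatability and method-agreement statistics for paired scar-mass series.
# Differences are oriented first argument minus second throughout.

check_pairs <- function(x, y, min_n = 2) {
  if (length(x) != length(y)) stop("series must have equal length", call. = FALSE)
  if (length(x) < min_n) stop(sprintf("need at least %d pairs", min_n), call. = FALSE)
  invisible(TRUE)
}

#' Bland-Altman analysis
#'
#' Bias (mean of `x - y`), SD of differences (sample, n-1), and 95% limits
#' of agreement `bias +/- 1.96 sd`.
#'
#' @param x,y paired measurement series.
#' @return list with `bias`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(x, y) {
  check_pairs(x, y)
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       n = length(d))
}

#' Lin's concordance correlation coefficient
#'
#' `2 s_xy / (s_x^2 + s_y^2 + (mean x - mean y)^2)` with population (1/n)
#' moments.
#'
#' @param x,y paired series (n >= 2, not both constant with equal means).
#' @return CCC in `[-1, 1]`, or `NA` when undefined.
#' @export
ccc <- function(x, y) {
  check_pairs(x, y)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- sx2 + sy2 + (mx - my)^2
  if (den == 0) return(NA_real_)
  2 * sxy / den
}

#' Intraclass correlation coefficient (two-way random, absolute agreement)
#'
#' Computed from the mean squares of the subject x rater two-way table:
#' single-measure ICC(A,1) or average-measure ICC(A,k).
#'
#' @param x,y paired series, one column per rater (k = 2).
#' @param form "two_way_random_absolute_single" or
#'   "two_way_random_absolute_average".
#' @return ICC, or `NA` when the mean squares are degenerate.
#' @export
icc <- function(x, y, form = c("two_way_random_absolute_single",
                               "two_way_random_absolute_average")) {
  form <- match.arg(form)
  check_pairs(x, y, min_n = 3)
  dat <- cbind(x, y)
  n <- nrow(dat); k <- ncol(dat)
  grand <- mean(dat)
  row_m <- rowMeans(dat); col_m <- colMeans(dat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- if (form == "two_way_random_absolute_single") {
    msr + (k - 1) * mse + (k / n) * (msc - mse)
  } else {
    msr + (msc - mse) / n
  }
  if (!is.finite(den) || den == 0) return(NA_real_)
  (msr - mse) / den
}

#' Within-subject coefficient of variation (root-mean-square method), percent
#'
#' `100 * sqrt( mean(d_i^2 / 2) ) / grand mean` with `d_i = x_i - y_i`.
#'
#' @param x,y paired positive-valued series.
#' @return CV in percent, or `NA` if the grand mean is not positive.
#' @export
cv_pct <- function(x, y) {
  check_pairs(x, y, min_n = 1)
  gm <- mean(c(x, y))
  if (gm <= 0) return(NA_real_)
  100 * sqrt(mean((x - y)^2 / 2)) / gm
}

#' Two-tailed paired t-test for systematic bias
#'
#' `t = bias / (sd_diff / sqrt(n))` with `n - 1` degrees of freedom.
#'
#' @param x,y paired series.
#' @return list with `t`, `p`, `df`; `t` is `NA` when the differences have
#'   zero SD.
#' @export
paired_t <- function(x, y) {
  check_pairs(x, y)
  d <- x - y
  s <- sd(d)
  n <- length(d)
  if (s == 0) return(list(t = NA_real_, p = NA_real_, df = n - 1))
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1), df = n - 1)
}

#' Pearson correlation of two series
#' @param x,y paired series.
#' @return r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  check_pairs(x, y)
  cor(x, y)
}

#' Bonett sample size for an ICC confidence interval
#'
#' Closed form `ceil( 8 z^2 (1 - rho)^2 (1 + (k-1) rho)^2 /
#' (k (k-1) w^2) + 1 )` for the number of subjects needed so that the
#' two-sided `1 - alpha` confidence interval for an ICC near `rho` with `k`
#' raters has width about `w` (Bonett 2002).
#'
#' @param rho expected ICC in (0, 1).
#' @param width desired CI width (> 0).
#' @param k number of raters (>= 2).
#' @param alpha two-sided error rate (default 0.05).
#' @return integer sample size.
#' @export
bonett_n <- function(rho, width, k = 2, alpha = 0.05) {
  stopifnot_scalar_num(rho, "rho", lo = 0, hi = 1, strict_lo = TRUE)
  if (rho >= 1) stop("`rho` must be below 1", call. = FALSE)
  stopifnot_scalar_num(width, "width", lo = 0, strict_lo = TRUE)
  stopifnot_scalar_num(k, "k", lo = 2)
  z <- qnorm(1 - alpha / 2)
  n <- 8 * z^2 * (1 - rho)^2 * (1 + (k - 1) * rho)^2 / (k * (k - 1) * width^2) + 1
  max(2L, as.integer(ceiling(n)))
}

#' Full agreement report for two paired measurement series
#'
#' Bundles Bland-Altman bias and limits of agreement, Pearson r, Lin's CCC,
#' single- and average-measure ICC, the within-subject CV, and the paired
#' t-test. Differences are `x - y`.
#'
#' @param x,y paired series (e.g. scar mass in grams from two raters).
#' @return object of class `agreement_report` (a list).
#' @export
agreement_report <- function(x, y) {
  ba <- bland_altman(x, y)
  tt <- paired_t(x, y)
  structure(list(n = ba$n,
                 bias = ba$bias, sd_diff = ba$sd_diff,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 pearson_r = pearson_r(x, y),
                 ccc = ccc(x, y),
                 icc_single = icc(x, y, "two_way_random_absolute_single"),
                 icc_average = icc(x, y, "two_way_random_absolute_average"),
                 cv_pct = cv_pct(x, y),
                 t_stat = tt$t, p_value = tt$p,
                 orientation = "first minus second"),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report (differences:", x$orientation, ")\n")
  cat(sprintf("  n pairs        : %d\n", x$n))
  cat(sprintf("  bias           : %.4f\n", x$bias))
  cat(sprintf("  SD of diffs    : %.4f\n", x$sd_diff))
  cat(sprintf("  95%% LoA        : [%.4f, %.4f]\n", x$loa_low, x$loa_high))
  cat(sprintf("  Pearson r      : %.4f\n", x$pearson_r))
  cat(sprintf("  Lin's CCC      : %.4f\n", x$ccc))
  cat(sprintf("  ICC (single)   : %.4f\n", x$icc_single))
  cat(sprintf("  ICC (average)  : %.4f\n", x$icc_average))
  cat(sprintf("  CV %%           : %.2f\n", x$cv_pct))
  cat(sprintf("  paired t, p    : %.4f, %.4g\n", x$t_stat, x$p_value))
  invisible(x)
}
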