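#' Intraclass correlation coefficient ICC(2,1) with 95% CI
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' two-way ANOVA mean squares (rows = subjects, columns = raters):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The confidence interval uses the F-distribution construction for
#' ICC(2,1) (Shrout-Fleiss / McGraw-Wong) with a Satterthwaite
#' approximation for the denominator degrees of freedom. Absolute
#' agreement penalizes a systematic between-rater offset, so a pure offset
#' yields ICC strictly below 1, while adding a common constant to every
#' cell leaves the ICC unchanged.
#'
#' @param ratings Numeric matrix, subjects x raters (n >= 3 rows for the
#'   CI, k >= 2 columns, no missing cells).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `icc_result`: `icc`, `ci_low`, `ci_high`, `n`,
#'   `k`. All `NA` when the total variance is zero (ICC undefined).
#' @examples
#' icc21(cbind(c(1, 3, 5), c(2, 4, 6)))
#' @export
icc21 <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (any(is.na(m))) stop("ratings must have no missing cells", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) stop("ICC confidence interval requires at least 3 subjects",
                  call. = FALSE)
  if (k < 2) stop("at least 2 raters required", call. = FALSE)

  gm <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - gm)^2)
  ssc <- n * sum((col_means - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (sst == 0 || denom == 0) {
    return(structure(list(icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, n = n, k = k),
                     class = "icc_result"))
  }
  r <- (msr - mse) / denom

  alpha <- 1 - conf_level
  a <- (k * r) / (n * (1 - r))
  b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
  ci <- if (!is.finite(a) || !is.finite(b) || mse == 0) {
    c(NA_real_, NA_real_)  # perfect agreement: no residual variance to test
  } else {
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    c(n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr),
      n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr))
  }
  structure(list(icc = r, ci_low = ci[1], ci_high = ci[2], n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (is.na(x$icc)) {
    cat("ICC(2,1): undefined (zero total variance)\n")
  } else {
    cat(sprintf("ICC(2,1) = %.3f (%.3f-%.3f), n = %d subjects, k = %d raters\n",
                x$icc, x$ci_low, x$ci_high, x$n, x$k))
  }
  invisible(x)
}

#' Bland-Altman agreement between two paired measurements
#'
#' Differences are taken as `x - y` (first minus second): pass the
#' bright-blood extents first and the dark-blood extents second so that a
#' positive bias means the dark arm underestimates. Bias is the mean
#' difference; limits of agreement are `bias +/- 1.96 SD` of the
#' differences (sample SD, n - 1 divisor).
#'
#' @param x,y Paired numeric vectors (n >= 2).
#' @param loa_mult Limits-of-agreement multiplier (1.96 for 95%).
#' @return Object of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, plus the per-pair `means` and `diffs` for plotting.
#' @examples
#' bland_altman(c(10, 10), c(9, 7)) # bias 2, sd sqrt(2)
#' @export
bland_altman <- function(x, y, loa_mult = 1.96) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("Bland-Altman requires at least 2 pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_d,
                 loa_low = bias - loa_mult * sd_d,
                 loa_high = bias + loa_mult * sd_d,
                 n = length(d), means = (x + y) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, SD %.3f, 95%% LoA [%.3f, %.3f], n = %d\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Mean-difference scatter with bias and limits-of-agreement lines.
#'
#' @param ba A [bland_altman()] result.
#' @param xlab,ylab,main Plot annotation.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `ba`.
#' @export
plot_bland_altman <- function(ba, xlab = "Mean of methods (%LV)",
                              ylab = "Difference (%LV)",
                              main = "Bland-Altman", ...) {
  stopifnot(inherits(ba, "bland_altman"))
  graphics::plot(ba$means, ba$diffs, xlab = xlab, ylab = ylab, main = main,
                 pch = 19, ...)
  graphics::abline(h = ba$bias, lty = 1)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  invisible(ba)
}

#' Ordinary least-squares regression of one extent series on another
#'
#' Fits `y = slope * x + intercept` by OLS via [stats::lm()] and reports
#' the squared Pearson correlation as R^2. Used to compare in-vivo against
#' ex-vivo IMH extents.
#'
#' @param x,y Numeric vectors (n >= 3, `var(x) > 0`).
#' @return List: `slope`, `intercept`, `r_squared`, `n`.
#' @export
extent_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("regression requires at least 3 points", call. = FALSE)
  if (stats::var(x) == 0) stop("`x` has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 0 else stats::cor(x, y)^2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = length(x))
}
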