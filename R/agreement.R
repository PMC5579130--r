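# Agreement statistics: Lin's concordance correlation coefficient with an
# asymptotic confidence interval, agreement slope/intercept, and the
# supporting classical tests (Shapiro-Wilk + paired t, Pearson).

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2*cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments — Lin's original estimator. Measures agreement
#' with the identity line, combining precision (Pearson correlation) and
#' accuracy (bias from the 45-degree line); `|CCC| <= |r|` always. The 95 %
#' confidence interval uses the Fisher z-transformation of the CCC with
#' Lin's asymptotic variance. The slope and intercept are the ordinary
#' least-squares regression of `y` on `x` (conventionally y =
#' computational, x = experimental values).
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with non-zero
#'   variance.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `agreement_result` with fields `ccc`,
#'   `ci95_low`, `ci95_high`, `slope`, `intercept`, `pearson`, `n`.
#' @export
lin_ccc <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 || sy2 == 0)
    stop("degenerate data: zero variance in `x` or `y`")
  sxy <- mean((x - mx) * (y - my))
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)

  # Lin (1989, corr. 2000) asymptotic variance of the z-transformed CCC
  u <- (mx - my) / sqrt(sqrt(sx2 * sy2))
  if (abs(r) < 1e-12 || abs(ccc) >= 1 - 1e-12 || n < 4) {
    lo <- hi <- ccc
  } else {
    s2z <- ((1 - r^2) * ccc^2 * (1 - ccc^2) / r^2 +
              2 * ccc^3 * (1 - ccc) * u^2 / r -
              ccc^4 * u^4 / (2 * r^2)) / (n - 2)
    s2z <- max(s2z, 0)
    z <- atanh(ccc)
    q <- qnorm(1 - (1 - conf) / 2)
    lo <- tanh(z - q * sqrt(s2z))
    hi <- tanh(z + q * sqrt(s2z))
  }
  fit <- lm(y ~ x)
  structure(list(ccc = ccc, ci95_low = lo, ci95_high = hi,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 pearson = r, n = n),
            class = "agreement_result")
}

#' @exportS3Method base::print
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "CCC %.3f (%.3f-%.3f), slope %.2f, intercept %.3g, n = %d\n",
    x$ccc, x$ci95_low, x$ci95_high, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Paired t-test with Shapiro-Wilk normality check
#'
#' Shapiro-Wilk test on the paired differences followed by a two-sided
#' paired Student t-test, the combination used throughout for comparing
#' repeat measurement states.
#'
#' @param a,b Paired numeric vectors of equal length `n >= 3`.
#' @return List with `shapiro_p`, `t_p`, `t_stat`, `mean_diff`, `n`.
#' @export
paired_t_and_normality <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have the same length")
  if (length(a) < 3) stop("need at least 3 pairs")
  d <- a - b
  sw <- if (sd(d) == 0) list(p.value = NA_real_) else shapiro.test(d)
  tt <- if (sd(d) == 0) {
    list(p.value = 1, statistic = c(t = 0))
  } else {
    t.test(a, b, paired = TRUE)
  }
  list(shapiro_p = sw$p.value, t_p = tt$p.value,
       t_stat = unname(tt$statistic), mean_diff = mean(d), n = length(a))
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper used to quantify the linearity of stress-strain
#' data over the functional strain range.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, non-zero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate data: zero variance in `x` or `y`")
  cor(x, y)
}

#' Write an agreement table (one row per condition) to CSV
#'
#' @param tab Data frame with at least the columns `condition`, `ccc`,
#'   `ci95_low`, `ci95_high`, `slope`, `intercept`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_agreement_table <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
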