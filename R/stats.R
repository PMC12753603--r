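# Agreement statistics between two dosimetry pathways: BMI stratification,
# percentage dose differences, two-way mixed single-measures absolute-
# agreement ICC with F-based 95% CI, Deming power-law regression with a
# configurable measurement-error ratio, and through-origin regression of
# organ dose on SSDE.

#' BMI category
#'
#' `BMI = weight / height^2`, categorized on left-closed intervals
#' [0, 18.5) underweight, [18.5, 25) healthy, [25, 30) overweight,
#' [30, Inf) obese.
#'
#' @param weight_kg Weight (kg), > 0.
#' @param height_m Height (m), > 0.
#' @return Factor level among underweight/healthy/overweight/obese.
#' @export
bmi_category <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0)) {
    stop("weight and height must be positive", call. = FALSE)
  }
  bmi <- weight_kg / height_m^2
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "healthy", "overweight", "obese"))
}

#' Percentage dose difference
#'
#' `100 * (y - x_ref) / x_ref`; negative values mean the comparator
#' underestimates the reference dose.
#'
#' @param x_ref Reference doses (mGy), > 0.
#' @param y Comparator doses (mGy).
#' @return Percentages, vectorized.
#' @export
percent_difference <- function(x_ref, y) {
  if (any(x_ref <= 0)) stop("reference doses must be positive", call. = FALSE)
  100 * (y - x_ref) / x_ref
}

#' Summarize percentage differences (mean of per-subject differences)
#'
#' @param diffs Percentage differences from [percent_difference()].
#' @return Named vector (mean, min, max).
#' @export
percent_difference_summary <- function(diffs) {
  c(mean = mean(diffs), min = min(diffs), max = max(diffs))
}

#' Intraclass correlation, two-way mixed, single measures, absolute agreement
#'
#' ICC(A,1) from the two-way ANOVA mean squares (rows = subjects, columns =
#' methods): `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with the
#' standard F-based 95% confidence interval. Negative estimates are allowed
#' and reported (within-subject variance exceeding between-subject
#' variance).
#'
#' @param x,y Paired measurements (the two methods), n >= 3.
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `icc_result`: `point_estimate`, `ci95`,
#'   `model = "two-way mixed, single measures, absolute agreement"`, `n`,
#'   and an agreement `label` (poor < 0.5 <= moderate < 0.75 <= good <
#'   0.9 <= excellent).
#' @export
icc_absolute_agreement <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  resid <- m - outer(row_means, rep(1, k)) -
    outer(rep(1, n), col_means) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  if (!is.finite(a) || !is.finite(b)) { a <- 0; b <- 1 }
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  v <- max(v, 1)
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  lower <- min(lower, icc); upper <- max(upper, icc)
  labels <- c("poor", "moderate", "good", "excellent")
  lab <- labels[findInterval(icc, c(-Inf, 0.5, 0.75, 0.9))]
  structure(list(point_estimate = icc, ci95 = c(lower = lower, upper = upper),
                 model = "two-way mixed, single measures, absolute agreement",
                 n = n, label = lab,
                 mean_squares = c(msr = msr, msc = msc, mse = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(A,1) = %.4f [%.4f, %.4f], n = %d (%s)\n",
              x$point_estimate, x$ci95[1], x$ci95[2], x$n, x$label))
  invisible(x)
}

#' Consistency ICC (two-way mixed, single measures)
#'
#' ICC(C,1) = (MSR - MSE) / (MSR + (k-1) MSE); insensitive to a constant
#' offset between methods, provided for contrast with the absolute-
#' agreement form.
#'
#' @inheritParams icc_absolute_agreement
#' @return The point estimate.
#' @export
icc_consistency <- function(x, y) {
  r <- icc_absolute_agreement(x, y)
  ms <- r$mean_squares
  (ms["msr"] - ms["mse"]) / (ms["msr"] + ms["mse"])
}

#' Deming power-law regression
#'
#' Fits `y = a * x^b` by errors-in-variables (Deming) regression on the
#' log-log scale, where the power law is linear and the stated relative
#' measurement errors become additive. The error-variance ratio is
#' `delta = (error_y / error_x)^2`. Defaults follow the study convention
#' of 10% reference-method and 25% comparator error; a sensitivity refit at
#' e.g. 35%/15% quantifies the coefficients' dependence on that choice.
#'
#' @param x,y Positive paired doses (mGy), n >= 3.
#' @param error_x,error_y Relative measurement errors (fractions).
#' @return Object of class `deming_fit`: `a`, `b`, `error_ratio`
#'   (`delta`), `n`.
#' @export
deming_powerlaw <- function(x, y, error_x = 0.10, error_y = 0.25) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(x <= 0) || any(y <= 0)) {
    stop("doses must be positive (log scale)", call. = FALSE)
  }
  if (error_x <= 0 || error_y <= 0) stop("errors must be positive", call. = FALSE)
  lx <- log(x); ly <- log(y)
  delta <- (error_y / error_x)^2
  sxx <- sum((lx - mean(lx))^2)
  syy <- sum((ly - mean(ly))^2)
  sxy <- sum((lx - mean(lx)) * (ly - mean(ly)))
  if (abs(sxy) < 1e-300) stop("degenerate data (no covariance)", call. = FALSE)
  b <- (syy - delta * sxx + sqrt((syy - delta * sxx)^2 + 4 * delta * sxy^2)) /
    (2 * sxy)
  ln_a <- mean(ly) - b * mean(lx)
  structure(list(a = exp(ln_a), b = b, error_ratio = delta,
                 error_x = error_x, error_y = error_y, n = length(x)),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("<deming_fit> y = %.4g * x^%.4g (delta = %.3g, n = %d)\n",
              x$a, x$b, x$error_ratio, x$n))
  invisible(x)
}

#' Deming sensitivity analysis
#'
#' Refits at an alternate error pair and reports the percentage shift of
#' both coefficients.
#'
#' @inheritParams deming_powerlaw
#' @param alt_error_x,alt_error_y Alternate relative errors (defaults
#'   35%/15%).
#' @return List with `fit`, `alt_fit`, and `shift_pct = c(a, b)`.
#' @export
deming_sensitivity <- function(x, y, error_x = 0.10, error_y = 0.25,
                               alt_error_x = 0.35, alt_error_y = 0.15) {
  f1 <- deming_powerlaw(x, y, error_x, error_y)
  f2 <- deming_powerlaw(x, y, alt_error_x, alt_error_y)
  list(fit = f1, alt_fit = f2,
       shift_pct = c(a = 100 * (f2$a - f1$a) / f1$a,
                     b = 100 * (f2$b - f1$b) / f1$b))
}

#' Through-origin regression of organ dose on SSDE
#'
#' `m = sum(x*y) / sum(x^2)` with the no-intercept coefficient of
#' determination `R^2 = 1 - sum((y - m x)^2) / sum(y^2)` (documented
#' convention).
#'
#' @param x SSDE values (mGy), n >= 2 (n = 1 allowed as the closed form).
#' @param y Organ doses (mGy).
#' @return Object of class `origin_fit`: `slope`, `r_squared`, `n`.
#' @export
origin_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (all(x == 0)) stop("all-zero x", call. = FALSE)
  m <- sum(x * y) / sum(x^2)
  r2 <- if (sum(y^2) > 0) 1 - sum((y - m * x)^2) / sum(y^2) else NA_real_
  structure(list(slope = m, r_squared = r2, n = length(x)),
            class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf("<origin_fit> y = %.4g x, R^2 = %.4f (n = %d)\n",
              x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Correlation of dose differences with anthropometrics
#'
#' Ordinary linear regression (with intercept) of percentage dose
#' difference on a covariate; returns the coefficient of determination.
#'
#' @param diffs Percentage differences.
#' @param covariate Height, weight or BMI values, non-constant; n >= 3.
#' @return R^2.
#' @export
correlation_with_anthropometrics <- function(diffs, covariate) {
  if (length(diffs) != length(covariate)) stop("length mismatch", call. = FALSE)
  if (length(diffs) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(covariate) == 0) stop("constant covariate", call. = FALSE)
  fit <- stats::lm(diffs ~ covariate)
  summary(fit)$r.squared
}
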