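test_that("BMI categories use left-closed boundaries at 18.5 / 25 / 30", {
  got <- bmi_category(c(18.4, 18.5, 24.9, 25, 29.9, 30), height_m = 1)
  expect_equal(as.character(got),
               c("underweight", "healthy", "healthy", "overweight",
                 "overweight", "obese"))
  expect_error(bmi_category(-70, 1.8), "positive")
})

test_that("percent difference is (y - x) / x * 100 and rejects x <= 0", {
  expect_equal(percent_difference(4, 5), 25)
  expect_equal(percent_difference(5, 4), -20)
  expect_error(percent_difference(0, 1), "positive")
})

test_that("ICC is 1 for identical columns and labels agreement bands", {
  r <- icc_absolute_agreement(1:10, 1:10)
  expect_equal(r$point_estimate, 1)
  expect_equal(r$label, "excellent")
  d <- paired_doses(n = 20, noise = 0.3)
  r2 <- icc_absolute_agreement(d$x, d$y)
  expect_true(r2$point_estimate > 0.9 && r2$point_estimate <= 1)
  expect_true(r2$ci95["lower"] <= r2$point_estimate &&
                r2$point_estimate <= r2$ci95["upper"])
})

test_that("a constant offset hurts absolute agreement but not consistency", {
  d <- paired_doses(n = 30, noise = 0.2, shift = 3)
  a <- icc_absolute_agreement(d$x, d$y)
  cons <- unname(icc_consistency(d$x, d$y))
  expect_gt(cons, a$point_estimate)
})

test_that("Deming power-law fit is exact on noise-free data", {
  x <- exp(seq(log(0.5), log(20), length.out = 30))
  y <- 1.5 * x^0.8
  f <- deming_powerlaw(x, y)
  expect_equal(f$a, 1.5, tolerance = 1e-8)
  expect_equal(f$b, 0.8, tolerance = 1e-8)
  expect_equal(f$error_ratio, (0.25 / 0.10)^2)
  expect_error(deming_powerlaw(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("sensitivity variant swaps the error assumption", {
  x <- exp(seq(log(1), log(10), length.out = 25))
  y <- 1.2 * x^0.9
  f <- deming_sensitivity(x, y)
  expect_equal(f$alt_fit$error_ratio, (0.15 / 0.35)^2)
  expect_equal(f$alt_fit$b, 0.9, tolerance = 1e-8)  # exact data: ratio irrelevant
  expect_lt(max(abs(f$shift_pct)), 1e-6)
})

test_that("property: Deming slope lies between the two OLS extremes", {
  set.seed(41)
  for (k in 1:20) {
    tru <- exp(runif(40, log(1), log(15)))
    x <- tru * exp(rnorm(40, 0, 0.15))
    y <- 1.3 * tru^0.9 * exp(rnorm(40, 0, 0.2))
    lx <- log(x); ly <- log(y)
    b_yx <- stats::cov(lx, ly) / stats::var(lx)      # OLS of y on x
    b_xy <- stats::var(ly) / stats::cov(lx, ly)      # inverse OLS
    b_dem <- deming_powerlaw(x, y)$b
    expect_true(b_dem >= min(b_yx, b_xy) - 1e-12 &&
                  b_dem <= max(b_yx, b_xy) + 1e-12)
  }
})

test_that("origin regression is exact on proportional data", {
  x <- 1:20
  o <- origin_regression(x, 2.5 * x)
  expect_equal(o$slope, 2.5, tolerance = 1e-12)
  expect_equal(o$r_squared, 1, tolerance = 1e-12)
})

test_that("anthropometric correlation validates its inputs", {
  set.seed(5)
  x <- runif(10, 60, 100)
  y <- 0.1 * x + rnorm(10, 0, 0.5)
  r2 <- correlation_with_anthropometrics(y, x)
  expect_true(r2 > 0 && r2 <= 1)
  expect_error(correlation_with_anthropometrics(1:2, 1:2), "3")
  expect_error(correlation_with_anthropometrics(1:5, rep(70, 5)), "constant")
})
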