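test_that("PE follows the sign convention (positive = underestimation)", {
  expect_equal(percentage_error(100, 100), 0)
  expect_equal(percentage_error(100, 90), 10)
  expect_equal(percentage_error(200, 250), -25)
  expect_equal(absolute_percentage_error(100, 90), 10)
  expect_equal(absolute_percentage_error(200, 250), 25)
  expect_error(percentage_error(0, 10), "positive")
})

test_that("APE = |PE| and both are scale invariant", {
  set.seed(51)
  gold <- runif(50, 10, 500)
  pred <- gold * runif(50, 0.5, 1.5)
  expect_equal(absolute_percentage_error(gold, pred),
               abs(percentage_error(gold, pred)))
  c_scale <- 3.7
  expect_equal(percentage_error(c_scale * gold, c_scale * pred),
               percentage_error(gold, pred))
  expect_true(all(absolute_percentage_error(gold, pred) >= 0))
  expect_equal(absolute_percentage_error(gold, gold), rep(0, 50))
})

test_that("acceptability band is closed at +/-10%", {
  expect_true(is_within_acceptable_limits(0))
  expect_true(is_within_acceptable_limits(10))
  expect_true(is_within_acceptable_limits(-10))
  expect_false(is_within_acceptable_limits(11.3))
  expect_false(is_within_acceptable_limits(-10.01))
})

test_that("group summary gives the median with binomial order-statistic CI", {
  # n = 5 is below the exact method's reach: range CI with a warning
  expect_warning(s <- group_summary(c(1, 2, 3, 4, 100)), "range")
  expect_equal(s$median, 3)

  expect_warning(sym <- group_summary(c(-2, -1, 0, 1, 2)), "range")
  expect_equal(sym$median, 0)
  expect_equal(sym$ci_lower, -sym$ci_upper)

  # n = 10: exact ranks from the binomial(10, 1/2) tails
  set.seed(52)
  v <- rnorm(10)
  s10 <- group_summary(v)
  sv <- sort(v)
  l <- qbinom(0.025, 10, 0.5)
  expect_identical(l, 2)
  expect_equal(s10$ci_lower, sv[l])
  expect_equal(s10$ci_upper, sv[10 + 1 - l])
  expect_lte(pbinom(l - 1, 10, 0.5) * 2, 0.05)  # coverage >= 95%
  expect_equal(s10$method, "binomial-order-statistic")

  expect_warning(s5 <- group_summary(c(5, 1, 9, 2, 4)), "range")
  expect_equal(c(s5$ci_lower, s5$ci_upper), c(1, 9))
  expect_error(group_summary(c(1, 2)), "at least 3")
})

test_that("Bland-Altman limits match the textbook formula", {
  same <- bland_altman(c(10, 20, 30), c(10, 20, 30))
  expect_equal(same$mean_difference, 0)
  expect_equal(c(same$loa_lower, same$loa_upper), c(0, 0))

  d2 <- bland_altman(c(0, 2), c(1, 1))  # differences -1, +1
  expect_equal(d2$mean_difference, 0)
  expect_equal(d2$sd_difference, sqrt(2))
  expect_equal(d2$loa_upper, 1.96 * sqrt(2), tolerance = 1e-9)
  expect_equal(d2$loa_lower, -1.96 * sqrt(2), tolerance = 1e-9)

  set.seed(53)
  a <- rnorm(40, 100, 15); b <- rnorm(40, 100, 15)
  res <- bland_altman(a, b)
  d <- a - b
  expect_lt(abs(res$mean_difference - mean(d)), 1e-9)
  expect_lt(abs(res$loa_upper - (mean(d) + 1.96 * sd(d))), 1e-9)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Bland-Altman limits contain about 95% of normal differences", {
  set.seed(54)
  n <- 1e4
  a <- rnorm(n); b <- rnorm(n)
  res <- bland_altman(a, b)
  inside <- mean((a - b) >= res$loa_lower & (a - b) <= res$loa_upper)
  expect_lt(abs(inside - 0.95), 0.01)
})

test_that("ICC(2,1) matches the explicit mean-squares oracle", {
  # perfect agreement
  m <- cbind(c(10, 20, 30, 40), c(10, 20, 30, 40))
  expect_equal(icc_two_way_random_absolute(m), 1)

  # absolute agreement penalizes a constant offset
  off <- cbind(c(10, 20, 30, 40), c(10, 20, 30, 40) + 30)
  expect_lt(icc_two_way_random_absolute(off), 0.5)

  # 6 x 2 fixture vs. mean squares computed by explicit sums
  x <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_lt(abs(icc_two_way_random_absolute(x) - oracle), 1e-9)

  expect_error(icc_two_way_random_absolute(cbind(c(1, NA), c(1, 2))),
               "complete")
})

test_that("ICC of subject-permuted ratings is near zero", {
  set.seed(55)
  a <- rnorm(50, 100, 20)
  ratings <- cbind(a, sample(a))
  expect_lte(abs(icc_two_way_random_absolute(ratings)), 0.15)
})

test_that("agreement report flags classes and excludes zero-gold classes", {
  fap <- generate_fap(5)
  per <- compute_agreement(list(fap, generate_fap(6), generate_fap(7)),
                           algorithm_parameters())
  expect_setequal(unique(per$class), activity_levels())
  expect_equal(per$ape, abs(per$pe))
  rep <- suppressWarnings(agreement_report(per))
  expect_true(all(rep$acceptable))

  # a participant with no standing time is excluded for that class only
  one <- list(recording = constant_recording(c(0.1, 0, 0.99), 30),
              annotation = activity_annotation(rep("sedentary", 30)))
  expect_warning(rows <- compute_agreement(list(one)), "zero gold time")
  expect_equal(rows$class, "sedentary")
})
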