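test_that("scalar logistic fit recovers a known slope", {
  set.seed(31)
  x <- runif(500, -1, 1)
  p <- plogis(8 * x)
  y <- rbinom(500, 1, p)
  fit <- fit_logistic_scalar(x, y)
  # recovery within the asymptotic 95% CI of the fit
  se <- summary(glm(y ~ x, family = binomial()))$coefficients["x", "Std. Error"]
  expect_lt(abs(fit$slope - 8), 1.96 * se + 1e-9)
  expect_false(fit$excluded)
  expect_lte(fit$deviance, fit$null_deviance)
})

test_that("deviance test excludes responders with no deviation dependence", {
  set.seed(32)
  hits <- replicate(400, {
    x <- runif(100, -1, 1)
    y <- rbinom(100, 1, 0.5)
    fit_logistic_scalar(x, y)$chi2_p > 0.05
  })
  expect_gte(mean(hits), 0.9)  # type-I behavior of the chi-square test
})

test_that("degenerate response patterns are flagged", {
  expect_true(fit_logistic_scalar(runif(30), rep(1, 30))$excluded)
  expect_true(fit_logistic_scalar(runif(30), rep(0, 30))$excluded)
  # perfect separation: slope capped and flagged
  x <- c(seq(-1, -0.1, length.out = 15), seq(0.1, 1, length.out = 15))
  y <- as.integer(x > 0)
  fit <- fit_logistic_scalar(x, y)
  expect_true(fit$separation)
  expect_lte(abs(fit$slope), 50)
})

test_that("scalar slope is invariant to a constant shift of the deviations", {
  set.seed(33)
  x <- runif(200, -1, 1)
  y <- rbinom(200, 1, plogis(4 * x))
  f1 <- fit_logistic_scalar(x, y)
  f2 <- fit_logistic_scalar(x + 5, y)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-6)
})

test_that("normalizing deviations rescales the slope reciprocally", {
  set.seed(34)
  x <- runif(300, -0.5, 0.5)
  y <- rbinom(300, 1, plogis(3 * x))
  s1 <- fit_logistic_scalar(x, y)$slope
  s2 <- fit_logistic_scalar(x / 0.25, y)$slope
  expect_equal(s2 * 4, s1, tolerance = 1e-6)
})

test_that("circular fit recovers direction and is rotation invariant", {
  set.seed(35)
  th <- runif(400, -pi, pi)
  y <- rbinom(400, 1, plogis(3 * cos(th)))
  fit <- fit_logistic_circular(th, y)
  ang <- atan2(fit$coefs[2], fit$coefs[1])
  expect_lt(abs(ang), 10 * pi / 180)  # aligned with (1, 0) within 10 degrees
  rot <- fit_logistic_circular(th + 1.3, y)
  expect_equal(rot$slope, fit$slope, tolerance = 1e-6)
  expect_equal(fit$chi2_p, rot$chi2_p, tolerance = 1e-6)
})

test_that("phase-independent labels are excluded at the nominal rate", {
  set.seed(36)
  hits <- replicate(300, {
    th <- runif(80, -pi, pi)
    y <- rbinom(80, 1, 0.5)
    fit_logistic_circular(th, y)$excluded
  })
  expect_gte(mean(hits), 0.9)
})

test_that("exclusion threshold semantics are exact at alpha = 0.05", {
  fits <- tibble::tibble(chi2_p = c(0.04, 0.06, 0, 0.05))
  out <- exclude_noisy(fits)
  expect_equal(out$excluded, c(FALSE, TRUE, FALSE, FALSE))
  # cohort layout: excluded only when both algorithm fits are noisy
  co <- tibble::tibble(chi2_p_abs = c(0.2, 0.01, 0.2),
                       chi2_p_rel = c(0.2, 0.2, 0.01))
  expect_equal(exclude_noisy(co)$excluded, c(TRUE, FALSE, FALSE))
})

test_that("dominance-curve fit recovers a generating parabola and its order", {
  set.seed(37)
  x <- runif(150, 0, 16)
  y <- 0.02 * x^2 - 0.17 * x + rnorm(150, 0, 0.2)
  fit <- fit_dominance_curve(tibble::tibble(slope_sum = x, slope_diff = y))
  expect_equal(fit$best_order, 2)
  td <- tidy(fit)
  expect_lt(abs(td$estimate[td$term == "x^2"] - 0.02),
            2 * td$std_error[td$term == "x^2"])
  expect_lt(abs(td$estimate[td$term == "x^1"] + 0.17),
            2 * td$std_error[td$term == "x^1"])
  expect_lte(fit$adj_r_square, 1)
  # the curve is significantly negative (relative-dominant) at low x
  below <- dplyr::filter(fit$zero_crossing_region, sign == "below")
  expect_equal(nrow(below), 1)
  expect_lt(below$x_min, 2)
})

test_that("AIC order selection is reliable at the stated noise level", {
  set.seed(38)
  correct <- replicate(50, {
    x <- runif(150, 0, 16)
    y <- 0.02 * x^2 - 0.17 * x + rnorm(150, 0, 0.2)
    fit_dominance_curve(tibble::tibble(slope_sum = x, slope_diff = y))$best_order == 2
  })
  expect_gte(mean(correct), 0.8)
})

test_that("degenerate dominance data are reported with a flag", {
  x <- seq(0.5, 10, length.out = 30)
  fit <- fit_dominance_curve(tibble::tibble(slope_sum = x, slope_diff = rep(0, 30)))
  expect_equal(unname(fit$coefficients), rep(0, fit$best_order))
  expect_equal(fit$adj_r_square, 0)
  expect_true(fit$adj_r_square_degenerate)
})

test_that("prediction band is wider than the confidence band", {
  set.seed(39)
  x <- runif(80, 0, 12)
  y <- 0.02 * x^2 - 0.17 * x + rnorm(80, 0, 0.3)
  d <- tibble::tibble(slope_sum = x, slope_diff = y)
  ci <- fit_dominance_curve(d, band = "confidence")
  pi_ <- fit_dominance_curve(d, band = "prediction")
  expect_true(all(pi_$band$hi - pi_$band$lo > ci$band$hi - ci$band$lo))
})

test_that("group comparisons behave under null and shifted alternatives", {
  set.seed(40)
  base <- rnorm(50)
  same <- dplyr::bind_rows(
    tibble::tibble(condition = "a", slope_diff = base),
    tibble::tibble(condition = "b", slope_diff = base))
  res <- compare_groups(same)
  expect_equal(res$p_value[res$type == "between (rank-sum)"], 1, tolerance = 0.05)
  # power at a 1 SD shift, n = 50 per group
  rejections <- replicate(40, {
    d <- dplyr::bind_rows(
      tibble::tibble(condition = "a", slope_diff = rnorm(50)),
      tibble::tibble(condition = "b", slope_diff = rnorm(50, 1)))
    r <- compare_groups(d)
    r$p_adjusted[r$type == "between (rank-sum)"] < 0.05
  })
  expect_gt(mean(rejections), 0.9)
  # within-condition sign consistent with the generating shift
  shifted <- tibble::tibble(condition = "c", slope_diff = rnorm(60, 0.8))
  rw <- compare_groups(shifted)
  expect_lt(rw$p_value[1], 0.001)
})
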