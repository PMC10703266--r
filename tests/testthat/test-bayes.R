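test_that("Gaussian fusion matches symmetry and the flat-prior identity", {
  post <- fuse(gaussian_estimate(0, 1, "prior"), gaussian_estimate(1, 1))
  expect_equal(post$mu, 0.5)
  expect_equal(post$sigma, 1 / sqrt(2))
  lik <- gaussian_estimate(0.73, 0.2)
  flat <- gaussian_estimate(NA, Inf, "prior")
  post2 <- fuse(flat, lik)
  expect_equal(post2$mu, lik$mu)
  expect_equal(post2$sigma, lik$sigma)
  expect_error(fuse(flat, gaussian_estimate(NA, Inf)), "flat")
})

test_that("fusion agrees with grid renormalization of the density product", {
  set.seed(81)
  for (rep in 1:20) {
    mp <- runif(1, -1, 1); sp <- runif(1, 0.05, 0.5)
    ms <- runif(1, -1, 1); ss <- runif(1, 0.05, 0.5)
    post <- fuse(gaussian_estimate(mp, sp, "prior"), gaussian_estimate(ms, ss))
    g <- seq(-4, 4, length.out = 40001)
    w <- dnorm(g, mp, sp) * dnorm(g, ms, ss)
    w <- w / sum(w)
    mu_g <- sum(g * w)
    sd_g <- sqrt(sum((g - mu_g)^2 * w))
    expect_equal(post$mu, mu_g, tolerance = 1e-6)
    expect_equal(post$sigma, sd_g, tolerance = 1e-6)
  }
})

test_that("posterior variance never exceeds either input variance", {
  set.seed(82)
  for (rep in 1:50) {
    sp <- runif(1, 0.01, 1); ss <- runif(1, 0.01, 1)
    post <- fuse(gaussian_estimate(rnorm(1), sp, "prior"),
                 gaussian_estimate(rnorm(1), ss))
    expect_lte(post$sigma, min(sp, ss) + 1e-12)
  }
})

test_that("relative prior is a through-origin weighted regression", {
  # exact isochronous posteriors recover the line exactly
  mu <- 0.4 * (1:7)
  pr <- relative_prior(mu, rep(0.05, 7), sigma_exp = 0.1, i = 8)
  expect_equal(pr$mu, 0.4 * 8)
  # generic WLS oracle on random inputs
  set.seed(83)
  for (rep in 1:30) {
    i <- sample(4:11, 1)
    mu_e <- sort(runif(i - 1, 0, 5))
    sd_e <- runif(i - 1, 0.02, 0.4)
    pr <- relative_prior(mu_e, sd_e, sigma_exp = 0.08, i = i)
    n <- seq_len(i - 1)
    wls <- lm(mu_e ~ 0 + n, weights = 1 / sd_e^2)
    expect_equal(pr$mu, unname(coef(wls)[1]) * i, tolerance = 1e-10)
    expect_equal(pr$sigma^2, i^2 / sum(n^2 / sd_e^2) + 0.08^2,
                 tolerance = 1e-12)
  }
  # precision is capped by the experimental jitter
  tiny <- relative_prior(0.4 * (1:7), rep(1e-8, 7), sigma_exp = 0.1, i = 8)
  expect_equal(tiny$sigma, 0.1, tolerance = 1e-6)
  expect_true(rhythmsim:::is_flat(relative_prior(0.4, 0.1, 0.1, i = 2)))
})

test_that("absolute prior: printed sums equal the telescoped closed form", {
  set.seed(84)
  for (i in 4:11) {
    mu_e <- sort(runif(i - 1, 0, 5))
    sd_e <- runif(i - 1, 0.02, 0.4)
    a <- absolute_prior(mu_e, sd_e, 0.08, i, form = "printed")
    b <- absolute_prior(mu_e, sd_e, 0.08, i, form = "telescoped")
    expect_equal(a$mu, b$mu, tolerance = 1e-12)
    expect_equal(a$sigma^2, b$sigma^2, tolerance = 1e-12)
    # mean interval + last tone, telescoped
    expect_equal(a$mu, (mu_e[i - 1] - mu_e[1]) / (i - 2) + mu_e[i - 1])
  }
  # noiseless posteriors leave only the experimental jitter
  nl <- absolute_prior(0.5 * (1:5), rep(1e-9, 5), sigma_exp = 0.07, i = 6)
  expect_equal(nl$sigma, 0.07, tolerance = 1e-6)
})

test_that("absolute prior variance matches a sampling experiment", {
  # draw tone times from the posteriors; the statistic mean-interval + last
  # tone must reproduce (mu_p, sigma_p^2 - sigma_exp^2)
  set.seed(85)
  i <- 7
  mu_e <- c(0.5, 1.05, 1.48, 2.02, 2.55, 2.98)
  sd_e <- c(0.05, 0.08, 0.03, 0.06, 0.04, 0.07)
  pr <- absolute_prior(mu_e, sd_e, sigma_exp = 0.1, i = i)
  nsim <- 2e5
  X <- sapply(seq_len(i - 1), function(n) rnorm(nsim, mu_e[n], sd_e[n]))
  stat <- (X[, i - 1] - X[, 1]) / (i - 2) + X[, i - 1]
  expect_equal(mean(stat), pr$mu, tolerance = 0.001)
  expect_equal(var(stat), pr$sigma^2 - 0.1^2, tolerance = 0.0005)
})

test_that("late-probability closed form matches quadrature and its landmarks", {
  pr <- gaussian_estimate(1.0, 0.3, "prior")
  expect_equal(p_late(pr, gaussian_estimate(1.0, 0.4)), 0.5)
  s <- gaussian_estimate(1.0 + sqrt(0.3^2 + 0.4^2), 0.4)
  expect_equal(p_late(pr, s), pnorm(1), tolerance = 1e-12)
  set.seed(86)
  for (rep in 1:25) {
    pr <- gaussian_estimate(runif(1, -1, 1), runif(1, 0.05, 0.5), "prior")
    se <- gaussian_estimate(runif(1, -1, 1), runif(1, 0.05, 0.5))
    expect_equal(p_late(pr, se), p_late_quadrature(pr, se), tolerance = 1e-8)
  }
})

test_that("observer trials narrow their posteriors and saturate at low noise", {
  cue <- 0.5 * (1:8) + c(0.01, -0.02, 0.015, 0, -0.01, 0.02, -0.005, 0.01)
  out <- simulate_observer_trial(cue, probe_time = 4.5, sigma_s = 0.05,
                                 sigma_exp = 0.1, prior_type = "absolute")
  est <- out$estimates
  expect_true(all(est$sigma_posterior[3:8] < 0.05))
  expect_true(all(est$sigma_posterior[3:8] < est$sigma_likelihood[3:8]))
  expect_true(all(is.infinite(est$sigma_prior[1:2])))
  # probe far later than predicted, tiny sensory noise: response is late
  set.seed(87)
  late <- replicate(20, simulate_observer_trial(
    0.5 * (1:8), probe_time = 6.0, sigma_s = 1e-4,
    sigma_exp = 0.1, prior_type = "absolute")$response)
  expect_true(all(late == 1))
})

test_that("decision probabilities are calibrated", {
  set.seed(88)
  cfg <- experiment_config("2hz")
  trials <- draw_trials(cfg, 2000)
  p <- purrr::map2_dbl(trials$cue_times, trials$probe_time, function(cue, pt) {
    pass <- rhythmsim:::observer_pass(cue, 0.08, cfg$jitter_sd, "absolute")
    p_late(pass$probe_prior, gaussian_estimate(pt, 0.08))
  })
  resp <- rbinom(length(p), 1, p)
  bins <- cut(p, breaks = seq(0, 1, 0.2), include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- bins == b
    if (sum(idx) < 30) next
    se <- sqrt(mean(p[idx]) * (1 - mean(p[idx])) / sum(idx))
    expect_lt(abs(mean(resp[idx]) - mean(p[idx])), 4 * se + 0.02)
  }
})

test_that("observer cohorts reproduce under a seed and respect noise scaling", {
  a <- run_observer_experiment("4hz", sigma_s_grid = c(0.02, 0.1),
                               n_trials = 60, seed = 10)
  b <- run_observer_experiment("4hz", sigma_s_grid = c(0.02, 0.1),
                               n_trials = 60, seed = 10)
  expect_identical(a, b)
  w <- run_observer_experiment("4hz", sigma_s_grid = 0.2,
                               noise_scaling = "weber", n_trials = 60, seed = 1)
  expect_equal(w$sigma_s, 0.2 * 0.25)  # fraction of the 4 Hz mean period
  r <- precision_ratio_analysis(a)
  expect_true(all(c("precision_ratio") %in% names(r)))
  expect_true(all(r$mean_sigma_p >= r$sigma_exp - 1e-9))
})
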