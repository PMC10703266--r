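test_that("trial draws satisfy the generative equations and hard bounds", {
  cfg <- experiment_config("1.2hz", n_trials = 50)
  trials <- draw_trials(cfg, seed = 42)
  expect_equal(nrow(trials), 50)
  expect_true(all(trials$n_tones %in% 8:10))
  expect_true(all(trials$base_period >= 0.700 & trials$base_period <= 1.000))
  # t_i - T*i = eps_i exactly, probe at T*(I+1) + eps_probe
  for (j in seq_len(nrow(trials))) {
    Tj <- trials$base_period[j]
    I <- trials$n_tones[j]
    expect_equal(trials$cue_times[[j]] - Tj * seq_len(I), trials$jitters[[j]])
    expect_equal(trials$probe_time[j], Tj * (I + 1) + trials$probe_jitter[j])
  }
  # hard probe bound: |eps_probe| <= 0.3 * E[T]
  expect_true(all(abs(trials$probe_jitter) <= 0.3 * 0.85))
})

test_that("zero-noise configuration yields exact, seed-independent trials", {
  cfg <- frozen_config(period = 0.5, n_tones = 9)
  a <- draw_trials(cfg, 3, seed = 1)
  b <- draw_trials(cfg, 3, seed = 999)
  expect_identical(a$cue_times, b$cue_times)
  expect_equal(a$cue_times[[1]], 0.5 * 1:9)
  expect_equal(a$probe_time, rep(0.5 * 10, 3))
  expect_false(any(a$nonmonotone))
})

test_that("jitter statistics match the stated distributions (Monte Carlo)", {
  cfg <- experiment_config("2hz")
  trials <- draw_trials(cfg, 15000, seed = 7)
  eps <- unlist(trials$jitters)
  expect_equal(sd(eps), 0.100, tolerance = 0.02)
  expect_equal(mean(eps), 0, tolerance = 0.003)
  # probe jitter uniform on +/- 0.3 * 0.5 s
  ks <- suppressWarnings(
    stats::ks.test(trials$probe_jitter, "punif", -0.15, 0.15))
  expect_gt(ks$p.value, 0.01)
  # mean realized inter-tone interval converges to the design mean period
  soa <- purrr::map_dbl(trials$cue_times, ~ mean(diff(.x)))
  expect_equal(mean(soa), 0.5, tolerance = 0.005)
})

test_that("non-monotone sequences are kept and flagged, or resampled on request", {
  cfg <- experiment_config("1.2hz")
  trials <- draw_trials(cfg, 3000, seed = 3)
  expect_gt(sum(trials$nonmonotone), 0)  # sigma/T large enough to occur
  cfg2 <- experiment_config("1.2hz", resample_nonmonotone = TRUE)
  trials2 <- draw_trials(cfg2, 400, seed = 3)
  expect_false(any(trials2$nonmonotone))
  expect_true(all(purrr::map_lgl(trials2$cue_times, ~ all(diff(.x) > 0))))
})

test_that("config invariants are enforced", {
  expect_error(experiment_config("custom", period_bounds = c(0.5, 0.4),
                                 jitter_sd = 0.1), "b_l")
  expect_error(experiment_config("custom", period_bounds = c(0.4, 0.6),
                                 jitter_sd = -1), "non-negative")
  expect_error(experiment_config("2hz", probe_jitter_frac = 0.6), "probe_jitter_frac")
  # tone duration at b_h must not overlap the next slot at b_l
  expect_error(experiment_config("custom", period_bounds = c(0.2, 0.6),
                                 jitter_sd = 0.05), "overlap")
})

test_that("envelope normalization is exact", {
  expect_equal(normalize_envelope(c(0, 0, 2, 2)), c(-1, -1, 1, 1))
  expect_error(normalize_envelope(rep(3, 10)), "constant")
  set.seed(1)
  for (i in 1:200) {
    x <- runif(50, 0, 10)
    out <- normalize_envelope(x)
    expect_equal(max(out), 1)
    expect_lte(mean(out), 1e-12)
  }
})

test_that("rendered envelopes have the printed tone duration and structure", {
  cfg <- experiment_config("2hz")
  trial <- manual_trial(0.5 * 1:5, probe_time = 3.0)
  env <- render_envelope(trial, cfg, include_probe = FALSE)
  expect_s3_class(env, "envelope_signal")
  expect_equal(max(env$values), 1)
  # tone duration 0.4 * 0.5 s = 0.2 s: support of each tone ~ 2000 samples
  above <- env$values > 0.5 * max(env$values)
  runs <- rle(above)
  widths <- runs$lengths[runs$values]
  expect_equal(length(widths), 5)
  expect_true(all(abs(widths / cfg$sample_rate - 0.2) < 0.01))
  # no tones -> error
  empty <- manual_trial(numeric(0), probe_time = 1)
  expect_error(render_envelope(empty, cfg, include_probe = FALSE), "no tones")
})

test_that("isochronous envelope autocorrelation peaks at the period", {
  cfg <- experiment_config("2hz")
  trial <- manual_trial(0.5 * 1:8, probe_time = 4.5)
  env <- render_envelope(trial, cfg, include_probe = FALSE)
  x <- env$values - mean(env$values)
  # FFT-based autocorrelation oracle
  n <- length(x)
  X <- fft(c(x, numeric(n)))
  ac <- Re(fft(X * Conj(X), inverse = TRUE))[1:n] / (2 * n)
  # first substantial nonzero-lag peak
  lag_min <- round(0.1 * cfg$sample_rate)
  pk <- which.max(ac[lag_min:round(0.8 * cfg$sample_rate)]) + lag_min - 1
  expect_equal(pk / cfg$sample_rate, 0.5, tolerance = 2 / cfg$sample_rate + 1e-9)
})

test_that("overlapping tones combine by default and error on request", {
  cfg <- experiment_config("2hz")
  trial <- manual_trial(c(0.5, 0.6), probe_time = 1.5)  # 0.2 s tones overlap
  expect_silent(env <- render_envelope(trial, cfg, include_probe = FALSE))
  expect_error(render_envelope(trial, cfg, include_probe = FALSE,
                               on_overlap = "error"), "overlap")
})

test_that("session assembly draws ITIs in [0.5, 1] between probe slot and next onset", {
  cfg <- quick_config()
  trials <- draw_trials(cfg, 30, seed = 5)
  ses <- assemble_session(trials, cfg, include_probe = FALSE, seed = 9)
  off <- ses$offsets
  gaps <- (off$offset[-1] + purrr::map_dbl(trials$cue_times[-1], 1)) -
    off$probe_slot_time[-nrow(off)]
  expect_true(all(gaps >= 0.5 - 1e-9 & gaps <= 1.0 + 1e-9))
  expect_equal(gaps, off$iti_after[-nrow(off)])
  # single trial: session envelope is that trial's envelope (up to padding)
  one <- assemble_session(trials[1, ], cfg, include_probe = TRUE, seed = 1)
  expect_equal(length(one$offsets$offset), 1)
  solo <- render_envelope(trials[1, ], cfg, include_probe = TRUE)
  expect_equal(length(unique(round(diff(one$envelope$event_times) -
                                     diff(solo$event_times), 9))), 1)
})

test_that("many ITI draws stay strictly inside the stated bounds", {
  cfg <- quick_config()
  trials <- draw_trials(cfg, 4, seed = 2)
  itis <- unlist(purrr::map(1:300, function(i) {
    ses <- assemble_session(trials, cfg, include_probe = FALSE, seed = i)
    ses$offsets$iti_after[-4]
  }))
  expect_gte(min(itis), 0.5)
  expect_lte(max(itis), 1.0)
  expect_equal(mean(itis), 0.75, tolerance = 0.01)
})
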