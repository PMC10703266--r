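# shared fixture builders (all fixtures are generated in code)

# a fast 2 Hz-like condition for unit tests
quick_config <- function(...) {
  experiment_config("2hz", n_trials = 20, ...)
}

# a noiseless, fixed-period condition: every draw is deterministic
frozen_config <- function(period = 0.5, n_tones = 9) {
  experiment_config("custom", period_bounds = c(period, period),
                    jitter_sd = 0, probe_jitter_frac = 0,
                    tone_count_choices = n_tones, n_trials = 5)
}

# classic (fixed-frequency) oscillator parameter point
classic_params <- function(...) wc_params(rho_e = 1.6, rho_i = -2.9, ...)

# unwrap a phase series (cumulative 2*pi correction)
unwrap_phase <- function(p) {
  d <- diff(p)
  p + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

# one-row trial tibble from explicit times
manual_trial <- function(cue_times, probe_time, base_period = NA_real_,
                         condition = "manual") {
  I <- length(cue_times)
  tibble::tibble(
    trial_id = 1L, condition = condition,
    base_period = if (is.na(base_period)) mean(diff(cue_times)) else base_period,
    n_tones = I, cue_times = list(cue_times),
    jitters = list(rep(0, I)),
    probe_time = probe_time, probe_jitter = 0, nonmonotone = FALSE
  )
}
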