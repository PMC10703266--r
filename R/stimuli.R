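#' Experiment configuration for a jittered tone-sequence condition
#'
#' The behavioral task presents 8--10 cue tones on an underlying isochronous
#' grid of period `T ~ U(b_l, b_h)`, each displaced by Gaussian jitter
#' `eps ~ N(0, sigma)`, followed by a probe tone at the next grid slot
#' displaced by uniform jitter within +/- `probe_jitter_frac` of the design
#' mean period. Four named conditions are built in, matching the published
#' experiments:
#'
#' | condition  | period bounds (s) | jitter SD (s) |
#' |------------|-------------------|---------------|
#' | `1.2hz`    | 0.700--1.000      | 0.170         |
#' | `1.2hz_lj` | 0.700--1.000      | 0.045         |
#' | `2hz`      | 0.400--0.600      | 0.100         |
#' | `4hz`      | 0.210--0.290      | 0.045         |
#'
#' @param condition Condition name, one of `"1.2hz"`, `"1.2hz_lj"`, `"2hz"`,
#'   `"4hz"`, or `"custom"` (supply bounds and jitter explicitly).
#' @param period_bounds Length-2 numeric, `(b_l, b_h)` in seconds.
#' @param jitter_sd Cue-tone jitter SD `sigma` in seconds.
#' @param probe_jitter_frac Probe jitter half-range as a fraction of the
#'   design mean period `(b_l + b_h)/2`. Default 0.3.
#' @param tone_count_choices Integer set the cue-tone count is drawn from.
#' @param n_trials Trials per behavioral session (default 150).
#' @param tone_duration_frac Tone duration as a fraction of the mean period
#'   (default 0.4).
#' @param sample_rate Envelope grid rate in Hz (default 10000, the inverse of
#'   the integration step).
#' @param resample_nonmonotone If `TRUE`, trials whose cue tones come out
#'   non-monotone (possible at large `sigma`) are redrawn; default `FALSE`
#'   (kept and flagged).
#'
#' @return A list of class `"experiment_config"`.
#' @export
#' @examples
#' experiment_config("2hz")
experiment_config <- function(condition = c("1.2hz", "2hz", "4hz", "1.2hz_lj", "custom"),
                              period_bounds = NULL, jitter_sd = NULL,
                              probe_jitter_frac = 0.3,
                              tone_count_choices = 8:10,
                              n_trials = 150,
                              tone_duration_frac = 0.4,
                              sample_rate = 10000,
                              resample_nonmonotone = FALSE) {
  condition <- match.arg(condition)
  presets <- list(
    "1.2hz"    = list(bounds = c(0.700, 1.000), sd = 0.170),
    "1.2hz_lj" = list(bounds = c(0.700, 1.000), sd = 0.045),
    "2hz"      = list(bounds = c(0.400, 0.600), sd = 0.100),
    "4hz"      = list(bounds = c(0.210, 0.290), sd = 0.045)
  )
  if (condition != "custom") {
    if (is.null(period_bounds)) period_bounds <- presets[[condition]]$bounds
    if (is.null(jitter_sd)) jitter_sd <- presets[[condition]]$sd
  }
  if (is.null(period_bounds) || is.null(jitter_sd))
    stop("custom configs need explicit `period_bounds` and `jitter_sd`")

  cfg <- structure(list(
    condition_name = condition,
    period_bounds = as.numeric(period_bounds),
    jitter_sd = jitter_sd,
    probe_jitter_frac = probe_jitter_frac,
    tone_count_choices = as.integer(tone_count_choices),
    n_trials = as.integer(n_trials),
    tone_duration_frac = tone_duration_frac,
    sample_rate = sample_rate,
    resample_nonmonotone = isTRUE(resample_nonmonotone)
  ), class = "experiment_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  b <- cfg$period_bounds
  if (!(length(b) == 2 && b[1] > 0 && b[1] <= b[2]))
    stop("period bounds must satisfy 0 < b_l <= b_h")
  if (cfg$jitter_sd < 0) stop("jitter_sd must be non-negative")
  if (cfg$probe_jitter_frac < 0 || cfg$probe_jitter_frac >= 0.5)
    stop("probe_jitter_frac must lie in [0, 0.5)")
  if (cfg$tone_duration_frac * b[2] >= b[1])
    stop("tone duration at the maximum period would overlap the next slot ",
         "at the minimum period: tone_duration_frac * b_h must be < b_l")
  if (cfg$sample_rate < 2000) stop("sample_rate below integration-grid needs")
  invisible(cfg)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config '%s'>\n", x$condition_name))
  cat(sprintf("  period T ~ U(%.3f, %.3f) s; cue jitter sd %.3f s\n",
              x$period_bounds[1], x$period_bounds[2], x$jitter_sd))
  cat(sprintf("  probe jitter U(+/- %.2f * %.3f s); %d trials; tones in {%s}\n",
              x$probe_jitter_frac, mean(x$period_bounds), x$n_trials,
              paste(x$tone_count_choices, collapse = ",")))
  invisible(x)
}

#' Design mean period of a configuration
#'
#' `(b_l + b_h) / 2`, the expectation of the per-trial base period; also the
#' reference for the probe jitter bound and the tone duration.
#' @param config An [experiment_config()].
#' @return Seconds.
#' @export
mean_period <- function(config) mean(config$period_bounds)

draw_one_trial <- function(config) {
  repeat {
    T_base <- runif(1, config$period_bounds[1], config$period_bounds[2])
    choices <- config$tone_count_choices
    I <- if (length(choices) == 1) choices else sample(choices, 1)
    eps <- rnorm(I, 0, config$jitter_sd)
    cue <- T_base * seq_len(I) + eps
    bound <- config$probe_jitter_frac * mean_period(config)
    eps_probe <- runif(1, -bound, bound)
    mono <- all(diff(cue) > 0)
    if (mono || !config$resample_nonmonotone) {
      return(tibble::tibble(
        condition = config$condition_name,
        base_period = T_base, n_tones = I,
        cue_times = list(cue), jitters = list(eps),
        probe_time = T_base * (I + 1) + eps_probe,
        probe_jitter = eps_probe,
        nonmonotone = !mono
      ))
    }
  }
}

#' Draw jittered tone-sequence trials
#'
#' Samples `n_trials` independent trials from a condition's generative
#' process: base period `T ~ U(b_l, b_h)`, cue count `I` uniform over the
#' configured choices, cue times `t_i = T i + eps_i` with
#' `eps_i ~ N(0, sigma)`, and probe time `t_probe = T (I + 1) + eps_probe`
#' with `eps_probe ~ U(-0.3 E[T], 0.3 E[T])`.
#'
#' Cue sequences that come out non-monotone (possible at the slow rate where
#' `sigma` is a large fraction of `T`) are kept and flagged in the
#' `nonmonotone` column unless `config$resample_nonmonotone` is set.
#'
#' @param config An [experiment_config()].
#' @param n_trials Number of trials; defaults to `config$n_trials`.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with one row per trial: `trial_id`, `condition`,
#'   `base_period`, `n_tones`, list-columns `cue_times` and `jitters`,
#'   `probe_time`, `probe_jitter`, `nonmonotone`.
#' @export
#' @examples
#' trials <- draw_trials(experiment_config("2hz"), n_trials = 5, seed = 1)
#' trials$cue_times[[1]]
draw_trials <- function(config, n_trials = config$n_trials, seed = NULL) {
  validate_config(config)
  draw <- function() {
    out <- purrr::map_dfr(seq_len(n_trials), function(i) draw_one_trial(config))
    out <- dplyr::mutate(out, trial_id = dplyr::row_number(), .before = 1)
    bound <- config$probe_jitter_frac * mean_period(config)
    stopifnot(all(abs(out$probe_jitter) <= bound))
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Normalize a stimulus envelope
#'
#' Mean-removes the series and divides by the maximum of the mean-removed
#' series, so the output peaks at exactly 1 with zero mean before division.
#' This is the normalization applied to the audio envelope before it drives
#' the excitatory population.
#'
#' @param values Numeric amplitude series (non-constant).
#' @return Numeric series with `max(out) == 1`.
#' @export
#' @examples
#' normalize_envelope(c(0, 0, 2, 2))
normalize_envelope <- function(values) {
  centred <- values - mean(values)
  m <- max(centred)
  if (m == 0) stop("constant envelope: max of mean-removed series is zero, cannot normalize")
  centred / m
}

# raised-cosine-ramped boxcar of `dur` seconds on a grid of step 1/fs
tone_shape <- function(dur, fs, ramp = 0.005) {
  n <- max(2L, round(dur * fs))
  shape <- rep(1, n)
  nr <- min(round(ramp * fs), floor(n / 2))
  if (nr > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    shape[seq_len(nr)] <- up
    shape[n + 1 - seq_len(nr)] <- up
  }
  shape
}

# place ramped boxcars at `onsets` on a grid running from 0 to t_end
render_onsets <- function(onsets, dur, fs, t_end, on_overlap = "combine") {
  if (length(onsets) == 0) stop("cannot render an envelope with no tones")
  if (any(onsets < 0)) stop("tone onsets must be non-negative on the render grid")
  if (on_overlap == "error" && any(diff(sort(onsets)) < dur))
    stop("overlapping tone supports (inter-onset interval below tone duration)")
  n <- ceiling(t_end * fs) + 1L
  values <- numeric(n)
  shape <- tone_shape(dur, fs)
  m <- length(shape)
  for (t0 in onsets) {
    i0 <- round(t0 * fs) + 1L
    idx <- i0:min(i0 + m - 1L, n)
    values[idx] <- pmax(values[idx], shape[seq_along(idx)])
  }
  values
}

#' Render a trial's stimulus envelope
#'
#' Each tone contributes a boxcar of duration `tone_duration_frac * (b_l +
#' b_h)/2` with 5 ms raised-cosine on/off ramps, placed at its onset on a
#' grid of `config$sample_rate` Hz. The result is normalized with
#' [normalize_envelope()] so it can drive the oscillator directly.
#'
#' Overlapping tones (possible under heavy jitter) are combined by pointwise
#' maximum by default, as superposed audio would be; set
#' `on_overlap = "error"` to refuse them.
#'
#' @param trial A one-row trial tibble from [draw_trials()].
#' @param config The [experiment_config()] that generated it.
#' @param include_probe Render the probe tone too? Default `TRUE`.
#' @param on_overlap `"combine"` (default) or `"error"`.
#' @param pad Trailing silence in seconds after the last tone offset.
#' @return A list of class `"envelope_signal"`: `sample_rate`, `values`
#'   (normalized), `event_times` (rendered onsets, seconds).
#' @export
render_envelope <- function(trial, config, include_probe = TRUE,
                            on_overlap = c("combine", "error"), pad = 0.1) {
  on_overlap <- match.arg(on_overlap)
  onsets <- trial$cue_times[[1]]
  if (include_probe) onsets <- c(onsets, trial$probe_time)
  if (length(onsets) == 0) stop("cannot render an envelope with no tones")
  dur <- config$tone_duration_frac * mean_period(config)
  fs <- config$sample_rate
  t_end <- max(onsets) + dur + pad
  values <- normalize_envelope(render_onsets(onsets, dur, fs, t_end, on_overlap))
  structure(list(sample_rate = fs, values = values, event_times = onsets),
            class = "envelope_signal")
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf("<envelope_signal> %d samples @ %g Hz (%.2f s), %d tone onsets\n",
              length(x$values), x$sample_rate,
              length(x$values) / x$sample_rate, length(x$event_times)))
  invisible(x)
}

#' Concatenate trials into one session envelope
#'
#' Trials are placed on a single time grid; the gap between each trial's
#' probe slot and the first tone of the next trial is an inter-trial interval
#' drawn as `0.75 + U(-0.25, 0.25)` seconds. Returned offsets map trial-local
#' times (cue times, probe slot) into session time.
#'
#' @param trials Trial tibble from [draw_trials()] (at least one row).
#' @param config The generating [experiment_config()].
#' @param include_probe Render probe tones into the envelope? `FALSE` for
#'   oscillator sessions (the probe slot time is still tracked).
#' @param start_pad Silence before the first trial's first tone (seconds).
#' @param on_overlap Passed to the renderer.
#' @param seed Optional seed for the ITI draws.
#' @param pad_to_composite Pad the end with silence so the number of envelope
#'   samples has only small prime factors (fast FFTs downstream).
#' @return A list of class `"session_envelope"`: `envelope` (an
#'   `envelope_signal` holding the whole session), and `offsets`, a tibble
#'   with `trial_id`, `offset` (seconds added to trial-local times),
#'   `probe_slot_time` (session time of the probe slot), and `iti_after`.
#' @export
assemble_session <- function(trials, config, include_probe = TRUE,
                             start_pad = 0.5, on_overlap = c("combine", "error"),
                             seed = NULL, pad_to_composite = FALSE) {
  on_overlap <- match.arg(on_overlap)
  stopifnot(nrow(trials) >= 1)
  n <- nrow(trials)
  itis <- if (is.null(seed)) 0.75 + runif(n - 1, -0.25, 0.25) else
    withr::with_seed(seed, 0.75 + runif(n - 1, -0.25, 0.25))

  first_tone <- purrr::map_dbl(trials$cue_times, 1)
  offsets <- numeric(n)
  # first tone of trial 1 at start_pad (shifted if jitter made t_1 large)
  offsets[1] <- max(start_pad - first_tone[1], 0.01)
  if (n > 1) {
    for (j in 2:n) {
      probe_prev <- offsets[j - 1] + trials$probe_time[j - 1]
      offsets[j] <- probe_prev + itis[j - 1] - first_tone[j]
    }
  }
  dur <- config$tone_duration_frac * mean_period(config)
  onsets <- unlist(purrr::map2(trials$cue_times, offsets, `+`))
  if (include_probe) onsets <- c(onsets, trials$probe_time + offsets)
  fs <- config$sample_rate
  t_end <- max(onsets, trials$probe_time + offsets) + dur + 0.5
  n_samp <- ceiling(t_end * fs) + 1L
  if (pad_to_composite) t_end <- (nextn(n_samp, c(2L, 3L, 5L)) - 1L) / fs
  values <- normalize_envelope(render_onsets(sort(onsets), dur, fs, t_end, on_overlap))
  env <- structure(list(sample_rate = fs, values = values, event_times = sort(onsets)),
                   class = "envelope_signal")
  list(
    envelope = env,
    offsets = tibble::tibble(
      trial_id = trials$trial_id,
      offset = offsets,
      probe_slot_time = trials$probe_time + offsets,
      iti_after = c(itis, NA_real_)
    )
  )
}
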