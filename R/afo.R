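#' Adaptive-frequency oscillator parameters
#'
#' The AFO is the Wilson-Cowan core with `rho_i = -7` plus slow first-order
#' dynamics on the excitatory tonic input,
#' \deqn{\dot\rho_E = -0.045\,(\rho_E - \rho_0),}
#' where the target \eqn{\rho_0} is \eqn{-3.4} during silence and, during a
#' tone sequence, follows the rational map of the running mean inter-tone
#' interval \eqn{\langle t \rangle}
#' \deqn{\rho_0 = 0.45\,\langle t\rangle / (\langle t\rangle - 0.21) - 3.6,}
#' chosen so that the unforced system's natural period approximates
#' \eqn{\langle t \rangle}. The map has a pole at 0.21 s; the mean interval
#' is clamped to at least `period_clamp` (default 0.23 s) and the mapped
#' value capped at `rho0_cap` before use.
#'
#' @param wc Wilson-Cowan core parameters ([wc_params()]); `rho_i` is forced
#'   to -7 and the initial `rho_e` to `rho0_silence`.
#' @param adapt_rate Adaptation rate, 1/s (default 0.045; e-fold time 22 s,
#'   so adaptation is partial within a trial and carries across trials).
#' @param rho0_silence Target during silence (default -3.4, just below the
#'   oscillation threshold).
#' @param rho0_map Constants `(c1, c2, c3)` of the map
#'   `c1 * t / (t - c2) - c3` (default `c(0.45, 0.21, 3.6)`).
#' @param period_clamp Minimum admissible mean interval before the map, s.
#' @param rho0_cap Upper cap on the mapped target.
#' @param iti_target Target during the silent gaps between trials:
#'   `"hold"` (default) keeps the previous trial's final estimate through
#'   the gap, resuming it at the next first tone — the learned rate is
#'   retained between trials; `"silence"` returns to the rest target -3.4
#'   from each probe slot until the next trial's second tone. Both carry
#'   cross-trial rate memory through the never-reset `rho_e`.
#' @return A list of class `"afo_params"`.
#' @export
afo_params <- function(wc = wc_params(), adapt_rate = 0.045,
                       rho0_silence = -3.4,
                       rho0_map = c(0.45, 0.21, 3.6),
                       period_clamp = 0.23, rho0_cap = 2,
                       iti_target = c("hold", "silence")) {
  stopifnot(adapt_rate > 0, length(rho0_map) == 3)
  wc$rho_i <- -7
  wc$rho_e <- rho0_silence
  structure(list(wc = wc, adapt_rate = adapt_rate,
                 rho0_silence = rho0_silence, rho0_map = rho0_map,
                 period_clamp = period_clamp, rho0_cap = rho0_cap,
                 iti_target = match.arg(iti_target)),
            class = "afo_params")
}

#' Map a perceived period to the tonic-input target
#'
#' `rho0 = c1 * t / (t - c2) - c3` with defaults `(0.45, 0.21, 3.6)`. Its
#' asymptote for slow rhythms, `c1 - c3 = -3.15`, sits just above the
#' oscillation threshold near -3.16, so any finite perceived period maps
#' into the oscillatory regime. Intervals at or below the clamp (the 4 Hz
#' condition approaches the pole at 0.21 s) are clamped with a warning.
#'
#' @param mean_interval Perceived mean inter-tone interval(s), seconds.
#' @param params An [afo_params()].
#' @return Target value(s) for `rho_e`.
#' @export
#' @examples
#' rho0_of_period(0.25) # 0.1125/0.04 - 3.6 = -0.7875
rho0_of_period <- function(mean_interval, params = afo_params()) {
  cl <- params$period_clamp
  if (any(mean_interval < cl)) {
    warning(sprintf("mean interval below %.2f s clamped before the rho0 map", cl))
    mean_interval <- pmax(mean_interval, cl)
  }
  m <- params$rho0_map
  pmin(m[1] * mean_interval / (mean_interval - m[2]) - m[3], params$rho0_cap)
}

#' Running mean of inter-onset intervals
#'
#' The perceived-period estimate the AFO tracks: after each tone from the
#' second onward, the mean of all intervals since the start of the trial.
#' Streaming and batch forms agree: after tone `j`, the estimate is
#' `(t_j - t_1) / (j - 1)`.
#'
#' @param onsets Increasing tone-onset times within one trial, seconds.
#' @return Numeric vector, one estimate per onset; `NA` for the first tone.
#' @export
#' @examples
#' running_mean_interval(c(0, 0.4, 0.8)) # NA, 0.4, 0.4
running_mean_interval <- function(onsets) {
  n <- length(onsets)
  if (n == 0) return(numeric(0))
  c(NA_real_, (onsets[-1] - onsets[1]) / seq_len(n - 1))
}

# piecewise-constant rho0 series over a session grid.
# Silence value before the first trial and during each inter-trial interval
# (probe slot to next first tone). During sound, the running-mean map of the
# current trial's intervals, actualized right after each tone; between a
# trial's first and second tone the previous trial's final estimate carries
# over (no estimate exists yet -- this is the cross-trial rate memory in the
# target; rho_e itself is additionally never reset).
session_rho0 <- function(trials, offsets, params, dt, n_steps) {
  warned <- FALSE
  map_safe <- function(x) withCallingHandlers(
    rho0_of_period(x, params),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  hold <- identical(params$iti_target, "hold")
  upd_t <- numeric(0)
  upd_v <- numeric(0)
  carry <- params$rho0_silence
  for (j in seq_len(nrow(trials))) {
    cue <- trials$cue_times[[j]] + offsets$offset[j]
    est <- running_mean_interval(trials$cue_times[[j]])
    vals <- map_safe(est[-1])
    if (hold) {
      # previous estimate resumes at the first tone, held through the gap
      upd_t <- c(upd_t, cue[1], cue[-1], offsets$probe_slot_time[j])
      upd_v <- c(upd_v, carry, vals, carry <- vals[length(vals)])
    } else {
      # rest target from the probe slot until the next second tone
      upd_t <- c(upd_t, cue[-1], offsets$probe_slot_time[j])
      upd_v <- c(upd_v, vals, params$rho0_silence)
    }
  }
  if (warned)
    message("rho0 map clamp active for some intervals (near the 0.21 s pole)")
  ord <- order(upd_t)
  idx <- pmin(pmax(round(upd_t[ord] / dt) + 1L, 1L), n_steps)
  breaks <- c(1L, idx, n_steps + 1L)
  out <- rep(c(params$rho0_silence, upd_v[ord]), pmax(diff(breaks), 0))
  length(out) <- n_steps
  out
}

#' Simulate one AFO session
#'
#' Integrates the adaptive oscillator continuously over a whole session of
#' trials (probe tones are not rendered into the envelope). `rho_e` is never
#' reset: it relaxes toward the running-mean map target, which is updated at
#' each tone and held through probe waits and inter-trial intervals, so the
#' slow dynamics carry rate memory across trials. The phase of the excitatory activity
#' (analytic signal over the full session) is read out at each trial's
#' drawn probe time.
#'
#' @param trials Trial tibble from [draw_trials()].
#' @param k Stimulus coupling gain for this simulated participant.
#' @param params An [afo_params()].
#' @param config The generating [experiment_config()].
#' @param seed Optional seed for the ITI draws.
#' @param keep_trace Return the (1 kHz) oscillator trace as well?
#' @param probe_phase_at Where to read the phase: `"drawn"` (default) reads
#'   at the jittered probe time that would have been presented, so the phase
#'   expresses the oscillator's own early/late judgment of that moment;
#'   `"slot"` reads at the expected location `T (I + 1)` on the underlying
#'   grid, keeping the probe's own jitter out of the phase.
#' @return A list: `phases` (tibble `trial_id`, `probe_slot_time`,
#'   `phase`), and optionally `trace`.
#' @export
simulate_afo_session <- function(trials, k, params = afo_params(), config,
                                 seed = NULL, keep_trace = FALSE,
                                 probe_phase_at = c("drawn", "slot")) {
  probe_phase_at <- match.arg(probe_phase_at)
  ses <- assemble_session(trials, config, include_probe = FALSE, seed = seed)
  dt <- params$wc$dt
  stopifnot(abs(config$sample_rate * dt - 1) < 1e-9)
  stim <- ses$envelope$values
  # pad with silence so the recorded-trace length has only small prime
  # factors (the analytic-signal FFT is O(n log n) only then)
  rec_n <- nextn(ceiling(length(stim) / 10), c(2L, 3L, 5L))
  n_steps <- 10L * rec_n
  stim <- c(stim, rep(min(stim), n_steps - length(stim)))
  rho0 <- session_rho0(trials, ses$offsets, params, dt, n_steps)
  wc <- params$wc
  wc$k <- k
  tr <- wc_integrate(wc, stim = stim,
                     duration = n_steps * dt,
                     rho0 = rho0, adapt_rate = params$adapt_rate,
                     record_every = 10)
  dt_rec <- attr(tr, "dt_record")
  phase <- extract_phase(tr$E)
  read_t <- if (probe_phase_at == "drawn") ses$offsets$probe_slot_time else
    ses$offsets$offset + trials$base_period * (trials$n_tones + 1)
  idx <- pmin(length(phase), pmax(1, round(read_t / dt_rec) + 1))
  out <- list(phases = tibble::tibble(
    trial_id = ses$offsets$trial_id,
    probe_slot_time = ses$offsets$probe_slot_time,
    read_time = read_t,
    phase = phase[idx],
    rho_e = tr$rho_e[idx]
  ))
  if (keep_trace) out$trace <- tr
  out
}

#' Simulate an AFO cohort
#'
#' One simulated participant = one coupling gain `k ~ 0.2 + U(0, 0.1)` and a
#' fresh set of trials. For each participant the AFO session is integrated,
#' the probe-slot phase extracted per trial, objective early/late labels
#' computed from the drawn probe time against each timing algorithm's
#' prediction, and a circular logistic fit (label on `(cos, sin)` of phase)
#' performed per algorithm. Noisy participants are flagged by the
#' chi-square exclusion rule.
#'
#' @param config An [experiment_config()] (the condition).
#' @param n_participants Cohort size (default 60, the published scale).
#' @param n_trials Trials per participant (default 300).
#' @param params An [afo_params()].
#' @param seed Seed for the whole cohort (trials, k draws, ITIs).
#' @param probe_phase_at Phase readout convention, see
#'   [simulate_afo_session()].
#' @return A subject-summary tibble: `subject_id`, `condition`, `k`,
#'   `slope_abs`, `slope_rel`, `chi2_p_abs`, `chi2_p_rel`, `excluded`,
#'   `slope_sum`, `slope_diff`.
#' @export
run_afo_cohort <- function(config, n_participants = 60, n_trials = 300,
                           params = afo_params(), seed = NULL,
                           probe_phase_at = c("drawn", "slot")) {
  probe_phase_at <- match.arg(probe_phase_at)
  run <- function() {
    purrr::map_dfr(seq_len(n_participants), function(s) {
      k <- 0.2 + runif(1, 0, 0.1)
      trials <- score_trials(draw_trials(config, n_trials))
      ses <- simulate_afo_session(trials, k, params, config,
                                  probe_phase_at = probe_phase_at)
      fa <- fit_logistic_circular(ses$phases$phase, trials$label_absolute)
      fr <- fit_logistic_circular(ses$phases$phase, trials$label_relative)
      tibble::tibble(subject_id = s, condition = config$condition_name, k = k,
                     slope_abs = fa$slope, slope_rel = fr$slope,
                     chi2_p_abs = fa$chi2_p, chi2_p_rel = fr$chi2_p)
    })
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  add_rotated_axes(exclude_noisy(out))
}

#' Scan the oscillation onset and fit the period map
#'
#' Measures the natural period over a grid of `rho_e` (optionally refining
#' around the onset), locates the smallest `rho_e` with sustained
#' oscillation (the SNIC bifurcation), and fits the rational form
#' `rho_e = c1 * p / (p - c2) + c3` to the (period, rho_e) pairs with
#' period at most `fit_max_period`.
#'
#' @param rho_grid Coarse `rho_e` grid (default -3.3 to -2.9 by 0.02,
#'   extended sparsely up to 0 for the map fit).
#' @param params Base [wc_params()] with `rho_i = -7`.
#' @param refine_step Refinement step around the onset (default 0.005; set
#'   `NULL` to skip).
#' @param window,transient Passed to [natural_period()].
#' @param fit_max_period Longest period used in the rational fit, seconds.
#' @return A list of class `"bifurcation_scan"`: `table` (tibble `rho_e`,
#'   `period`), `onset` (smallest oscillating `rho_e`), `fit` (the `nls`
#'   object or `NULL`), `map_constants` (`c1`, `c2`, `c3`).
#' @export
scan_bifurcation <- function(rho_grid = c(seq(-3.3, -2.9, by = 0.02),
                                          seq(-2.8, -1.2, by = 0.2), -0.6, 0),
                             params = wc_params(rho_i = -7),
                             refine_step = 0.005,
                             window = 60, transient = 5,
                             fit_max_period = 1.2) {
  measure <- function(rho) {
    p <- params; p$rho_e <- rho
    natural_period(p, window = window, transient = transient)
  }
  rho_grid <- sort(rho_grid)
  periods <- purrr::map_dbl(rho_grid, measure)
  if (all(is.na(periods))) stop("no oscillation detected anywhere on the grid")
  onset <- min(rho_grid[!is.na(periods)])
  if (!is.null(refine_step)) {
    below <- rho_grid[rho_grid < onset]
    if (length(below) > 0) {
      lo <- max(below)
      fine <- seq(lo + refine_step, onset - refine_step / 2, by = refine_step)
      if (length(fine) > 0) {
        fine_p <- purrr::map_dbl(fine, measure)
        rho_grid <- c(rho_grid, fine)
        periods <- c(periods, fine_p)
        if (any(!is.na(fine_p))) onset <- min(fine[!is.na(fine_p)])
      }
    }
  }
  tab <- dplyr::arrange(tibble::tibble(rho_e = rho_grid, period = periods),
                        .data$rho_e)
  fit_tab <- dplyr::filter(tab, !is.na(.data$period),
                           .data$period <= fit_max_period)
  fit <- NULL
  consts <- c(c1 = NA_real_, c2 = NA_real_, c3 = NA_real_)
  if (nrow(fit_tab) >= 5) {
    # same parametrization as rho_e = c1 p/(p - c2) + c3, but the residuals
    # are taken on the period (the quantity the map must reproduce; a fit on
    # rho_e residuals is degenerate near the onset where rho_e is flat in p)
    fit <- minpack.lm::nlsLM(
      period ~ c2 * (rho_e - c3) / (rho_e - c3 - c1), data = fit_tab,
      start = list(c1 = 0.45, c2 = 0.21, c3 = -3.6),
      control = minpack.lm::nls.lm.control(maxiter = 300))
    consts <- stats::setNames(coef(fit), c("c1", "c2", "c3"))
  }
  structure(list(table = tab, onset = onset, fit = fit,
                 map_constants = consts),
            class = "bifurcation_scan")
}

#' @export
print.bifurcation_scan <- function(x, ...) {
  cat(sprintf("<bifurcation_scan> oscillation onset at rho_e = %.3f\n", x$onset))
  if (!is.null(x$fit))
    cat(sprintf("  rational map fit: rho_e = %.3f p/(p - %.3f) + %.3f\n",
                x$map_constants[1], x$map_constants[2], x$map_constants[3]))
  invisible(x)
}

#' @rdname scan_bifurcation
#' @param object A `bifurcation_scan`.
#' @param ... Unused.
#' @export
autoplot.bifurcation_scan <- function(object, ...) {
  tab <- dplyr::filter(object$table, !is.na(.data$period))
  p <- ggplot2::ggplot(tab, ggplot2::aes(.data$period, .data$rho_e)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$onset, linetype = 2) +
    ggplot2::labs(x = "natural period (s)", y = expression(rho[E]))
  if (!is.null(object$fit)) {
    cc <- object$map_constants
    grid <- tibble::tibble(period = seq(min(tab$period), max(tab$period),
                                        length.out = 200))
    grid$rho_e <- cc[1] * grid$period / (grid$period - cc[2]) + cc[3]
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}
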