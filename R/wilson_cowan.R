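#' Wilson-Cowan model parameters
#'
#' The two-population neural mass model
#' \deqn{\tau \dot E = -E + S(\rho_E + cE - aI + k\,Stim)}
#' \deqn{\tau \dot I = -I + S(\rho_I + bE - gI)}
#' with logistic `S`. Defaults are the values used throughout: synaptic
#' couplings `a = b = c = 10`, `g = -2`, membrane time constant
#' `tau = 1/17` s, Euler step `dt = 1e-4` s. The tonic inputs `rho_e`,
#' `rho_i` select the dynamical regime: `(1.6, -2.9)` is the fixed-frequency
#' "classic" oscillator near a Hopf bifurcation; `rho_i = -7` with `rho_e`
#' scanned crosses a SNIC bifurcation near `rho_e = -3.16`.
#'
#' @param a,b,c,g Synaptic couplings.
#' @param tau Membrane time constant, seconds.
#' @param rho_e,rho_i Tonic inputs.
#' @param k Stimulus coupling gain.
#' @param dt Euler step, seconds (must satisfy `dt <= tau / 50`).
#' @return A list of class `"wc_params"`.
#' @export
#' @examples
#' wc_params(rho_e = 1.6, rho_i = -2.9) # classic oscillator
wc_params <- function(a = 10, b = 10, c = 10, g = -2, tau = 1 / 17,
                      rho_e = -3.4, rho_i = -7, k = 1, dt = 1e-4) {
  stopifnot(tau > 0, dt > 0)
  if (dt > tau / 50) stop("dt must be <= tau / 50 for a stable Euler step")
  structure(list(a = a, b = b, c = c, g = g, tau = tau,
                 rho_e = rho_e, rho_i = rho_i, k = k, dt = dt),
            class = "wc_params")
}

#' Logistic sigmoid
#'
#' `S(x) = 1 / (1 + exp(-x))`, the saturating response function of both
#' populations.
#' @param x Numeric.
#' @return Values in (0, 1).
#' @export
wc_sigmoid <- function(x) 1 / (1 + exp(-x))

#' Integrate the Wilson-Cowan system
#'
#' Forward-Euler integration (compiled) of the two-population model, with an
#' optional stimulus envelope driving the excitatory population and optional
#' first-order adaptation of `rho_e` toward a (piecewise-constant) target
#' `rho0`. Deterministic given the initial state.
#'
#' @param params A [wc_params()].
#' @param stim An `envelope_signal`, a numeric vector on the `dt` grid, or
#'   `NULL` for no stimulus. An envelope's sample rate must equal `1/dt`.
#' @param duration Seconds to integrate; defaults to the stimulus length.
#' @param init Initial `(E, I)` state, default `c(0.25, 0.25)`.
#' @param record_every Record state every this many Euler steps (default 10,
#'   i.e. a 1 kHz trace for `dt = 1e-4`).
#' @param rho0 Adaptation target for `rho_e`: scalar or vector on the `dt`
#'   grid. Ignored when `adapt_rate = 0`.
#' @param adapt_rate Adaptation rate (1/s), default 0 (fixed `rho_e`).
#' @return A tibble of class `"oscillator_trace"` with columns `time`, `E`,
#'   `I`, `rho_e`, and attributes `params`, `dt_record`, `final_state`.
#' @export
#' @examples
#' tr <- wc_integrate(wc_params(rho_e = -3.0), duration = 3)
#' range(tr$E)
wc_integrate <- function(params, stim = NULL, duration = NULL,
                         init = c(0.25, 0.25), record_every = 10,
                         rho0 = params$rho_e, adapt_rate = 0) {
  if (inherits(stim, "envelope_signal")) {
    if (abs(stim$sample_rate * params$dt - 1) > 1e-9)
      stop("stimulus sample rate must equal 1/dt")
    stim <- stim$values
  }
  if (is.null(stim)) stim <- 0
  if (is.null(duration)) {
    if (length(stim) <= 1) stop("`duration` required when no stimulus grid is given")
    duration <- length(stim) * params$dt
  }
  n_steps <- max(2L, round(duration / params$dt))
  res <- wc_euler_cpp(n_steps, params$dt, params$a, params$b, params$c,
                      params$g, params$tau, params$k, params$rho_i,
                      params$rho_e, as.numeric(stim), as.numeric(rho0),
                      adapt_rate, init[1], init[2], as.integer(record_every))
  dt_rec <- params$dt * record_every
  out <- tibble::tibble(
    time = (seq_along(res$E) - 1) * dt_rec,
    E = res$E, I = res$I, rho_e = res$rho_e
  )
  attr(out, "params") <- params
  attr(out, "dt_record") <- dt_rec
  attr(out, "final_state") <- c(E = res$E_final, I = res$I_final,
                                rho_e = res$rho_e_final)
  class(out) <- c("oscillator_trace", class(out))
  out
}

#' @export
autoplot.oscillator_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("E", "I", "rho_e"),
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

# indices of E peaks: local maxima with prominence >= 10% of signal range.
# Prominence is measured against the deepest troughs separating a peak from
# its neighbouring local maxima (adequate for smooth oscillatory traces).
find_e_peaks <- function(E, min_prominence_frac = 0.1) {
  rng <- diff(range(E))
  if (rng < .Machine$double.eps) return(integer(0))
  pk <- pracma::findpeaks(E)
  if (is.null(pk)) return(integer(0))
  idx <- sort(pk[, 2])
  bounds <- c(1L, idx, length(E))
  prom <- vapply(seq_along(idx), function(i) {
    left <- min(E[bounds[i]:idx[i]])
    right <- min(E[idx[i]:bounds[i + 2]])
    E[idx[i]] - max(left, right)
  }, numeric(1))
  idx[prom >= min_prominence_frac * rng]
}

#' Natural period of the unforced oscillator
#'
#' Integrates the model without stimulus and returns the mean inter-peak
#' interval of the excitatory activity after discarding a transient, or `NA`
#' if no sustained oscillation is detected within the window (fewer than
#' three peaks, or peak-to-peak amplitude below `amp_tol`).
#'
#' @param params A [wc_params()] (the stimulus gain is ignored).
#' @param window Integration window, seconds (default 60).
#' @param transient Transient to discard, seconds (default 5).
#' @param init Initial state.
#' @param amp_tol Minimum peak-to-peak E amplitude to count as oscillation.
#' @return Period in seconds, or `NA_real_`.
#' @export
#' @examples
#' natural_period(wc_params(rho_e = -2.0), window = 20)
natural_period <- function(params, window = 60, transient = 5,
                           init = c(0.25, 0.25), amp_tol = 0.01) {
  tr <- wc_integrate(params, duration = window, init = init)
  dt_rec <- attr(tr, "dt_record")
  E <- tr$E[tr$time >= transient]
  if (diff(range(E)) < amp_tol) return(NA_real_)
  pk <- find_e_peaks(E)
  if (length(pk) < 3) return(NA_real_)
  mean(diff(pk)) * dt_rec
}

# analytic signal via FFT: x + i H[x]
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of the excitatory activity
#'
#' Phase of the analytic signal (FFT-based Hilbert transform) of the
#' mean-removed series. With this convention the phase is near 0 at E
#' maxima and increases through the cycle.
#'
#' @param x Numeric series (an `oscillator_trace`'s `E` column), at least a
#'   few cycles long and non-constant.
#' @return Phase in radians, wrapped to `(-pi, pi]`.
#' @export
extract_phase <- function(x) {
  if (inherits(x, "oscillator_trace")) x <- x$E
  if (diff(range(x)) < .Machine$double.eps)
    stop("cannot extract phase from a constant series")
  Arg(analytic_signal(x - mean(x)))
}

#' Phase concentration (mean resultant length)
#'
#' `PC = |mean(exp(i theta))|`: 1 when all phases coincide, near 0 for
#' uniformly scattered phases.
#'
#' @param phases Phases in radians (non-empty).
#' @return Value in `[0, 1]`.
#' @export
#' @examples
#' phase_concentration(c(0, 0, 0))    # 1
#' phase_concentration(c(0, pi))      # 0
phase_concentration <- function(phases) {
  if (length(phases) == 0) stop("no phases supplied")
  Mod(mean(exp(1i * phases)))
}

#' Phase response curve of the driven oscillator
#'
#' A reference oscillator is run from a frozen start for four cycles; a
#' perturbed copy receives a single tone whose onset roves across the second
#' cycle in 1 ms steps. The PRC value at each onset is the mean phase
#' difference (perturbed minus reference) over the fourth cycle, reported
#' against the reference phase at stimulus onset.
#'
#' @param params A [wc_params()] in an oscillatory regime.
#' @param k_values Stimulus coupling gains to evaluate.
#' @param tone_duration Tone length in seconds (default 0.1, a 4 Hz tone).
#' @param init Frozen start state.
#' @return A tibble: `k`, `onset_time`, `onset_phase`, `phase_shift`.
#' @export
phase_response_curve <- function(params,
                                 k_values = c(0.02, seq(0.1, 1.0, by = 0.1)),
                                 tone_duration = 0.1, init = c(0.25, 0.25)) {
  p0 <- natural_period(params, window = 20, transient = 2, init = init)
  if (is.na(p0)) stop("parameters are not in an oscillatory regime")
  dt <- params$dt
  # settle onto the limit cycle, then freeze that state as the start point
  settle <- wc_integrate(params, duration = 2 + 3 * p0, init = init,
                         record_every = 10)
  fs <- attr(settle, "final_state")
  init <- c(fs[["E"]], fs[["I"]])
  run_t <- 5.5 * p0 + tone_duration
  n <- round(run_t / dt)
  ref <- wc_integrate(params, stim = numeric(n), duration = run_t,
                      init = init, record_every = 1)
  ref_phase <- extract_phase(ref$E)
  # cycle boundaries from reference peaks
  pk <- find_e_peaks(ref$E)
  if (length(pk) < 5) stop("reference run too short to delimit four cycles")
  cyc2 <- c(pk[2], pk[3])  # second cycle, samples
  cyc4 <- c(pk[4], pk[5])  # fourth cycle
  onsets <- seq(cyc2[1], cyc2[2], by = max(1L, round(0.001 / dt)))
  shape <- tone_shape(tone_duration, 1 / dt)

  purrr::map_dfr(k_values, function(k) {
    pk_par <- wc_params(a = params$a, b = params$b, c = params$c,
                        g = params$g, tau = params$tau, rho_e = params$rho_e,
                        rho_i = params$rho_i, k = k, dt = dt)
    shift <- purrr::map_dbl(onsets, function(i0) {
      stim <- numeric(n)
      idx <- i0:min(i0 + length(shape) - 1L, n)
      stim[idx] <- shape[seq_along(idx)]
      pert <- wc_integrate(pk_par, stim = stim, duration = run_t,
                           init = init, record_every = 1)
      dphi <- Arg(exp(1i * (extract_phase(pert$E)[cyc4[1]:cyc4[2]] -
                              ref_phase[cyc4[1]:cyc4[2]])))
      mean(dphi)
    })
    tibble::tibble(k = k, onset_time = (onsets - 1) * dt,
                   onset_phase = ref_phase[onsets], phase_shift = shift)
  })
}

#' Phase concentration at algorithm-predicted probe times
#'
#' Drives a fixed-frequency ("classic") oscillator with many independent
#' trials and measures how concentrated its phase is at the probe time
#' predicted by each timing algorithm. A permutation test (trial-label
#' shuffles are not meaningful here, so phases are compared by randomly
#' swapping each trial's ABS/REL phase pair) assesses whether the two
#' algorithms differ in concentration; when several coupling gains are
#' scanned the p-values are BH-FDR corrected.
#'
#' @param params Classic-oscillator [wc_params()] (e.g. `rho_e = 1.6`,
#'   `rho_i = -2.9`).
#' @param config An [experiment_config()] supplying the trial statistics;
#'   use `period_bounds` to restrict the rate range.
#' @param k_values Coupling gains to scan.
#' @param n_trials Trials per gain (default 300).
#' @param n_perm Permutation draws (default 10000).
#' @param seed Optional seed.
#' @return A tibble: `k`, `pc_abs`, `pc_rel`, `pc_diff`, `p_perm`,
#'   `p_fdr`.
#' @export
concentration_at_predictions <- function(params, config, k_values = 0.3,
                                         n_trials = 300, n_perm = 10000,
                                         seed = NULL) {
  run <- function() {
    trials <- score_trials(draw_trials(config, n_trials))
    purrr::map_dfr(k_values, function(k) {
      ph <- purrr::pmap_dfr(
        list(trials$cue_times, trials$pred_absolute, trials$pred_relative),
        function(cue, pa, pr) {
          env <- render_envelope(
            tibble::tibble(cue_times = list(cue),
                           probe_time = max(pa, pr) + 0.5),
            config, include_probe = FALSE)
          pk_par <- wc_params(a = params$a, b = params$b, c = params$c,
                              g = params$g, tau = params$tau,
                              rho_e = params$rho_e, rho_i = params$rho_i,
                              k = k, dt = params$dt)
          dur <- max(pa, pr) + 0.2
          nstep <- round(dur / pk_par$dt)
          stim <- env$values
          if (length(stim) < nstep)  # extend with the silent baseline
            stim <- c(stim, rep(min(stim), nstep - length(stim)))
          tr <- wc_integrate(pk_par, stim = stim[seq_len(nstep)],
                             duration = dur, record_every = 10)
          phase <- extract_phase(tr$E)
          dt_rec <- attr(tr, "dt_record")
          at <- function(t) phase[pmin(length(phase), pmax(1, round(t / dt_rec) + 1))]
          tibble::tibble(phase_abs = at(pa), phase_rel = at(pr))
        })
      pc_abs <- phase_concentration(ph$phase_abs)
      pc_rel <- phase_concentration(ph$phase_rel)
      obs <- pc_abs - pc_rel
      # null: ABS/REL assignment exchangeable within trial
      perm <- replicate(n_perm, {
        swap <- runif(nrow(ph)) < 0.5
        a <- ifelse(swap, ph$phase_rel, ph$phase_abs)
        r <- ifelse(swap, ph$phase_abs, ph$phase_rel)
        phase_concentration(a) - phase_concentration(r)
      })
      p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm)
      tibble::tibble(k = k, pc_abs = pc_abs, pc_rel = pc_rel,
                     pc_diff = obs, p_perm = p)
    })
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out$p_fdr <- p.adjust(out$p_perm, "BH")
  out
}
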