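#' Relative (rhythm-based) prediction of the next tone time
#'
#' Ordinary least squares of tone times on tone index (with intercept),
#' evaluated at index `I + 1`: the listener reconstructs the underlying
#' isochronous grid and extrapolates it one slot.
#'
#' @param cue_times Numeric vector of cue-tone times in seconds (>= 2).
#' @return Predicted probe time in seconds.
#' @export
#' @examples
#' predict_relative(c(0.5, 1.0, 1.5)) # exact line -> 2.0
predict_relative <- function(cue_times) {
  n <- length(cue_times)
  if (n < 2) stop("relative prediction needs at least 2 cue tones")
  i <- seq_len(n)
  b <- cov(i, cue_times) / var(i)
  a <- mean(cue_times) - b * mean(i)
  a + b * (n + 1)
}

#' Absolute (duration-based) prediction of the next tone time
#'
#' Averages the observed inter-tone intervals and adds the mean interval to
#' the last tone's time. By telescoping this equals
#' `t_I + (t_I - t_1) / (I - 1)`, so the last tone's jitter propagates fully
#' into the prediction ("drift").
#'
#' @inheritParams predict_relative
#' @return Predicted probe time in seconds.
#' @export
#' @examples
#' predict_absolute(c(0, 1.0, 1.2)) # 1.2 + mean interval 0.6 -> 1.8
predict_absolute <- function(cue_times) {
  n <- length(cue_times)
  if (n < 2) stop("absolute prediction needs at least 2 cue tones")
  cue_times[n] + mean(diff(cue_times))
}

#' Score trials against both timing algorithms
#'
#' For each trial, computes the relative and absolute predictions of the
#' probe time, the probe deviations `t_probe - prediction`, their
#' normalization by the trial's mean realized stimulus onset asynchrony
#' (SOA), and the objective early/late label per algorithm (0 = probe before
#' the prediction, 1 = after). A deviation of exactly zero is labelled late
#' with a warning (measure-zero tie-break).
#'
#' @param trials Trial tibble from [draw_trials()].
#' @param soa Normalize by the `"realized"` mean interval of the trial
#'   (default) or by the `"base"` period `T` (sensitivity analysis).
#' @return `trials` with columns `pred_relative`, `pred_absolute`,
#'   `dev_relative`, `dev_absolute`, `dev_relative_norm`, `dev_absolute_norm`,
#'   `label_relative`, `label_absolute` appended.
#' @export
#' @examples
#' trials <- draw_trials(experiment_config("4hz"), n_trials = 3, seed = 1)
#' score_trials(trials)[, c("dev_relative_norm", "label_relative")]
score_trials <- function(trials, soa = c("realized", "base")) {
  soa <- match.arg(soa)
  pred_rel <- purrr::map_dbl(trials$cue_times, predict_relative)
  pred_abs <- purrr::map_dbl(trials$cue_times, predict_absolute)
  mean_soa <- switch(soa,
    realized = purrr::map_dbl(trials$cue_times, ~ mean(diff(.x))),
    base = trials$base_period
  )
  out <- dplyr::mutate(trials,
    pred_relative = pred_rel,
    pred_absolute = pred_abs,
    dev_relative = .data$probe_time - pred_rel,
    dev_absolute = .data$probe_time - pred_abs,
    dev_relative_norm = .data$dev_relative / mean_soa,
    dev_absolute_norm = .data$dev_absolute / mean_soa
  )
  if (any(out$dev_relative == 0 | out$dev_absolute == 0))
    warning("probe exactly at a predicted time; tie-broken to 'late'")
  dplyr::mutate(out,
    label_relative = as.integer(.data$dev_relative >= 0),
    label_absolute = as.integer(.data$dev_absolute >= 0)
  )
}
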