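#' Gaussian belief about a tone's time
#'
#' Priors, likelihoods and posteriors in the ideal observer are all Gaussian
#' beliefs `(mu, sigma)` over a tone's time. A flat (uninformative) prior is
#' represented exactly by `sigma = Inf` (zero precision), never by a large
#' finite value.
#'
#' @param mu Mean, seconds.
#' @param sigma SD, seconds (> 0, or `Inf` for a flat belief).
#' @param kind `"prior"`, `"likelihood"` or `"posterior"`.
#' @param tone_index Optional 1-based tone index.
#' @return A list of class `"gaussian_estimate"`.
#' @export
gaussian_estimate <- function(mu, sigma, kind = c("likelihood", "prior", "posterior"),
                              tone_index = NA_integer_) {
  kind <- match.arg(kind)
  if (!is.infinite(sigma) && sigma <= 0) stop("sigma must be positive (or Inf for flat)")
  if (is.infinite(sigma) && is.na(mu)) mu <- NA_real_
  structure(list(mu = mu, sigma = sigma, kind = kind, tone_index = tone_index),
            class = "gaussian_estimate")
}

#' @export
print.gaussian_estimate <- function(x, ...) {
  cat(sprintf("<gaussian_estimate %s> mu = %s, sigma = %s\n", x$kind,
              format(x$mu), format(x$sigma)))
  invisible(x)
}

is_flat <- function(g) is.infinite(g$sigma)

#' Fuse a prior and a likelihood by precision weighting
#'
#' The posterior of a product of two Gaussian densities: precision is the
#' sum of precisions, mean the precision-weighted mean,
#' \deqn{\mu_e = \frac{\mu_p/\sigma_p^2 + \mu_s/\sigma_s^2}
#'                    {1/\sigma_p^2 + 1/\sigma_s^2}, \qquad
#'       \sigma_e^2 = \frac{1}{1/\sigma_p^2 + 1/\sigma_s^2}.}
#' A flat prior returns the likelihood unchanged.
#'
#' @param prior,likelihood [gaussian_estimate()] objects (prior may be flat).
#' @return A posterior `gaussian_estimate`.
#' @export
#' @examples
#' fuse(gaussian_estimate(0, 1, "prior"), gaussian_estimate(1, 1))
fuse <- function(prior, likelihood) {
  if (is_flat(prior) && is_flat(likelihood))
    stop("cannot fuse two flat beliefs")
  if (is_flat(prior))
    return(gaussian_estimate(likelihood$mu, likelihood$sigma, "posterior",
                             likelihood$tone_index))
  if (is_flat(likelihood))
    return(gaussian_estimate(prior$mu, prior$sigma, "posterior",
                             prior$tone_index))
  wp <- 1 / prior$sigma^2
  ws <- 1 / likelihood$sigma^2
  gaussian_estimate((prior$mu * wp + likelihood$mu * ws) / (wp + ws),
                    sqrt(1 / (wp + ws)), "posterior", likelihood$tone_index)
}

#' Relative (rhythm-based) prior for tone i
#'
#' Through-origin weighted linear regression of the posterior means of tones
#' `1 .. i-1` on their indices (weights = posterior precisions), extrapolated
#' to index `i`; time zero is the start of the first tone. With running
#' index `n`,
#' \deqn{\mu_{p,i} = i\,\frac{\sum_n n\,\mu_{e,n}/\sigma_{e,n}^2}
#'                           {\sum_n n^2/\sigma_{e,n}^2}, \qquad
#'       \sigma_{p,i}^2 = \frac{i^2}{\sum_n n^2/\sigma_{e,n}^2}
#'                        + \sigma_{exp}^2,}
#' where \eqn{\sigma_{exp}} is the known per-tone jitter of the experiment,
#' which caps the achievable prior precision. For `i < 3` the prior is flat.
#'
#' @param mu_e,sigma_e Posterior means and SDs of tones `1 .. i-1`.
#' @param sigma_exp Experiment jitter SD, seconds.
#' @param i Index of the tone being predicted.
#' @return A `gaussian_estimate` of kind `"prior"`.
#' @export
relative_prior <- function(mu_e, sigma_e, sigma_exp, i) {
  if (i < 3) return(gaussian_estimate(NA_real_, Inf, "prior", i))
  n <- seq_len(i - 1)
  stopifnot(length(mu_e) >= i - 1, length(sigma_e) >= i - 1)
  w <- 1 / sigma_e[n]^2
  denom <- sum(n^2 * w)
  mu_p <- i * sum(n * mu_e[n] * w) / denom
  gaussian_estimate(mu_p, sqrt(i^2 / denom + sigma_exp^2), "prior", i)
}

#' Absolute (duration-based) prior for tone i
#'
#' The mean of the `i - 2` observed inter-tone intervals added to the last
#' posterior mean,
#' \deqn{\mu_{p,i} = \frac{\sum_{n=1}^{i-2} (\mu_{e,n+1}-\mu_{e,n})}{i-2}
#'                   + \mu_{e,i-1}
#'                 = \frac{\mu_{e,i-1}-\mu_{e,1}}{i-2} + \mu_{e,i-1}.}
#' The variance sums the interval variances with the covariance corrections
#' for shared neighbours and for the mean interval sharing the last tone:
#' \deqn{\sigma_{p,i}^2 =
#'   \frac{\sum_{n=1}^{i-2}(\sigma_{e,n+1}^2+\sigma_{e,n}^2)
#'         - 2\sum_{n=2}^{i-2}\sigma_{e,n}^2}{(i-2)^2}
#'   + \sigma_{e,i-1}^2 + \frac{2\sigma_{e,i-1}^2}{i-2} + \sigma_{exp}^2,}
#' which telescopes to
#' `(sigma_1^2 + sigma_{i-1}^2)/(i-2)^2 + sigma_{i-1}^2 +
#'  2 sigma_{i-1}^2/(i-2) + sigma_exp^2`. Both forms are implemented
#' (`form` argument); they agree to machine precision. For `i < 3` the
#' prior is flat.
#'
#' @inheritParams relative_prior
#' @param form `"printed"` (explicit sums, default) or `"telescoped"`.
#' @return A `gaussian_estimate` of kind `"prior"`.
#' @export
absolute_prior <- function(mu_e, sigma_e, sigma_exp, i,
                           form = c("printed", "telescoped")) {
  form <- match.arg(form)
  if (i < 3) return(gaussian_estimate(NA_real_, Inf, "prior", i))
  stopifnot(length(mu_e) >= i - 1, length(sigma_e) >= i - 1)
  m <- i - 2
  mu_p <- sum(mu_e[2:(i - 1)] - mu_e[1:m]) / m + mu_e[i - 1]
  s2 <- sigma_e^2
  if (form == "printed") {
    interval_var <- sum(s2[2:(i - 1)] + s2[1:m])
    if (m >= 2) interval_var <- interval_var - 2 * sum(s2[2:m])
    var_p <- interval_var / m^2 + s2[i - 1] + 2 * s2[i - 1] / m + sigma_exp^2
  } else {
    var_p <- (s2[1] + s2[i - 1]) / m^2 + s2[i - 1] + 2 * s2[i - 1] / m +
      sigma_exp^2
  }
  gaussian_estimate(mu_p, sqrt(var_p), "prior", i)
}

#' Probability that the sensed probe is later than expected
#'
#' `P(late) = P(X_s > X_p)` for independent `X_p ~ N(mu_p, sigma_p)` and
#' `X_s ~ N(mu_s, sigma_s)`; in closed form
#' \deqn{P(late) = \Phi\!\left(\frac{\mu_s-\mu_p}
#'                                  {\sqrt{\sigma_p^2+\sigma_s^2}}\right).}
#' [p_late_quadrature()] evaluates the defining integral (the prior's CDF
#' marginalized against the sensory density) numerically and is kept as a
#' cross-check.
#'
#' @param prior,sensed [gaussian_estimate()] objects (not flat).
#' @return Probability in (0, 1).
#' @export
p_late <- function(prior, sensed) {
  stopifnot(!is_flat(prior), !is_flat(sensed))
  pnorm((sensed$mu - prior$mu) / sqrt(prior$sigma^2 + sensed$sigma^2))
}

#' @rdname p_late
#' @export
p_late_quadrature <- function(prior, sensed) {
  f <- function(t) pnorm(t, prior$mu, prior$sigma) * dnorm(t, sensed$mu, sensed$sigma)
  integrate(f, -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# one causal pass over the cue tones: exact likelihood means (mu_s = t_i),
# fusion with the running prior; returns posterior moments and prior SDs.
observer_pass <- function(cue_times, sigma_s, sigma_exp, prior_type) {
  I <- length(cue_times)
  mu_e <- numeric(I); sd_e <- numeric(I)
  mu_p <- rep(NA_real_, I); sd_p <- rep(Inf, I)
  prior_fun <- if (prior_type == "relative") relative_prior else absolute_prior
  for (i in seq_len(I)) {
    if (i < 3) {
      mu_e[i] <- cue_times[i]; sd_e[i] <- sigma_s
    } else {
      pr <- prior_fun(mu_e, sd_e, sigma_exp, i)
      mu_p[i] <- pr$mu; sd_p[i] <- pr$sigma
      post <- fuse(pr, gaussian_estimate(cue_times[i], sigma_s, tone_index = i))
      mu_e[i] <- post$mu; sd_e[i] <- post$sigma
    }
  }
  probe_prior <- prior_fun(mu_e, sd_e, sigma_exp, I + 1)
  list(mu_e = mu_e, sd_e = sd_e, mu_p = mu_p, sd_p = sd_p,
       probe_prior = probe_prior)
}

#' Simulate one observer trial
#'
#' Sequential causal pass over the cue tones: each tone's likelihood is
#' centred on its true time with SD `sigma_s`; tones 1--2 get a flat prior
#' (posterior = likelihood); later tones fuse the running prior with the
#' likelihood. For the probe there is no fusion: the probe prior (at index
#' `I + 1`) is compared with the sensed probe and the response is a weighted
#' coin flip on `P(late)`.
#'
#' @param cue_times Cue-tone times, seconds.
#' @param probe_time Probe time, seconds.
#' @param sigma_s Sensory SD, seconds.
#' @param sigma_exp Experiment jitter SD, seconds (known a priori).
#' @param prior_type `"absolute"` or `"relative"`.
#' @return A list: `response` (0/1), `p_late`, `estimates` (tibble with
#'   per-tone prior/posterior moments), `probe_prior`.
#' @export
simulate_observer_trial <- function(cue_times, probe_time, sigma_s, sigma_exp,
                                    prior_type = c("absolute", "relative")) {
  prior_type <- match.arg(prior_type)
  pass <- observer_pass(cue_times, sigma_s, sigma_exp, prior_type)
  p <- p_late(pass$probe_prior, gaussian_estimate(probe_time, sigma_s))
  list(
    response = rbinom(1, 1, p),
    p_late = p,
    estimates = tibble::tibble(
      tone_index = seq_along(cue_times),
      mu_prior = pass$mu_p, sigma_prior = pass$sd_p,
      mu_likelihood = cue_times, sigma_likelihood = sigma_s,
      mu_posterior = pass$mu_e, sigma_posterior = pass$sd_e
    ),
    probe_prior = pass$probe_prior
  )
}

#' Simulate a cohort of Bayesian observers
#'
#' One simulated observer per `sigma_s` value per condition: `n_trials`
#' fresh trials are drawn, the observer responds to each by a weighted coin
#' flip on `P(late)`, and the responses are scored exactly like human data
#' (deviations from both algorithms' predictions, SOA-normalized, scalar
#' logistic fits, chi-square exclusion).
#'
#' `sigma_exp` is each condition's own jitter SD. Under
#' `noise_scaling = "weber"` the grid values are fractions of the
#' condition's design mean period (`sigma_s = fraction * mean period`), so
#' the same fraction grid is comparable across rates; under `"absolute"`
#' the grid values are seconds, identical across conditions.
#'
#' @param conditions Character vector of condition names, or a list of
#'   [experiment_config()] objects.
#' @param sigma_s_grid Numeric grid: seconds (`"absolute"`) or fractions of
#'   the mean period (`"weber"`). Default: 60 observers log-spaced over
#'   `[0.1, 3] * sigma_exp` of each condition (absolute mode) or the
#'   equivalent fraction range of the first condition (weber mode).
#' @param prior_type `"absolute"` or `"relative"`.
#' @param noise_scaling `"absolute"` or `"weber"`.
#' @param n_trials Trials per observer (default 300).
#' @param n_observers Grid size when `sigma_s_grid` is not given.
#' @param seed Optional seed.
#' @return Subject-summary tibble: `condition`, `prior_type`,
#'   `noise_scaling`, `sigma_s` (seconds), `sigma_s_grid` (the grid value),
#'   `sigma_exp`, `mean_sigma_p` (mean prior SD at the probe), `slope_abs`,
#'   `slope_rel`, `chi2_p_abs`, `chi2_p_rel`, `excluded`, `slope_sum`,
#'   `slope_diff`.
#' @export
run_observer_experiment <- function(conditions = c("1.2hz", "2hz", "4hz"),
                                    sigma_s_grid = NULL,
                                    prior_type = c("absolute", "relative"),
                                    noise_scaling = c("absolute", "weber"),
                                    n_trials = 300, n_observers = 60,
                                    seed = NULL) {
  prior_type <- match.arg(prior_type)
  noise_scaling <- match.arg(noise_scaling)
  configs <- lapply(conditions, function(cc)
    if (inherits(cc, "experiment_config")) cc else experiment_config(cc))

  run <- function() {
    purrr::map_dfr(configs, function(cfg) {
      sigma_exp <- cfg$jitter_sd
      grid <- sigma_s_grid
      if (is.null(grid)) {
        ref <- if (noise_scaling == "absolute") sigma_exp else
          configs[[1]]$jitter_sd / mean_period(configs[[1]])
        grid <- exp(seq(log(0.1 * ref), log(3 * ref),
                        length.out = n_observers))
      }
      purrr::map_dfr(seq_along(grid), function(gi) {
        sigma_s <- if (noise_scaling == "weber")
          grid[gi] * mean_period(cfg) else grid[gi]
        trials <- score_trials(draw_trials(cfg, n_trials))
        sim <- purrr::map2(trials$cue_times, trials$probe_time, function(cue, pt) {
          pass <- observer_pass(cue, sigma_s, sigma_exp, prior_type)
          p <- p_late(pass$probe_prior, gaussian_estimate(pt, sigma_s))
          c(p = p, sigma_p = pass$probe_prior$sigma)
        })
        p_vec <- purrr::map_dbl(sim, "p")
        responses <- rbinom(length(p_vec), 1, p_vec)
        fa <- fit_logistic_scalar(trials$dev_absolute_norm, responses)
        fr <- fit_logistic_scalar(trials$dev_relative_norm, responses)
        tibble::tibble(
          condition = cfg$condition_name, prior_type = prior_type,
          noise_scaling = noise_scaling,
          sigma_s = sigma_s, sigma_s_grid = grid[gi], sigma_exp = sigma_exp,
          mean_sigma_p = mean(purrr::map_dbl(sim, "sigma_p")),
          slope_abs = fa$slope, slope_rel = fr$slope,
          chi2_p_abs = fa$chi2_p, chi2_p_rel = fr$chi2_p
        )
      })
    })
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  add_rotated_axes(exclude_noisy(out))
}

#' Dominance versus prior-to-sensory precision ratio
#'
#' Recasts observer results on the axis that unifies jitter conditions: the
#' ratio of mean prior SD at the probe to the sensory SD,
#' `sigma_p / sigma_s`. On this axis, cohorts run at different experiment
#' jitters collapse onto a single curve.
#'
#' @param results Output of [run_observer_experiment()] (>= 1 condition).
#' @return The input with a `precision_ratio` column, ordered by it.
#' @export
precision_ratio_analysis <- function(results) {
  stopifnot(all(c("mean_sigma_p", "sigma_s") %in% names(results)))
  dplyr::arrange(
    dplyr::mutate(results, precision_ratio = .data$mean_sigma_p / .data$sigma_s),
    .data$precision_ratio)
}
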