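#' Fit a scalar logistic psychometric function
#'
#' Maximum-likelihood binomial-logit fit of early/late responses on a scalar
#' probe deviation. The slope is the consistency measure: the steeper the
#' fit, the better the deviation axis sorts the responses. A chi-square
#' deviance test against the constant model (`df = 1`) gives the exclusion
#' p-value used to drop noisy responders.
#'
#' Degenerate inputs are handled explicitly: one-class response vectors are
#' returned flagged as excluded (the deviance test cannot reject the
#' constant model); complete separation is detected and the slope capped at
#' `slope_cap` with `separation = TRUE`.
#'
#' @param deviations Numeric vector (typically SOA-normalized deviations).
#' @param responses 0/1 vector, 0 = early, 1 = late.
#' @param slope_cap Cap on `|slope|` under separation (default 50).
#' @return A list of class `"psychometric_fit"`: `slope`, `intercept`,
#'   `deviance`, `null_deviance`, `chi2_p`, `n_trials`, `excluded`,
#'   `separation`, `kind = "scalar"`.
#' @seealso [fit_logistic_circular()], [exclude_noisy()]
#' @export
fit_logistic_scalar <- function(deviations, responses, slope_cap = 50) {
  stopifnot(length(deviations) == length(responses),
            all(responses %in% c(0, 1)))
  n <- length(responses)
  if (length(unique(responses)) < 2) {
    return(new_psychometric_fit(slope = NA_real_, intercept = NA_real_,
                                deviance = 0, null_deviance = 0, chi2_p = 1,
                                n_trials = n, excluded = TRUE,
                                separation = FALSE, kind = "scalar"))
  }
  fit <- suppressWarnings(glm(responses ~ deviations, family = binomial()))
  slope <- unname(coef(fit)[2])
  mu <- fit$fitted.values
  sep <- all(mu < 1e-8 | mu > 1 - 1e-8)
  if (sep) slope <- sign(slope) * min(abs(slope), slope_cap)
  p <- pchisq(fit$null.deviance - fit$deviance, df = 1, lower.tail = FALSE)
  new_psychometric_fit(slope = slope, intercept = unname(coef(fit)[1]),
                       deviance = fit$deviance, null_deviance = fit$null.deviance,
                       chi2_p = p, n_trials = n, excluded = p > 0.05,
                       separation = sep, kind = "scalar")
}

#' Fit a circular logistic psychometric function
#'
#' Binomial-logit fit of early/late labels on the two regressors
#' `(cos(theta), sin(theta))` of an oscillator phase. The slope is the
#' Euclidean norm of the two coefficients, which is invariant to rotating
#' all phases by a constant. The deviance test against the constant model
#' uses `df = 2`.
#'
#' @param phases Phases in radians.
#' @param labels 0/1 labels (objective early/late per timing algorithm).
#' @param slope_cap Cap on the coefficient norm under separation.
#' @return A `"psychometric_fit"` with `kind = "circular"` and an extra
#'   `coefs` element holding the `(cos, sin)` coefficient pair.
#' @export
fit_logistic_circular <- function(phases, labels, slope_cap = 50) {
  stopifnot(length(phases) == length(labels), all(labels %in% c(0, 1)))
  n <- length(labels)
  if (length(unique(labels)) < 2) {
    out <- new_psychometric_fit(slope = NA_real_, intercept = NA_real_,
                                deviance = 0, null_deviance = 0, chi2_p = 1,
                                n_trials = n, excluded = TRUE,
                                separation = FALSE, kind = "circular")
    out$coefs <- c(NA_real_, NA_real_)
    return(out)
  }
  cx <- cos(phases); sx <- sin(phases)
  fit <- suppressWarnings(glm(labels ~ cx + sx, family = binomial()))
  coefs <- unname(coef(fit)[2:3])
  slope <- sqrt(sum(coefs^2))
  mu <- fit$fitted.values
  sep <- all(mu < 1e-8 | mu > 1 - 1e-8)
  if (sep) slope <- min(slope, slope_cap)
  p <- pchisq(fit$null.deviance - fit$deviance, df = 2, lower.tail = FALSE)
  out <- new_psychometric_fit(slope = slope, intercept = unname(coef(fit)[1]),
                              deviance = fit$deviance,
                              null_deviance = fit$null.deviance,
                              chi2_p = p, n_trials = n, excluded = p > 0.05,
                              separation = sep, kind = "circular")
  out$coefs <- coefs
  out
}

new_psychometric_fit <- function(...) structure(list(...), class = "psychometric_fit")

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit (%s)> slope %.3f, chi2 p = %.3g, n = %d%s\n",
              x$kind, x$slope, x$chi2_p, x$n_trials,
              if (x$excluded) " [excluded]" else ""))
  invisible(x)
}

#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, deviance = x$deviance,
                 null_deviance = x$null_deviance, chi2_p = x$chi2_p,
                 n_trials = x$n_trials, excluded = x$excluded,
                 separation = x$separation)
}

#' Flag noisy responders
#'
#' Marks a subject excluded when the chi-square deviance test of their
#' psychometric fit against the constant model fails to reject
#' (`chi2_p > alpha`). When a subject has one fit per algorithm, exclusion is
#' triggered only if *both* fail (a subject sortable by either axis carries
#' signal).
#'
#' @param summaries A tibble with a `chi2_p` column, or with `chi2_p_abs` and
#'   `chi2_p_rel` columns (cohort output).
#' @param alpha Exclusion threshold, default 0.05.
#' @return `summaries` with a logical `excluded` column (re)computed.
#' @export
exclude_noisy <- function(summaries, alpha = 0.05) {
  if (all(c("chi2_p_abs", "chi2_p_rel") %in% names(summaries))) {
    dplyr::mutate(summaries,
      excluded = .data$chi2_p_abs > alpha & .data$chi2_p_rel > alpha)
  } else if ("chi2_p" %in% names(summaries)) {
    dplyr::mutate(summaries, excluded = .data$chi2_p > alpha)
  } else stop("no chi2_p column(s) found")
}

#' Build per-subject slope summaries
#'
#' Combines a subject's absolute- and relative-algorithm slopes into the
#' rotated coordinates used by the dominance analysis: overall performance
#' `slope_sum = slope_abs + slope_rel` and algorithm dominance
#' `slope_diff = slope_abs - slope_rel`.
#'
#' @param summaries Tibble with `slope_abs` and `slope_rel` columns.
#' @return Input with `slope_sum` and `slope_diff` columns (re)computed.
#' @export
add_rotated_axes <- function(summaries) {
  dplyr::mutate(summaries,
    slope_sum = .data$slope_abs + .data$slope_rel,
    slope_diff = .data$slope_abs - .data$slope_rel)
}

#' Fit the dominance curve (slope difference vs slope sum)
#'
#' Least-squares polynomial fits, with no intercept term, of
#' `slope_diff` on `slope_sum` for orders 1--3, compared by AIC (full
#' Gaussian log-likelihood with ML variance; `k` = coefficients + 1). The
#' no-intercept form encodes the symmetry that equal slopes imply zero
#' difference; the published order-2 form is `y = a x^2 + b x`.
#'
#' A 95% band of the fitted mean (or, optionally, the prediction interval)
#' is evaluated on a grid, and the x-regions where the band excludes zero
#' identify significant relative dominance (`y < 0`) or absolute dominance
#' (`y > 0`).
#'
#' @param summaries Subject summary tibble with `slope_sum`, `slope_diff`,
#'   and optionally `excluded` (excluded rows are dropped).
#' @param orders Polynomial orders to compare, default `1:3`.
#' @param band `"confidence"` (default; band of the fitted mean, the
#'   zero-crossing criterion) or `"prediction"`.
#' @param level Band level, default 0.95.
#' @param grid_n Number of x grid points for the band.
#' @return An object of class `"dominance_fit"`: `best_order`,
#'   `coefficients` (of the best fit, ascending powers `x, x^2, ...`),
#'   `aic` (named per order), `adj_r_square`, `band` (tibble `x, fit, lo,
#'   hi`), `zero_crossing_region` (x-range where the band excludes 0, split
#'   by sign), `n`, and the underlying `lm` fits.
#' @export
fit_dominance_curve <- function(summaries, orders = 1:3,
                                band = c("confidence", "prediction"),
                                level = 0.95, grid_n = 200) {
  band <- match.arg(band)
  if ("excluded" %in% names(summaries))
    summaries <- dplyr::filter(summaries, !.data$excluded)
  if (!all(c("slope_sum", "slope_diff") %in% names(summaries)))
    summaries <- add_rotated_axes(summaries)
  x <- summaries$slope_sum
  y <- summaries$slope_diff
  n <- length(x)
  if (n < 10) stop("need at least 10 included subjects")

  fits <- lapply(orders, function(p) {
    X <- stats::poly(x, degree = p, raw = TRUE)
    colnames(X) <- paste0("x", seq_len(p))
    lm(y ~ 0 + X)
  })
  names(fits) <- paste0("order", orders)
  if (any(vapply(fits, function(f) f$rank, 1L) < orders))
    stop("rank-deficient polynomial design")
  aic <- vapply(fits, AIC, numeric(1))  # 2k - 2 logLik, ML variance, k = p + 1
  best_i <- which.min(aic)
  best <- fits[[best_i]]
  best_order <- orders[best_i]

  degenerate <- all(y == 0)
  adj_r2 <- if (degenerate) 0 else summary(best)$adj.r.squared

  xg <- seq(min(x), max(x), length.out = grid_n)
  Xg <- stats::poly(xg, degree = best_order, raw = TRUE)
  colnames(Xg) <- paste0("x", seq_len(best_order))
  pr <- predict(best, newdata = list(X = Xg), se.fit = TRUE)
  tq <- qt(1 - (1 - level) / 2, df = best$df.residual)
  half <- if (band == "confidence") tq * pr$se.fit else
    tq * sqrt(pr$se.fit^2 + summary(best)$sigma^2)
  band_tbl <- tibble::tibble(x = xg, fit = as.numeric(pr$fit),
                             lo = as.numeric(pr$fit) - half,
                             hi = as.numeric(pr$fit) + half)
  region <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(band_tbl,
        sign = dplyr::case_when(.data$hi < 0 ~ "below", .data$lo > 0 ~ "above",
                                TRUE ~ "spans")),
      .data$sign),
    x_min = min(.data$x), x_max = max(.data$x), .groups = "drop")

  structure(list(
    best_order = best_order,
    coefficients = unname(coef(best)),
    aic = stats::setNames(aic, paste0("order", orders)),
    adj_r_square = adj_r2,
    adj_r_square_degenerate = degenerate,
    band_type = band,
    band = band_tbl,
    zero_crossing_region = region,
    n = n, fits = fits,
    data = tibble::tibble(slope_sum = x, slope_diff = y)
  ), class = "dominance_fit")
}

#' @export
print.dominance_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<dominance_fit> order %d selected by AIC (n = %d)\n",
              x$best_order, x$n))
  cat("  coefficients (x, x^2, ...): ",
      paste(sprintf("%.4g", co), collapse = ", "), "\n", sep = "")
  cat(sprintf("  adj R-square = %.3f; AIC: %s\n", x$adj_r_square,
              paste(sprintf("%s = %.1f", names(x$aic), x$aic), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.dominance_fit <- function(x, ...) {
  s <- summary(x$fits[[paste0("order", x$best_order)]])$coefficients
  tibble::tibble(term = paste0("x^", seq_len(x$best_order)),
                 estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.dominance_fit <- function(x, ...) {
  tibble::tibble(best_order = x$best_order, adj_r_square = x$adj_r_square,
                 n = x$n, aic_best = min(x$aic))
}

#' @rdname fit_dominance_curve
#' @param object A `dominance_fit`.
#' @param ... Unused.
#' @export
autoplot.dominance_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$slope_sum,
                                            y = .data$slope_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_ribbon(data = object$band,
                         ggplot2::aes(x = .data$x, ymin = .data$lo,
                                      ymax = .data$hi),
                         inherit.aes = FALSE, alpha = 0.25) +
    ggplot2::geom_line(data = object$band,
                       ggplot2::aes(x = .data$x, y = .data$fit),
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "slope sum (overall performance)",
                  y = "slope difference (absolute - relative)",
                  title = sprintf("Dominance curve, order %d (adj R² = %.2f)",
                                  object$best_order, object$adj_r_square))
}

#' Rank tests on algorithm dominance between and within conditions
#'
#' Within each condition, a two-sided Wilcoxon signed-rank test of
#' `slope_diff` against zero; between each pair of conditions, a two-sided
#' Mann-Whitney-Wilcoxon test on `slope_diff`, Bonferroni-corrected across
#' the pairwise comparisons.
#'
#' @param summaries Subject summary tibble with `condition` and `slope_diff`
#'   (excluded rows dropped if flagged).
#' @return A tibble: `comparison`, `type`, `statistic`, `p_value`,
#'   `p_adjusted`.
#' @export
compare_groups <- function(summaries) {
  if ("excluded" %in% names(summaries))
    summaries <- dplyr::filter(summaries, !.data$excluded)
  conds <- unique(summaries$condition)
  within <- purrr::map_dfr(conds, function(cc) {
    d <- summaries$slope_diff[summaries$condition == cc]
    w <- suppressWarnings(wilcox.test(d, mu = 0, exact = FALSE))
    tibble::tibble(comparison = cc, type = "within (signed-rank vs 0)",
                   statistic = unname(w$statistic), p_value = w$p.value)
  })
  between <- NULL
  if (length(conds) > 1) {
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    between <- purrr::map_dfr(pairs, function(pp) {
      d1 <- summaries$slope_diff[summaries$condition == pp[1]]
      d2 <- summaries$slope_diff[summaries$condition == pp[2]]
      w <- suppressWarnings(wilcox.test(d1, d2, exact = FALSE))
      tibble::tibble(comparison = paste(pp, collapse = " vs "),
                     type = "between (rank-sum)",
                     statistic = unname(w$statistic), p_value = w$p.value)
    })
    between$p_adjusted <- p.adjust(between$p_value, "bonferroni")
  }
  within$p_adjusted <- within$p_value
  dplyr::bind_rows(within, between)
}
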