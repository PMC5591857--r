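#' Fit normalized stimulus-specific adaptation rates
#'
#' For every response series (one recording site x one stimulus) in a
#' trial-level table, fits an ordinary least-squares line to response
#' magnitude versus trial number over the linear region of the adaptation
#' profile (inclusive `fit_window`, default trials 6-25) and normalizes the
#' slope by the mean magnitude over that window:
#'
#' \deqn{rate = 100 \cdot slope / \bar{m}_{window}}
#'
#' expressed as percent change per trial. Negative rates indicate
#' adaptation; a shallower (less negative) rate for a familiar song than for
#' novel songs is the signature of neuronal memory. Division by the observed
#' window mean makes the rate dimensionless and invariant to any rescaling
#' of the site's magnitudes (amplifier gain, electrode impedance).
#'
#' Series whose normalization denominator falls at or below `epsilon` are
#' returned with `rate = NA` and `excluded_reason = "near_zero_mean"` rather
#' than dropped, so exclusions stay visible downstream.
#'
#' @param trials Data frame with columns `trial` and `magnitude`; every other
#'   column is treated as a series label (e.g. `bird, group, hemisphere,
#'   region, site, set, stimulus, stim_class`). Each labelled series must
#'   contain every trial of `fit_window` exactly once.
#' @param fit_window Inclusive `c(first, last)` trial interval for the fit.
#' @param epsilon Positive threshold below which the normalization
#'   denominator is treated as zero.
#' @param denominator Normalization denominator: `"window_mean"` (default;
#'   mean observed magnitude over the fit window), `"intercept"` (fitted
#'   magnitude at the first window trial) or `"first_trial"` (observed
#'   magnitude at the first window trial).
#' @return A tibble with the label columns plus `rate` (percent/trial),
#'   `mean_magnitude`, `r_squared` (NA for a zero-variance series) and
#'   `excluded_reason` (NA when the rate is defined).
#' @export
#' @examples
#' tr <- data.frame(stimulus = "s", trial = 1:25, magnitude = 200 - 2 * (1:25))
#' fit_ssa_rates(tr)$rate  # 100 * (-2) / 169
fit_ssa_rates <- function(trials, fit_window = c(6L, 25L), epsilon = 1e-9,
                          denominator = c("window_mean", "intercept", "first_trial")) {
  denominator <- match.arg(denominator)
  check_columns(trials, c("trial", "magnitude"), "`trials`")
  if (length(fit_window) != 2 || fit_window[1] >= fit_window[2] || fit_window[1] < 1) {
    abort_field("fit_window", "must be c(first, last) with 1 <= first < last")
  }
  if (!is.numeric(epsilon) || epsilon <= 0) abort_field("epsilon", "must be > 0")
  if (any(!is.finite(trials$magnitude)) || any(trials$magnitude < 0)) {
    abort_field("magnitude", "must be finite and >= 0")
  }

  key_cols <- setdiff(names(trials), c("trial", "magnitude"))
  tt <- seq.int(fit_window[1], fit_window[2])
  n_win <- length(tt)

  w <- tibble::as_tibble(trials) |>
    dplyr::filter(.data$trial >= fit_window[1], .data$trial <= fit_window[2]) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(key_cols, "trial"))))

  bad <- w |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::summarise(n = dplyr::n(), n_distinct = dplyr::n_distinct(.data$trial),
                     .groups = "drop") |>
    dplyr::filter(.data$n != n_win | .data$n_distinct != n_win)
  if (nrow(bad) > 0) {
    keys <- if (length(key_cols) > 0) {
      apply(bad[key_cols], 1, paste, collapse = "/")
    } else {
      "<unlabelled series>"
    }
    stop("series with missing or duplicated trials in the fit window:\n  ",
         paste(utils::head(keys, 20), collapse = "\n  "), call. = FALSE)
  }
  if (nrow(w) == 0) stop("no trials fall inside the fit window", call. = FALSE)

  n_series <- nrow(w) / n_win
  # after arranging, every series occupies one contiguous, trial-ordered block
  stopifnot(all(w$trial == rep(tt, times = n_series)))
  y <- matrix(w$magnitude, nrow = n_win)
  x <- cbind(1, tt)
  fit <- stats::lm.fit(x, y)
  coefs <- matrix(fit$coefficients, nrow = 2)
  slope <- coefs[2, ]
  means <- colMeans(y)
  res <- matrix(fit$residuals, nrow = n_win)
  rss <- colSums(res^2)
  tss <- colSums((y - rep(means, each = n_win))^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)

  denom <- switch(denominator,
    window_mean = means,
    intercept   = coefs[1, ] + slope * fit_window[1],
    first_trial = y[1, ]
  )
  defined <- denom > epsilon
  rate <- ifelse(defined, 100 * slope / denom, NA_real_)

  labels <- w[seq(1, nrow(w), by = n_win), key_cols, drop = FALSE]
  out <- tibble::as_tibble(labels)
  out$rate <- rate
  out$mean_magnitude <- means
  out$r_squared <- r2
  out$excluded_reason <- ifelse(defined, NA_character_, "near_zero_mean")
  out
}

#' Fit the SSA rate of a single response series
#'
#' Convenience wrapper around [fit_ssa_rates()] for one series. Accepts
#' either a data frame with `trial` and `magnitude` columns or a bare
#' numeric vector of magnitudes indexed by 1-based trial.
#'
#' @inheritParams fit_ssa_rates
#' @param series Data frame (`trial`, `magnitude`, optional labels) or
#'   numeric vector of magnitudes for trials `1:length(series)`.
#' @return A one-row tibble as returned by [fit_ssa_rates()].
#' @export
fit_ssa_rate <- function(series, fit_window = c(6L, 25L), epsilon = 1e-9,
                         denominator = c("window_mean", "intercept", "first_trial")) {
  if (is.numeric(series) && is.null(dim(series))) {
    series <- tibble::tibble(trial = seq_along(series), magnitude = as.numeric(series))
  }
  out <- fit_ssa_rates(series, fit_window = fit_window, epsilon = epsilon,
                       denominator = denominator)
  if (nrow(out) != 1) {
    stop("`series` contains more than one labelled series; use fit_ssa_rates()",
         call. = FALSE)
  }
  out
}
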