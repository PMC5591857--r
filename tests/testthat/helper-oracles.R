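# Independent oracles used by unit and acceptance tests. These deliberately
# use different computational routes than the package (explicit sum formulas,
# enumeration, ECDF sweeps) so agreement is evidence, not tautology.

# Normalized slope by explicit normal equations.
oracle_rate <- function(trial, magnitude, window = c(6, 25)) {
  sel <- trial >= window[1] & trial <= window[2]
  t <- trial[sel]
  y <- magnitude[sel]
  n <- length(t)
  slope <- (n * sum(t * y) - sum(t) * sum(y)) / (n * sum(t^2) - sum(t)^2)
  100 * slope / mean(y)
}

# Two-sided sign-test p by binomial enumeration: twice the smaller tail,
# capped at 1.
oracle_sign_p <- function(k, n) {
  lower <- sum(stats::dbinom(0:k, n, 0.5))
  upper <- sum(stats::dbinom(k:n, n, 0.5))
  min(1, 2 * min(lower, upper))
}

# Continuity-corrected normal approximation for the large-sample sign test.
oracle_sign_z <- function(k, n) {
  d <- k - n / 2
  if (d == 0) 0 else sign(d) * (abs(d) - 0.5) / sqrt(n / 4)
}

# K-S d statistic by sweeping every observed value as an ECDF breakpoint.
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1)))
}

# Small deterministic response table: one site, one set, 2F + 2N series with
# chosen normalized rates, exact linear profiles over trials 1-25.
linear_series_table <- function(rates_f = c(-1, -1), rates_n = c(-2, -2),
                                amplitude = 100) {
  stims <- tibble::tibble(
    stimulus = c("set1_F1", "set1_F2", "set1_N1", "set1_N2"),
    stim_class = c("F", "F", "N", "N"),
    rate = c(rates_f, rates_n)
  )
  tidyr::expand_grid(stims, trial = 1:25) |>
    dplyr::mutate(
      bird = "b1", group = "g", hemisphere = "left", region = "NCM",
      site = "e1", set = 1L,
      magnitude = amplitude * (1 + rate / 100 * (trial - 15.5))
    ) |>
    dplyr::select(bird, group, hemisphere, region, site, set, stimulus,
                  stim_class, trial, magnitude)
}

tiny_config <- function(...) {
  cohort_config(n_birds = c(hdac3i = 1, vehicle = 1),
                electrodes_per_hemisphere_ncm = 2,
                electrodes_per_hemisphere_nonncm = 0,
                n_test_sets = 2, seed = 99, ...)
}
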