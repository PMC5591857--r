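#' Sign test of the median against a fixed null
#'
#' Two-sided sign test that the population median equals `null` (1.0 for
#' Familiarity Index data: the no-memory value). Values tied with the null
#' are dropped (classical convention) and their count reported. For samples
#' of at most `exact_max_n` observations the exact binomial p-value is used;
#' for larger samples the normal approximation with continuity correction is
#' used and the Z statistic reported, matching the convention of reporting Z
#' only for samples above 100.
#'
#' @param x Numeric vector.
#' @param null Null median (default 1.0).
#' @param exact_max_n Largest n for which the exact binomial p is computed.
#' @return A one-row tibble: `test`, `statistic_name` ("k" exact / "Z"
#'   approximate), `statistic`, `p_value`, `n` (after dropping ties),
#'   `n_above`, `null_value`, `ties_dropped`.
#' @export
#' @examples
#' sign_test(rep(1.2, 10), null = 1)$p_value  # 2 * 0.5^10
sign_test <- function(x, null = 1, exact_max_n = 100L) {
  if (!is.numeric(x)) abort_field("x", "must be numeric")
  x <- x[is.finite(x)]
  ties <- sum(x == null)
  x <- x[x != null]
  n <- length(x)
  if (n < 1) {
    stop("degenerate input: no values differ from the null", call. = FALSE)
  }
  k <- sum(x > null)
  if (n <= exact_max_n) {
    p <- stats::binom.test(k, n, p = 0.5)$p.value
    stat <- as.numeric(k)
    stat_name <- "k"
  } else {
    d <- k - n / 2
    z <- if (d == 0) 0 else sign(d) * (abs(d) - 0.5) / sqrt(n / 4)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    stat <- z
    stat_name <- "Z"
  }
  tibble::tibble(test = "sign_test", statistic_name = stat_name,
                 statistic = stat, p_value = p, n = n, n_above = k,
                 null_value = null, ties_dropped = ties)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two empirical distributions (e.g. FI records of two treatment
#' groups or two hemispheres) by the supremum distance between their ECDFs
#' (d statistic) with the asymptotic two-sided p-value. Being rank-based,
#' the d statistic is invariant under any common strictly monotone
#' transform of both samples.
#'
#' @param a,b Numeric samples (non-empty).
#' @return A one-row tibble: `test`, `statistic_name` ("d"), `statistic`,
#'   `p_value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) == 0) abort_field("a", "must contain at least one finite value")
  if (length(b) == 0) abort_field("b", "must contain at least one finite value")
  ht <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                        exact = FALSE))
  tibble::tibble(test = "ks_two_sample", statistic_name = "d",
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 n1 = length(a), n2 = length(b))
}

#' One-sample t test
#'
#' Standard two-sided one-sample t test against `mu` (used for relative
#' gene-expression percentages against the 100% reference level).
#'
#' @param x Numeric vector (n >= 2, non-zero variance).
#' @param mu Null mean.
#' @return A one-row tibble: `test`, `statistic_name` ("t"), `statistic`,
#'   `df`, `p_value`, `n`, `null_value`.
#' @export
one_sample_t <- function(x, mu) {
  x <- x[is.finite(x)]
  if (length(x) < 2) abort_field("x", "needs at least 2 finite values")
  if (stats::var(x) == 0) abort_field("x", "has zero variance")
  ht <- stats::t.test(x, mu = mu)
  tibble::tibble(test = "one_sample_t", statistic_name = "t",
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, n = length(x), null_value = mu)
}

#' Two-sample t test (pooled variance)
#'
#' Two-sided two-sample t test with pooled variance (df = n1 + n2 - 2),
#' the form consistent with reporting t with 8 degrees of freedom for two
#' groups of five samples.
#'
#' @param x,y Numeric samples (each n >= 2; pooled variance non-zero).
#' @return A one-row tibble: `test`, `statistic_name` ("t"), `statistic`,
#'   `df`, `p_value`, `n1`, `n2`.
#' @export
two_sample_t <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2) abort_field("x", "needs at least 2 finite values")
  if (length(y) < 2) abort_field("y", "needs at least 2 finite values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    abort_field("x", "both samples have zero variance")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  tibble::tibble(test = "two_sample_t", statistic_name = "t",
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, n1 = length(x), n2 = length(y))
}

#' Bonferroni correction
#'
#' `p' = min(1, m * p)`. The default correction factor is 2 (the
#' per-hemisphere or per-region pair of comparisons) or the number of
#' p-values supplied, whichever is larger.
#'
#' @param p Numeric vector of p-values.
#' @param m Number of comparisons (>= 1).
#' @return Corrected p-values.
#' @export
#' @examples
#' bonferroni(c(0.03, 0.8), m = 2)  # 0.06, 1.0
bonferroni <- function(p, m = max(2L, length(p))) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort_field("p", "must contain p-values in [0, 1]")
  }
  m <- check_count(m, "m")
  pmin(1, m * p)
}

#' Two-sided normal p-value for a Z statistic
#'
#' Maps a Z statistic to its two-sided p-value, `2 * pnorm(-|z|)`. Useful
#' for checking reported Z/p pairings from the sign test's large-sample
#' form.
#'
#' @param z Z statistic(s).
#' @return Two-sided p-value(s).
#' @export
#' @examples
#' signif(bonferroni(z_to_p(3.85), m = 2), 2)  # 2.4e-4
z_to_p <- function(z) {
  2 * stats::pnorm(-abs(z))
}
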