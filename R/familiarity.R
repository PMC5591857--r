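#' Compute Familiarity Index records from fitted SSA rates
#'
#' The Familiarity Index (FI) of a familiar song at one recording site is the
#' ratio of the adaptation rate to novel songs over the adaptation rate to
#' that familiar song (N/F). FI > 1 means the site adapts more slowly to the
#' familiar song than to novel songs, i.e. it carries a neuronal memory of
#' it; FI = 1 means the familiar song is processed as if novel.
#'
#' One FI record is produced per site x test set x familiar song, with the
#' novel denominator taken as the mean of the same set's novel-song rates at
#' that site (same-session novels control for drift). Records are emitted
#' for every familiar rate, but an FI value is only defined when both the
#' familiar rate and the novel mean are negative (genuine adaptation);
#' otherwise the record carries `fi = NA` and an `excluded_reason` code:
#' \describe{
#'   \item{`upstream_excluded`}{the familiar rate was excluded by
#'     [fit_ssa_rates()];}
#'   \item{`nonnegative_rate`}{the familiar rate is >= 0 (the ratio would be
#'     undefined or of the wrong sign);}
#'   \item{`no_valid_novel`}{no non-excluded novel rate in the set;}
#'   \item{`nonnegative_novel_mean`}{the novel-rate mean is >= 0.}
#' }
#'
#' @param rates Tibble from [fit_ssa_rates()] including `stim_class` ("F" or
#'   "N"), `set`, `rate` and `excluded_reason` columns plus site labels.
#' @return A tibble of FI records: site labels, `set`, `familiar_stimulus`,
#'   `familiar_rate`, `novel_rate_mean`, `n_novel`, `fi`, `excluded_reason`.
#' @export
#' @examples
#' rates <- tibble::tibble(
#'   site = "e1", set = 1,
#'   stimulus = c("F1", "N1", "N2"), stim_class = c("F", "N", "N"),
#'   rate = c(-0.5, -1.0, -1.5), mean_magnitude = 100, r_squared = 0.9,
#'   excluded_reason = NA_character_
#' )
#' compute_fi(rates)$fi  # 2.5
compute_fi <- function(rates) {
  check_columns(rates, c("set", "stimulus", "stim_class", "rate", "excluded_reason"),
                "`rates`")
  if (!all(rates$stim_class %in% c("F", "N"))) {
    abort_field("stim_class", 'must be "F" or "N"')
  }
  key_cols <- setdiff(names(rates),
                      c("stimulus", "stim_class", "rate", "mean_magnitude",
                        "r_squared", "excluded_reason"))
  rates <- tibble::as_tibble(rates)

  novel <- rates |>
    dplyr::filter(.data$stim_class == "N") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::summarise(
      n_novel_present = dplyr::n(),
      n_novel = sum(is.na(.data$excluded_reason)),
      novel_rate_mean = mean(.data$rate[is.na(.data$excluded_reason)]),
      .groups = "drop"
    )

  fam <- rates |>
    dplyr::filter(.data$stim_class == "F") |>
    dplyr::select(dplyr::all_of(key_cols), familiar_stimulus = "stimulus",
                  familiar_rate = "rate", upstream_reason = "excluded_reason")
  joined <- dplyr::left_join(fam, novel, by = key_cols)

  no_novel <- is.na(joined$n_novel_present)
  if (any(no_novel)) {
    keys <- apply(joined[no_novel, key_cols, drop = FALSE], 1, paste, collapse = "/")
    stop("no novel rates available for: ",
         paste(utils::head(unique(keys), 10), collapse = ", "), call. = FALSE)
  }

  reason <- dplyr::case_when(
    !is.na(joined$upstream_reason)              ~ "upstream_excluded",
    joined$familiar_rate >= 0                   ~ "nonnegative_rate",
    joined$n_novel == 0                         ~ "no_valid_novel",
    joined$novel_rate_mean >= 0                 ~ "nonnegative_novel_mean",
    TRUE                                        ~ NA_character_
  )
  fi <- ifelse(is.na(reason), joined$novel_rate_mean / joined$familiar_rate,
               NA_real_)

  out <- joined |>
    dplyr::select(dplyr::all_of(key_cols), "familiar_stimulus", "familiar_rate",
                  "novel_rate_mean", "n_novel")
  out$fi <- fi
  out$excluded_reason <- reason
  out
}

#' Pool Familiarity Index records into per-cell medians
#'
#' Pools non-excluded FI records over a grouping key (by default treatment
#' group x hemisphere x region) and reports the median FI, its interquartile
#' range and the record count per cell. Cells that appear in the input but
#' retain no non-excluded records are reported explicitly with `n = 0` and
#' `NA` summaries rather than silently omitted.
#'
#' @param records FI records from [compute_fi()].
#' @param by Character vector of grouping columns.
#' @return A tibble with the grouping columns plus `n`, `median_fi`,
#'   `iqr_fi`, `q25`, `q75` and `empty` (TRUE when a cell has no usable
#'   records).
#' @export
pool_fi <- function(records, by = c("group", "hemisphere", "region")) {
  check_columns(records, c(by, "fi", "excluded_reason"), "`records`")
  cells <- dplyr::distinct(tibble::as_tibble(records)[by])
  ok <- records |>
    dplyr::filter(is.na(.data$excluded_reason)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_fi = stats::median(.data$fi),
      iqr_fi = stats::IQR(.data$fi),
      q25 = stats::quantile(.data$fi, 0.25, names = FALSE),
      q75 = stats::quantile(.data$fi, 0.75, names = FALSE),
      .groups = "drop"
    )
  out <- dplyr::left_join(cells, ok, by = by) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L), empty = .data$n == 0L) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
  out
}
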