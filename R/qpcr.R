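#' Relative gene expression by the delta-delta-CT method
#'
#' Computes per-sample relative expression of target genes as percent of a
#' reference (vehicle) group, normalized to a housekeeping gene. Per sample,
#' `dct = ct_target - ct_housekeeping` within the same (bird, hemisphere,
#' region); the per-sample fold level is `2^(-dct)` (assuming 100%
#' amplification efficiency), and relative expression is that fold level as
#' a percentage of the reference group's level within the same
#' gene x region x hemisphere cell.
#'
#' Two conventions are offered for the reference level:
#' \describe{
#'   \item{`"fold_mean"` (default)}{reference level = arithmetic mean of the
#'     reference samples' `2^(-dct)`. The reference group then averages to
#'     exactly 100% in every cell.}
#'   \item{`"ct_mean"`}{classic delta-delta-CT: `ddct = dct - mean(reference
#'     dct)`, relative expression `100 * 2^(-ddct)`. The reference group's
#'     geometric mean is 100%, its arithmetic mean slightly above.}
#' }
#' Both are invariant to a common shift of target and housekeeping CT and
#' agree exactly when reference samples are noise-free.
#'
#' @param ct Data frame with columns `bird, group, hemisphere, region, gene,
#'   ct` (threshold cycles, finite and > 0).
#' @param housekeeping_gene Name of the housekeeping gene; every (bird,
#'   hemisphere, region) must carry exactly one housekeeping measurement.
#' @param reference_group Name of the reference (control) group; must be
#'   represented in every gene x region x hemisphere cell.
#' @param reference_aggregate `"fold_mean"` or `"ct_mean"` (see above).
#' @return A tibble `bird, group, hemisphere, region, gene, ct, ct_housekeeping,
#'   dct, ddct, rel_expression` (percent of reference).
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   bird = c("v1", "d1", "v1", "d1"),
#'   group = c("vehicle", "hdac3i", "vehicle", "hdac3i"),
#'   hemisphere = "left", region = "NCM",
#'   gene = c("zenk", "zenk", "s18", "s18"),
#'   ct = c(26, 25, 12, 12)
#' )
#' delta_delta_ct(ct)$rel_expression  # 100, 200
delta_delta_ct <- function(ct, housekeeping_gene = "s18",
                           reference_group = "vehicle",
                           reference_aggregate = c("fold_mean", "ct_mean")) {
  reference_aggregate <- match.arg(reference_aggregate)
  check_columns(ct, c("bird", "group", "hemisphere", "region", "gene", "ct"),
                "`ct`")
  ct <- tibble::as_tibble(ct)
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    abort_field("ct", "CT values must be finite and > 0")
  }
  if (!housekeeping_gene %in% ct$gene) {
    abort_field("housekeeping_gene",
                sprintf('gene "%s" not present in the table', housekeeping_gene))
  }

  hk <- ct |>
    dplyr::filter(.data$gene == housekeeping_gene) |>
    dplyr::select("bird", "hemisphere", "region", ct_housekeeping = "ct")
  dup <- hk |> dplyr::count(.data$bird, .data$hemisphere, .data$region) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicated housekeeping CT for: ",
         paste(apply(dup[1:3], 1, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }

  tgt <- ct |>
    dplyr::filter(.data$gene != housekeeping_gene) |>
    dplyr::left_join(hk, by = c("bird", "hemisphere", "region"))
  miss <- is.na(tgt$ct_housekeeping)
  if (any(miss)) {
    keys <- apply(tgt[miss, c("bird", "hemisphere", "region")], 1, paste,
                  collapse = "/")
    stop("missing housekeeping CT for sample(s): ",
         paste(utils::head(unique(keys), 10), collapse = ", "), call. = FALSE)
  }
  tgt$dct <- tgt$ct - tgt$ct_housekeeping

  ref <- tgt |>
    dplyr::filter(.data$group == reference_group) |>
    dplyr::group_by(.data$gene, .data$region, .data$hemisphere) |>
    dplyr::summarise(ref_dct_mean = mean(.data$dct),
                     ref_fold_mean = mean(2^(-.data$dct)), .groups = "drop")
  out <- dplyr::left_join(tgt, ref, by = c("gene", "region", "hemisphere"))
  empty <- is.na(out$ref_dct_mean)
  if (any(empty)) {
    cells <- unique(apply(out[empty, c("gene", "region", "hemisphere")], 1,
                          paste, collapse = "/"))
    stop(sprintf('reference group "%s" is empty in cell(s): %s',
                 reference_group,
                 paste(utils::head(cells, 10), collapse = ", ")), call. = FALSE)
  }

  if (reference_aggregate == "fold_mean") {
    out$rel_expression <- 100 * 2^(-out$dct) / out$ref_fold_mean
    out$ddct <- -log2(out$rel_expression / 100)
  } else {
    out$ddct <- out$dct - out$ref_dct_mean
    out$rel_expression <- 100 * 2^(-out$ddct)
  }
  out |>
    dplyr::select("bird", "group", "hemisphere", "region", "gene", "ct",
                  "ct_housekeeping", "dct", "ddct", "rel_expression")
}

#' Per-cell expression contrasts
#'
#' For every gene x region x hemisphere cell, tests whether the treatment
#' group's relative expression differs from the reference. The default is a
#' pooled-variance two-sample t test of treatment versus reference
#' percentages (df = n1 + n2 - 2, consistent with reporting df = 8 for two
#' groups of five); `method = "one_sample"` instead tests the treatment
#' percentages against the 100% reference level. P-values are Bonferroni
#' corrected across the two hemispheres within each gene x region.
#'
#' @param rel Output of [delta_delta_ct()].
#' @param treatment_group,reference_group Group labels.
#' @param method `"two_sample"` (default) or `"one_sample"`.
#' @param m Bonferroni correction factor (default 2: the hemisphere pair).
#' @return A tibble with one row per gene x region x hemisphere:
#'   `gene, region, hemisphere, mean_rel_treatment, statistic_name, statistic,
#'   df, p_value, p_adjusted, n1, n2`.
#' @export
expression_contrast <- function(rel, treatment_group = "hdac3i",
                                reference_group = "vehicle",
                                method = c("two_sample", "one_sample"),
                                m = 2L) {
  method <- match.arg(method)
  check_columns(rel, c("group", "hemisphere", "region", "gene", "rel_expression"),
                "`rel`")
  cells <- rel |>
    dplyr::filter(.data$group %in% c(treatment_group, reference_group)) |>
    dplyr::group_by(.data$gene, .data$region, .data$hemisphere)
  out <- cells |>
    dplyr::group_modify(function(df, key) {
      x <- df$rel_expression[df$group == treatment_group]
      y <- df$rel_expression[df$group == reference_group]
      res <- if (method == "two_sample") {
        two_sample_t(x, y)
      } else {
        cmp <- one_sample_t(x, mu = 100)
        cmp$n1 <- cmp$n
        cmp$n2 <- NA_integer_
        cmp
      }
      tibble::tibble(mean_rel_treatment = mean(x),
                     statistic_name = res$statistic_name,
                     statistic = res$statistic, df = res$df,
                     p_value = res$p_value, n1 = res$n1, n2 = res$n2)
    }) |>
    dplyr::ungroup()
  out |>
    dplyr::group_by(.data$gene, .data$region) |>
    dplyr::mutate(p_adjusted = bonferroni(.data$p_value, m = m)) |>
    dplyr::ungroup()
}
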