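#' Run the full neuronal-memory analysis
#'
#' Orchestrates the complete pipeline: simulate (or accept) a trial-level
#' response table, fit normalized SSA rates per series, derive Familiarity
#' Index records, pool them into group/hemisphere/region medians, run the
#' inferential battery (sign tests against FI = 1, two-sample K-S contrasts
#' between groups, hemispheres and regions), and optionally the companion
#' delta-delta-CT gene-expression analysis. Returns a machine-readable
#' report; with `out_dir` set, also writes every intermediate table as CSV
#' plus the report as JSON and a stage log, so each stage can be re-run from
#' its predecessor's CSV.
#'
#' The report is reproducible byte-for-byte for a fixed `(config, seed)`
#' apart from the `created` timestamp in its metadata.
#'
#' @param config A [cohort_config()]; supplies the simulation parameters and
#'   root seed (ignored for simulation when `trials` is given, but still
#'   recorded in the metadata).
#' @param trials Optional pre-existing trial-level table (e.g. from
#'   [read_trial_table()]); when NULL the cohort is simulated from `config`.
#' @param ct Optional qPCR CT table; when NULL and `qpcr_args` is a list,
#'   a CT table is simulated via [generate_qpcr()] (its `seed` defaults to
#'   the cohort seed). When both are NULL the qPCR stage is skipped.
#' @param qpcr_args Optional list of arguments for [generate_qpcr()].
#' @param out_dir Optional output directory (created if needed).
#' @param treatment_group,control_group,extended_group Group labels used for
#'   the standard contrasts; contrasts whose groups are absent are skipped
#'   (and logged).
#' @param region_of_interest,control_region Region labels (default NCM and
#'   nonNCM).
#' @param alpha Significance level recorded in the report.
#' @return An object of class `ssafi_report`: a list with `metadata`,
#'   `pooled_fi`, `comparisons`, `qpcr` (or NULL), and `exclusions`.
#' @export
#' @examples
#' cfg <- cohort_config(n_birds = c(hdac3i = 2, vehicle = 2),
#'                      electrodes_per_hemisphere_nonncm = 0, seed = 11)
#' rep <- run_analysis(cfg)
#' rep$pooled_fi
run_analysis <- function(config,
                         trials = NULL,
                         ct = NULL,
                         qpcr_args = NULL,
                         out_dir = NULL,
                         treatment_group = "hdac3i",
                         control_group = "vehicle",
                         extended_group = "x200",
                         region_of_interest = "NCM",
                         control_region = "nonNCM",
                         alpha = 0.05) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created with cohort_config()", call. = FALSE)
  }
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  # --- simulate / load ------------------------------------------------------
  if (is.null(trials)) {
    cohort <- generate_cohort(config)
    trials <- cohort$trials
    note("simulate: generated %d trial rows (%d sites, seed %d)",
         nrow(trials), nrow(cohort$ground_truth$site_amplitude), config$seed)
  } else {
    validate_trial_table(trials)
    note("load: accepted %d trial rows", nrow(trials))
  }

  # --- rates ----------------------------------------------------------------
  fit_window <- c(6L, min(25L, config$trials_per_song))
  rates <- fit_ssa_rates(trials, fit_window = fit_window)
  n_excl_rates <- sum(!is.na(rates$excluded_reason))
  note("rates: fit %d series over trials %d-%d; %d excluded (near-zero mean)",
       nrow(rates), fit_window[1], fit_window[2], n_excl_rates)

  # --- familiarity ----------------------------------------------------------
  fi <- compute_fi(rates)
  fi_excl <- fi |>
    dplyr::filter(!is.na(.data$excluded_reason)) |>
    dplyr::count(.data$excluded_reason, name = "n")
  note("fi: %d records, %d excluded", nrow(fi), sum(fi_excl$n))
  pooled <- pool_fi(fi, by = c("group", "hemisphere", "region"))
  pooled_region <- pool_fi(fi, by = c("group", "region"))

  # --- stats ----------------------------------------------------------------
  groups <- unique(fi$group)
  regions <- unique(fi$region)
  ok <- fi |> dplyr::filter(is.na(.data$excluded_reason))
  cell <- function(...) {
    conds <- list(...)
    sel <- rep(TRUE, nrow(ok))
    for (nm in names(conds)) sel <- sel & ok[[nm]] == conds[[nm]]
    ok$fi[sel]
  }
  comparisons <- list()
  add <- function(label, row) {
    row$label <- label
    comparisons[[length(comparisons) + 1L]] <<- row
  }

  # sign tests vs 1 per group x region (Bonferroni across the region pair)
  for (g in groups) {
    rows <- list()
    for (r in regions) {
      v <- cell(group = g, region = r)
      if (length(v[v != 1]) < 1) {
        note("stats: skipped sign test for %s/%s (degenerate cell)", g, r)
        next
      }
      st <- sign_test(v, null = 1)
      st$region <- r
      rows[[r]] <- st
    }
    if (length(rows) > 0) {
      m_corr <- max(2L, length(rows))
      for (r in names(rows)) {
        row <- rows[[r]]
        row$p_adjusted <- bonferroni(row$p_value, m = m_corr)
        add(sprintf("fi_vs_1|%s|%s", g, r), row)
      }
    }
  }

  # sign tests vs 1 per group x hemisphere within the region of interest
  for (g in groups) {
    rows <- list()
    for (h in c("left", "right")) {
      v <- cell(group = g, region = region_of_interest, hemisphere = h)
      if (length(v[v != 1]) < 1) {
        note("stats: skipped sign test for %s/%s/%s (degenerate cell)",
             g, region_of_interest, h)
        next
      }
      st <- sign_test(v, null = 1)
      st$region <- region_of_interest
      st$hemisphere <- h
      rows[[h]] <- st
    }
    for (h in names(rows)) {
      row <- rows[[h]]
      row$p_adjusted <- bonferroni(row$p_value, m = 2L)
      add(sprintf("fi_vs_1|%s|%s|%s", g, region_of_interest, h), row)
    }
  }

  ks_pair <- function(label, a, b) {
    if (length(a) < 1 || length(b) < 1) {
      note("stats: skipped %s (empty cell)", label)
      return(invisible(NULL))
    }
    add(label, ks_two_sample(a, b))
  }
  if (all(c(treatment_group, control_group) %in% groups)) {
    ks_pair(sprintf("ks_fi|%s_vs_%s|%s", treatment_group, control_group,
                    region_of_interest),
            cell(group = treatment_group, region = region_of_interest),
            cell(group = control_group, region = region_of_interest))
  }
  if (treatment_group %in% groups && control_region %in% regions) {
    ks_pair(sprintf("ks_fi|%s|%s_vs_%s", treatment_group, region_of_interest,
                    control_region),
            cell(group = treatment_group, region = region_of_interest),
            cell(group = treatment_group, region = control_region))
  }
  for (g in groups) {
    ks_pair(sprintf("ks_fi|%s|left_vs_right|%s", g, region_of_interest),
            cell(group = g, region = region_of_interest, hemisphere = "left"),
            cell(group = g, region = region_of_interest, hemisphere = "right"))
  }
  if (all(c(extended_group, treatment_group) %in% groups)) {
    ks_pair(sprintf("ks_fi|%s_vs_%s|%s", extended_group, treatment_group,
                    region_of_interest),
            cell(group = extended_group, region = region_of_interest),
            cell(group = treatment_group, region = region_of_interest))
  }
  comparisons <- dplyr::bind_rows(comparisons) |>
    dplyr::relocate("label")
  note("stats: %d comparisons", nrow(comparisons))

  # --- qpcr -----------------------------------------------------------------
  qpcr <- NULL
  if (is.null(ct) && is.list(qpcr_args)) {
    if (is.null(qpcr_args$seed)) qpcr_args$seed <- config$seed
    ct <- do.call(generate_qpcr, qpcr_args)
    note("qpcr: simulated %d CT rows", nrow(ct))
  }
  if (!is.null(ct)) {
    validate_ct_table(ct)
    rel <- delta_delta_ct(ct, reference_group = control_group)
    contrasts <- expression_contrast(rel, treatment_group = treatment_group,
                                     reference_group = control_group)
    summary_rel <- rel |>
      dplyr::group_by(.data$group, .data$gene, .data$region, .data$hemisphere) |>
      dplyr::summarise(n = dplyr::n(),
                       mean_rel_expression = mean(.data$rel_expression),
                       .groups = "drop")
    qpcr <- list(relative_expression = rel, summary = summary_rel,
                 contrasts = contrasts)
    note("qpcr: %d samples, %d contrasts", nrow(rel), nrow(contrasts))
  }

  exclusions <- list(
    rates_excluded = n_excl_rates,
    fi_excluded_by_reason = fi_excl,
    ties_dropped_total = sum(comparisons$ties_dropped, na.rm = TRUE)
  )

  report <- structure(list(
    metadata = list(
      package = "ssafi",
      version = as.character(utils::packageVersion("ssafi")),
      seed = config$seed,
      alpha = alpha,
      fit_window = fit_window,
      config = config_as_list(config),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    pooled_fi = pooled,
    pooled_fi_by_region = pooled_region,
    comparisons = comparisons,
    qpcr = qpcr,
    exclusions = exclusions,
    log = log_lines
  ), class = "ssafi_report")

  if (!is.null(out_dir)) {
    write_report_files(report, trials, rates, fi, ct, out_dir)
  }
  report
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$n_birds <- as.list(out$n_birds)
  out$fi_true <- as.data.frame(out$fi_true)
  out
}

write_report_files <- function(report, trials, rates, fi, ct, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_csv(trials, p("trials.csv"))
  readr::write_csv(rates, p("ssa_rates.csv"))
  readr::write_csv(fi, p("fi_records.csv"))
  readr::write_csv(report$pooled_fi, p("pooled_fi.csv"))
  readr::write_csv(report$comparisons, p("comparisons.csv"))
  if (!is.null(ct)) {
    readr::write_csv(ct, p("qpcr_ct.csv"))
    readr::write_csv(report$qpcr$relative_expression,
                     p("qpcr_relative_expression.csv"))
    readr::write_csv(report$qpcr$contrasts, p("qpcr_contrasts.csv"))
  }
  serial <- unclass(report)
  jsonlite::write_json(serial, p("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  writeLines(report$log, p("log.txt"))
  invisible(out_dir)
}

#' @export
print.ssafi_report <- function(x, ...) {
  cat(sprintf("ssafi analysis report (seed %d, created %s)\n",
              x$metadata$seed, x$metadata$created))
  cat("\nPooled Familiarity Index (group x hemisphere x region):\n")
  print(as.data.frame(x$pooled_fi), row.names = FALSE, digits = 4)
  cat("\nComparisons:\n")
  cols <- intersect(c("label", "statistic_name", "statistic", "p_value",
                      "p_adjusted", "n", "n1", "n2"), names(x$comparisons))
  print(as.data.frame(x$comparisons[cols]), row.names = FALSE, digits = 4)
  if (!is.null(x$qpcr)) {
    cat("\nGene expression contrasts (% of control):\n")
    print(as.data.frame(x$qpcr$contrasts), row.names = FALSE, digits = 4)
  }
  cat(sprintf("\nExclusions: %d series (near-zero mean); %d FI records.\n",
              x$exclusions$rates_excluded,
              sum(x$exclusions$fi_excluded_by_reason$n)))
  invisible(x)
}
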