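#' Configure a synthetic recording cohort
#'
#' Builds a validated configuration for [generate_cohort()]. The defaults
#' mirror the recording design used throughout the package: awake birds tested
#' with four song sets, each holding two familiar (F) and two novel (N)
#' conspecific songs, every song repeated 25 times, with four electrodes per
#' hemisphere in NCM and four in a non-NCM control region (Field L complex).
#'
#' Each generated response series declines linearly (in trial number) across
#' the linear region of the adaptation profile (trials 6 to
#' `trials_per_song`), preceded by a geometric fast-adaptation phase over
#' trials 1-5. Novel songs decay with a normalized slope of
#' `novel_slope_pct` percent per trial; familiar songs decay with
#' `novel_slope_pct / fi` for their (group, hemisphere, region) cell, so the
#' Familiarity Index recovered downstream equals the configured `fi_true`
#' exactly when `noise_cv = 0`.
#'
#' @param n_birds Named integer vector: birds per treatment group. Default
#'   mirrors a limited-exposure drug group (n = 8), a limited-exposure vehicle
#'   group (n = 6) and an extended-exposure group (n = 6).
#' @param electrodes_per_hemisphere_ncm,electrodes_per_hemisphere_nonncm
#'   Recording sites per hemisphere in NCM / the non-NCM control region. The
#'   non-NCM count may be 0 to generate an NCM-only cohort.
#' @param n_test_sets Number of test song sets.
#' @param familiar_per_set,novel_per_set Familiar / novel songs per set.
#' @param trials_per_song Repetitions of each song (>= 7 so a fit window
#'   exists).
#' @param amplitude_log_mean,amplitude_log_sd Meanlog/sdlog of the lognormal
#'   per-site baseline response magnitude (arbitrary units).
#' @param novel_slope_pct Normalized adaptation slope of novel songs, percent
#'   change per trial; must be negative and shallow enough that magnitudes
#'   stay positive over the linear region.
#' @param fi_true Either a single number applied everywhere, or a data frame
#'   with columns `group`, `hemisphere`, `region`, `fi` giving the true
#'   familiar-slope attenuation per cell (cells not listed default to 1, i.e.
#'   no memory). All values must be > 0.
#' @param fast_phase_drop_frac Fraction of the baseline amplitude added at
#'   trial 1 and decaying geometrically (ratio 0.35) over trials 1-5.
#' @param noise_cv Coefficient of variation of multiplicative lognormal trial
#'   noise (0 disables noise).
#' @param seed Integer root seed; per-site substreams are derived from it.
#'
#' @return A `cohort_config` object (a validated list).
#' @seealso [generate_cohort()], [scenario_config()]
#' @export
#' @examples
#' cfg <- cohort_config(n_birds = c(hdac3i = 2, vehicle = 2), seed = 42)
#' cfg$trials_per_song
cohort_config <- function(n_birds = c(hdac3i = 8L, vehicle = 6L, x200 = 6L),
                          electrodes_per_hemisphere_ncm = 4L,
                          electrodes_per_hemisphere_nonncm = 4L,
                          n_test_sets = 4L,
                          familiar_per_set = 2L,
                          novel_per_set = 2L,
                          trials_per_song = 25L,
                          amplitude_log_mean = log(100),
                          amplitude_log_sd = 0.5,
                          novel_slope_pct = -3.5,
                          fi_true = NULL,
                          fast_phase_drop_frac = 0.5,
                          noise_cv = 0.15,
                          seed = 1L) {
  if (length(n_birds) < 1 || is.null(names(n_birds)) || any(!nzchar(names(n_birds)))) {
    abort_field("n_birds", "must be a named vector (group name -> bird count)")
  }
  if (anyDuplicated(names(n_birds))) abort_field("n_birds", "group names must be unique")
  n_birds <- vapply(seq_along(n_birds), function(i) {
    check_count(n_birds[[i]], sprintf("n_birds[%s]", names(n_birds)[i]))
  }, integer(1), USE.NAMES = FALSE) |> stats::setNames(names(n_birds))

  cfg <- list(
    n_birds = n_birds,
    electrodes_per_hemisphere_ncm =
      check_count(electrodes_per_hemisphere_ncm, "electrodes_per_hemisphere_ncm"),
    electrodes_per_hemisphere_nonncm =
      check_count(electrodes_per_hemisphere_nonncm, "electrodes_per_hemisphere_nonncm", min = 0L),
    n_test_sets = check_count(n_test_sets, "n_test_sets"),
    familiar_per_set = check_count(familiar_per_set, "familiar_per_set"),
    novel_per_set = check_count(novel_per_set, "novel_per_set"),
    trials_per_song = check_count(trials_per_song, "trials_per_song", min = 7L),
    amplitude_log_mean = check_number(amplitude_log_mean, "amplitude_log_mean"),
    amplitude_log_sd = check_number(amplitude_log_sd, "amplitude_log_sd", lower = 0),
    novel_slope_pct = check_number(novel_slope_pct, "novel_slope_pct"),
    fast_phase_drop_frac = check_number(fast_phase_drop_frac, "fast_phase_drop_frac", lower = 0),
    noise_cv = check_number(noise_cv, "noise_cv", lower = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$novel_slope_pct >= 0) abort_field("novel_slope_pct", "must be negative")

  # Linear decline is centred on the fit-window midpoint; make sure the
  # deepest point of the window stays positive.
  half_span <- (cfg$trials_per_song - 6) / 2
  if (abs(cfg$novel_slope_pct) / 100 * half_span >= 1) {
    abort_field("novel_slope_pct",
                "too steep: magnitudes would become non-positive within the fit window")
  }

  cfg$fi_true <- normalize_fi_true(fi_true, names(n_birds))
  structure(cfg, class = "cohort_config")
}

normalize_fi_true <- function(fi_true, groups) {
  if (is.null(fi_true)) {
    return(tibble::tibble(group = character(), hemisphere = character(),
                          region = character(), fi = numeric()))
  }
  if (is.numeric(fi_true) && length(fi_true) == 1) {
    if (!is.finite(fi_true) || fi_true <= 0) abort_field("fi_true", "must be > 0")
    grid <- tidyr::expand_grid(group = groups,
                               hemisphere = c("left", "right"),
                               region = c("NCM", "nonNCM"))
    grid$fi <- as.numeric(fi_true)
    return(grid)
  }
  if (!is.data.frame(fi_true)) {
    abort_field("fi_true", "must be NULL, a single number, or a data frame")
  }
  check_columns(fi_true, c("group", "hemisphere", "region", "fi"), "`fi_true`")
  if (any(!is.finite(fi_true$fi)) || any(fi_true$fi <= 0)) {
    abort_field("fi_true", "all fi values must be finite and > 0")
  }
  bad <- setdiff(fi_true$group, groups)
  if (length(bad) > 0) {
    abort_field("fi_true", paste("unknown group(s):", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(fi_true[c("group", "hemisphere", "region")])) {
    abort_field("fi_true", "duplicate (group, hemisphere, region) rows")
  }
  tibble::as_tibble(fi_true)[c("group", "hemisphere", "region", "fi")]
}

# Geometric decay ratio of the fast adaptation phase (trials 1-5).
FAST_PHASE_RATIO <- 0.35

site_table <- function(config) {
  groups <- names(config$n_birds)
  birds <- purrr::map_dfr(groups, function(g) {
    tibble::tibble(group = g,
                   bird = sprintf("%s_b%02d", g, seq_len(config$n_birds[[g]])))
  })
  regions <- tibble::tibble(
    region = c("NCM", "nonNCM"),
    n_sites = c(config$electrodes_per_hemisphere_ncm,
                config$electrodes_per_hemisphere_nonncm)
  )
  regions <- regions[regions$n_sites > 0, ]
  sites <- tidyr::expand_grid(birds, hemisphere = c("left", "right"), regions) |>
    dplyr::mutate(site_idx = purrr::map(.data$n_sites, seq_len)) |>
    tidyr::unnest("site_idx") |>
    dplyr::mutate(site = sprintf("%s_%s_e%d", .data$hemisphere, .data$region,
                                 .data$site_idx)) |>
    dplyr::select("group", "bird", "hemisphere", "region", "site")
  sites |>
    dplyr::left_join(config$fi_true, by = c("group", "hemisphere", "region")) |>
    dplyr::mutate(fi = dplyr::coalesce(.data$fi, 1))
}

series_prototype <- function(config) {
  tidyr::expand_grid(
    set = seq_len(config$n_test_sets),
    stim = c(sprintf("F%d", seq_len(config$familiar_per_set)),
             sprintf("N%d", seq_len(config$novel_per_set)))
  ) |>
    dplyr::mutate(stimulus = sprintf("set%d_%s", .data$set, .data$stim),
                  stim_class = substr(.data$stim, 1, 1)) |>
    dplyr::select("set", "stimulus", "stim_class")
}

#' Generate a synthetic cohort of trial-level responses with ground truth
#'
#' Simulates per-site multiunit response magnitudes for every (bird,
#' hemisphere, region, site, set, stimulus, trial) combination defined by the
#' configuration. The adaptation profile is piecewise: a geometric fast drop
#' over trials 1-5 followed by an exactly linear decline (in trial number)
#' over trials 6 to `trials_per_song`, centred so that the window mean equals
#' the site's baseline amplitude. Trial noise is multiplicative lognormal
#' with unit mean and coefficient of variation `noise_cv`.
#'
#' Each site draws from its own RNG substream derived from the root seed and
#' the site's labels, so enlarging the cohort never perturbs previously
#' generated sites, and identical `(config, seed)` give bit-identical output.
#'
#' @param config A [cohort_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{trials}{tibble with columns `bird, group, hemisphere, region,
#'       site, set, stimulus, stim_class, trial, magnitude`.}
#'     \item{ground_truth}{list with `site_amplitude` (true baseline per
#'       site), `series_slope` (true absolute slope and normalized rate per
#'       site x stimulus), `cell_fi` (true FI per group x hemisphere x
#'       region) and `seed`.}
#'   }
#' @export
#' @examples
#' cfg <- cohort_config(n_birds = c(vehicle = 1), noise_cv = 0, seed = 7)
#' cohort <- generate_cohort(cfg)
#' head(cohort$trials)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created with cohort_config()", call. = FALSE)
  }
  sites <- site_table(config)
  proto <- series_prototype(config)
  n_series_site <- nrow(proto)
  t_all <- seq_len(config$trials_per_song)
  mid <- (6 + config$trials_per_song) / 2
  sigma <- sqrt(log(1 + config$noise_cv^2))

  series <- tidyr::crossing(sites, proto) |>
    dplyr::arrange(.data$group, .data$bird, .data$hemisphere, .data$region,
                   .data$site, .data$set, .data$stimulus)
  # per-series normalized slope (percent/trial): novel as configured,
  # familiar attenuated by the cell's true FI
  series$slope_pct <- ifelse(series$stim_class == "N",
                             config$novel_slope_pct,
                             config$novel_slope_pct / series$fi)

  site_keys <- dplyr::distinct(series, .data$group, .data$bird,
                               .data$hemisphere, .data$region, .data$site)
  n_sites <- nrow(site_keys)
  draws <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    sk <- site_keys[i, ]
    seed_i <- substream_seed(config$seed, sk$group, sk$bird, sk$hemisphere,
                             sk$region, sk$site)
    draws[[i]] <- with_seed(seed_i, {
      a <- stats::rlnorm(1, config$amplitude_log_mean, config$amplitude_log_sd)
      eps <- if (config$noise_cv > 0) {
        stats::rnorm(n_series_site * config$trials_per_song)
      } else {
        NULL
      }
      list(a = a, eps = eps)
    })
  }
  site_keys$amplitude <- vapply(draws, function(d) d$a, numeric(1))

  # series table carries the site amplitude; expand to trials
  series <- dplyr::left_join(series, site_keys,
                             by = c("group", "bird", "hemisphere", "region", "site"))
  n_series <- nrow(series)
  idx <- rep(seq_len(n_series), each = config$trials_per_song)
  trial <- rep(t_all, times = n_series)
  a <- series$amplitude[idx]
  s <- series$slope_pct[idx]
  base <- a * (1 + s / 100 * (trial - mid))
  fast <- ifelse(trial <= 5,
                 a * config$fast_phase_drop_frac * FAST_PHASE_RATIO^(trial - 1),
                 0)
  magnitude <- base + fast
  if (config$noise_cv > 0) {
    eps <- unlist(lapply(draws, function(d) d$eps), use.names = FALSE)
    magnitude <- magnitude * exp(sigma * eps - sigma^2 / 2)
  }

  trials <- tibble::tibble(
    bird = series$bird[idx], group = series$group[idx],
    hemisphere = series$hemisphere[idx], region = series$region[idx],
    site = series$site[idx], set = series$set[idx],
    stimulus = series$stimulus[idx], stim_class = series$stim_class[idx],
    trial = trial, magnitude = magnitude
  )

  ground_truth <- list(
    site_amplitude = tibble::as_tibble(site_keys),
    series_slope = series |>
      dplyr::transmute(.data$bird, .data$group, .data$hemisphere, .data$region,
                       .data$site, .data$set, .data$stimulus, .data$stim_class,
                       slope_abs = .data$amplitude * .data$slope_pct / 100,
                       rate_pct = .data$slope_pct),
    cell_fi = tidyr::expand_grid(
      group = names(config$n_birds),
      hemisphere = c("left", "right"),
      region = unique(sites$region)
    ) |>
      dplyr::left_join(config$fi_true, by = c("group", "hemisphere", "region")) |>
      dplyr::mutate(fi = dplyr::coalesce(.data$fi, 1)),
    seed = config$seed
  )
  list(trials = trials, ground_truth = ground_truth)
}

#' Reference simulation scenario mirroring the study design
#'
#' Convenience wrapper around [cohort_config()] that encodes the package's
#' reference scenario: a limited-exposure drug-treated group (8 birds) with a
#' left-biased NCM memory effect (true FI 1.28 left, 1.15 right), a
#' limited-exposure vehicle group (6 birds) with no memory (FI 1 everywhere),
#' and an extended-exposure group (6 birds) with a bilateral NCM effect
#' (FI 1.19 in both hemispheres). Non-NCM cells always have FI 1.
#'
#' @param seed Integer root seed.
#' @param n_birds Named group sizes (must use the scenario's group names
#'   `hdac3i`, `vehicle`, `x200`).
#' @param ... Further arguments passed to [cohort_config()] (for example
#'   `electrodes_per_hemisphere_nonncm = 0` for an NCM-only cohort, or
#'   `noise_cv`).
#' @return A `cohort_config` object.
#' @export
scenario_config <- function(seed = 1L,
                            n_birds = c(hdac3i = 8L, vehicle = 6L, x200 = 6L),
                            ...) {
  fi_true <- tibble::tribble(
    ~group,    ~hemisphere, ~region, ~fi,
    "hdac3i",  "left",      "NCM",   1.28,
    "hdac3i",  "right",     "NCM",   1.15,
    "x200",    "left",      "NCM",   1.19,
    "x200",    "right",     "NCM",   1.19
  )
  fi_true <- fi_true[fi_true$group %in% names(n_birds), ]
  cohort_config(n_birds = n_birds, fi_true = fi_true, seed = seed, ...)
}

#' Generate raw voltage epochs realizing a response series
#'
#' Synthesizes one voltage epoch per trial of a response series: Gaussian
#' baseline noise throughout the epoch plus an additional independent
#' Gaussian evoked component inside the stimulus window, scaled so that the
#' expected baseline-subtracted RMS of the stimulus window equals the
#' series' magnitude for that trial. Epochs are returned in a shuffled
#' presentation order (as in a shuffled playback design) together with the
#' within-stimulus repetition index, so they exercise the reordering done by
#' [build_series()].
#'
#' @param series Data frame with columns `trial` and `magnitude` (one row per
#'   trial; any additional label columns are carried through).
#' @param sampling_rate Sampling rate in Hz.
#' @param stim_window,baseline_window Half-open `c(start, end)` intervals in
#'   seconds relative to epoch start; must not overlap.
#' @param baseline_sd Standard deviation of the baseline noise (voltage
#'   units); may be 0.
#' @param seed Integer seed.
#' @return A tibble with the label columns of `series` plus `trial`,
#'   `presentation` (shuffled playback position) and `epoch` (list column of
#'   [epoch()] objects), ordered by presentation.
#' @export
generate_epochs <- function(series, sampling_rate = 25000,
                            stim_window = c(0.5, 1.5),
                            baseline_window = c(0, 0.5),
                            baseline_sd = 5, seed = 1L) {
  check_columns(series, c("trial", "magnitude"), "`series`")
  sampling_rate <- check_number(sampling_rate, "sampling_rate")
  if (sampling_rate <= 0) abort_field("sampling_rate", "must be > 0")
  baseline_sd <- check_number(baseline_sd, "baseline_sd", lower = 0)
  check_window <- function(w, field) {
    if (length(w) != 2 || !is.numeric(w) || any(!is.finite(w)) || w[2] <= w[1] || w[1] < 0) {
      abort_field(field, "must be c(start, end) with 0 <= start < end")
    }
    as.numeric(w)
  }
  stim_window <- check_window(stim_window, "stim_window")
  baseline_window <- check_window(baseline_window, "baseline_window")
  if (stim_window[1] < baseline_window[2] && baseline_window[1] < stim_window[2]) {
    abort_field("stim_window", "stimulus and baseline windows must not overlap")
  }
  if (any(series$magnitude < 0)) abort_field("series", "magnitudes must be >= 0")

  duration <- max(stim_window[2], baseline_window[2])
  n <- floor(duration * sampling_rate)
  with_seed(check_count(seed, "seed", min = 0L), {
    n_trials <- nrow(series)
    presentation <- sample.int(n_trials)
    epochs <- lapply(seq_len(n_trials), function(i) {
      m <- series$magnitude[i]
      samples <- stats::rnorm(n, 0, baseline_sd)
      i0 <- floor(stim_window[1] * sampling_rate) + 1L
      i1 <- floor(stim_window[2] * sampling_rate)
      evoked_sd <- sqrt((baseline_sd + m)^2 - baseline_sd^2)
      if (evoked_sd > 0) {
        samples[i0:i1] <- samples[i0:i1] + stats::rnorm(i1 - i0 + 1L, 0, evoked_sd)
      }
      epoch(samples, sampling_rate, stim_window, baseline_window)
    })
    out <- tibble::as_tibble(series[setdiff(names(series), "magnitude")])
    out$presentation <- presentation
    out$epoch <- epochs
    dplyr::arrange(out, .data$presentation)
  })
}

#' Generate a synthetic qPCR CT table
#'
#' Simulates threshold-cycle (CT) measurements for target genes and a
#' housekeeping gene across treatment groups, hemispheres and regions.
#' Target CT values are `base_ct[gene] - log2(fold_change) + noise`; the
#' housekeeping CT is independent of group, so a fold change of `f` in a cell
#' yields an expected relative expression of `100 * f` percent of the
#' reference group downstream.
#'
#' @param fold_changes NULL (no effects anywhere) or a data frame with
#'   columns `group, hemisphere, region, gene, fold` (> 0); cells not listed
#'   have fold 1.
#' @param n_ncm,n_ap Named integer vectors: birds per group sampled in NCM
#'   and in the anterior-pole (AP) control region. AP birds are a subset of
#'   the NCM birds.
#' @param genes Target gene names.
#' @param housekeeping_gene Housekeeping gene name.
#' @param base_ct Named numeric: baseline CT per gene (targets and
#'   housekeeping).
#' @param noise_sd Standard deviation (cycles) of Gaussian CT noise; 0
#'   disables noise.
#' @param seed Integer seed.
#' @return A tibble `bird, group, hemisphere, region, gene, ct`.
#' @export
generate_qpcr <- function(fold_changes = NULL,
                          n_ncm = c(hdac3i = 5L, vehicle = 5L),
                          n_ap = c(hdac3i = 3L, vehicle = 3L),
                          genes = c("zenk", "cfos"),
                          housekeeping_gene = "s18",
                          base_ct = c(zenk = 26, cfos = 27, s18 = 12),
                          noise_sd = 0.3, seed = 1L) {
  groups <- names(n_ncm)
  if (is.null(groups) || anyDuplicated(groups)) {
    abort_field("n_ncm", "must be a named vector with unique group names")
  }
  if (!setequal(names(n_ap), groups)) {
    abort_field("n_ap", "group names must match n_ncm")
  }
  all_genes <- c(genes, housekeeping_gene)
  if (!all(all_genes %in% names(base_ct))) {
    abort_field("base_ct", "must name every target gene and the housekeeping gene")
  }
  noise_sd <- check_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(fold_changes)) {
    check_columns(fold_changes, c("group", "hemisphere", "region", "gene", "fold"),
                  "`fold_changes`")
    if (any(!is.finite(fold_changes$fold)) || any(fold_changes$fold <= 0)) {
      abort_field("fold_changes", "all fold values must be finite and > 0")
    }
  }

  samples <- purrr::map_dfr(groups, function(g) {
    ncm_birds <- sprintf("%s_q%02d", g, seq_len(check_count(n_ncm[[g]], "n_ncm")))
    n_ap_g <- check_count(n_ap[[g]], "n_ap", min = 0L)
    if (n_ap_g > length(ncm_birds)) abort_field("n_ap", "cannot exceed n_ncm")
    dplyr::bind_rows(
      tidyr::expand_grid(bird = ncm_birds, region = "NCM"),
      if (n_ap_g > 0) tidyr::expand_grid(bird = ncm_birds[seq_len(n_ap_g)],
                                         region = "AP")
    ) |>
      dplyr::mutate(group = g)
  })
  tbl <- tidyr::expand_grid(samples, hemisphere = c("left", "right"),
                            gene = all_genes) |>
    dplyr::select("bird", "group", "hemisphere", "region", "gene")
  fold <- rep(1, nrow(tbl))
  if (!is.null(fold_changes)) {
    matched <- dplyr::left_join(
      tbl, tibble::as_tibble(fold_changes),
      by = c("group", "hemisphere", "region", "gene")
    )
    fold <- dplyr::coalesce(matched$fold, 1)
  }
  # housekeeping CT never carries a treatment effect
  fold[tbl$gene == housekeeping_gene] <- 1
  with_seed(check_count(seed, "seed", min = 0L), {
    noise <- if (noise_sd > 0) stats::rnorm(nrow(tbl), 0, noise_sd) else 0
    tbl$ct <- base_ct[tbl$gene] - log2(fold) + noise
  })
  names(tbl$ct) <- NULL
  tbl
}
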