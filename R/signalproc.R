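#' Construct a voltage epoch
#'
#' A single per-trial recording epoch: an ordered vector of voltage samples
#' with its sampling rate and two half-open analysis windows (stimulus and
#' baseline) given in seconds relative to epoch start. Windows must lie
#' within the epoch, must not overlap, and must each contain at least one
#' sample.
#'
#' @param samples Numeric vector of voltage samples.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param stim_window,baseline_window Half-open `c(start, end)` intervals in
#'   seconds.
#' @return An object of class `epoch`.
#' @export
#' @examples
#' fs <- 1000
#' t <- seq(0, 2 - 1 / fs, by = 1 / fs)
#' x <- ifelse(t >= 1, sin(2 * pi * 10 * t), 0)
#' ep <- epoch(x, fs, stim_window = c(1, 2), baseline_window = c(0, 1))
#' extract_magnitude(ep)  # ~ 1 / sqrt(2)
epoch <- function(samples, sampling_rate, stim_window, baseline_window) {
  if (!is.numeric(samples) || length(samples) == 0 || any(!is.finite(samples))) {
    abort_field("samples", "must be a non-empty finite numeric vector")
  }
  if (length(sampling_rate) != 1 || !is.numeric(sampling_rate) ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    abort_field("sampling_rate", "must be a single number > 0")
  }
  duration <- length(samples) / sampling_rate
  chk <- function(w, field) {
    if (length(w) != 2 || !is.numeric(w) || any(!is.finite(w)) ||
        w[1] < 0 || w[2] <= w[1]) {
      abort_field(field, "must be c(start, end) with 0 <= start < end")
    }
    if (w[2] > duration + 1e-12) {
      abort_field(field, sprintf("window [%g, %g) extends beyond the %g s epoch",
                                 w[1], w[2], duration))
    }
    idx <- window_indices(w, sampling_rate, length(samples))
    if (length(idx) == 0) abort_field(field, "window contains no samples")
    as.numeric(w)
  }
  stim_window <- chk(stim_window, "stim_window")
  baseline_window <- chk(baseline_window, "baseline_window")
  if (stim_window[1] < baseline_window[2] && baseline_window[1] < stim_window[2]) {
    abort_field("stim_window", "stimulus and baseline windows must not overlap")
  }
  structure(list(samples = as.numeric(samples),
                 sampling_rate = as.numeric(sampling_rate),
                 stim_window = stim_window,
                 baseline_window = baseline_window),
            class = "epoch")
}

# Sample indices covered by half-open window [start, end) at rate fs.
window_indices <- function(w, fs, n) {
  i0 <- floor(w[1] * fs + 1e-9) + 1L
  i1 <- min(floor(w[2] * fs + 1e-9), n)
  if (i1 < i0) integer(0) else i0:i1
}

#' @export
print.epoch <- function(x, ...) {
  cat(sprintf("<epoch> %d samples @ %g Hz; stim [%g, %g) s; baseline [%g, %g) s\n",
              length(x$samples), x$sampling_rate,
              x$stim_window[1], x$stim_window[2],
              x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}

#' Extract the response magnitude of an epoch
#'
#' The response magnitude is the baseline-subtracted RMS of the multiunit
#' trace: `max(0, RMS(stim window) - RMS(baseline window))`, in the voltage
#' units of the input. RMS is computed about each window's own mean (the AC
#' component), so the measure is exactly invariant to a DC offset added to
#' the whole epoch and scales linearly with input gain. The clamp at zero
#' keeps downstream slope normalization defined for silent sites.
#'
#' @param ep An [epoch()] object.
#' @return Non-negative scalar response magnitude.
#' @export
extract_magnitude <- function(ep) {
  if (!inherits(ep, "epoch")) stop("`ep` must be an epoch object", call. = FALSE)
  n <- length(ep$samples)
  stim <- ep$samples[window_indices(ep$stim_window, ep$sampling_rate, n)]
  base <- ep$samples[window_indices(ep$baseline_window, ep$sampling_rate, n)]
  max(0, rms(stim - mean(stim)) - rms(base - mean(base)))
}

#' Assemble response series from per-trial epochs
#'
#' Takes a manifest of epochs (one row per presentation, in any order, e.g.
#' the shuffled playback order) and produces the trial-level response table
#' consumed by [fit_ssa_rates()]: one row per (labels, trial) with the
#' extracted response magnitude, ordered by within-stimulus repetition index.
#' Every (labels) group must contain trials `1:n_trials` exactly once.
#'
#' @param manifest Data frame with an `epoch` list column of [epoch()]
#'   objects, a `trial` column (within-stimulus repetition index, 1-based),
#'   and any label columns (e.g. `bird, group, hemisphere, region, site, set,
#'   stimulus, stim_class`). A `presentation` column, if present, is dropped.
#' @param n_trials Required number of trials per series.
#' @return A tibble of the label columns plus `trial` and `magnitude`,
#'   ordered by labels then trial.
#' @export
build_series <- function(manifest, n_trials = 25L) {
  check_columns(manifest, c("epoch", "trial"), "`manifest`")
  n_trials <- check_count(n_trials, "n_trials")
  key_cols <- setdiff(names(manifest), c("epoch", "trial", "presentation", "magnitude"))
  tbl <- tibble::as_tibble(manifest)

  problems <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::summarise(
      missing = paste(setdiff(seq_len(n_trials), .data$trial), collapse = ","),
      duplicated = paste(sort(unique(.data$trial[duplicated(.data$trial)])),
                         collapse = ","),
      extra = paste(setdiff(.data$trial, seq_len(n_trials)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::filter(nzchar(.data$missing) | nzchar(.data$duplicated) | nzchar(.data$extra))
  if (nrow(problems) > 0) {
    desc <- apply(problems, 1, function(r) {
      key <- paste(r[key_cols], collapse = "/")
      parts <- c(
        if (nzchar(r[["missing"]])) paste0("missing trials ", r[["missing"]]),
        if (nzchar(r[["duplicated"]])) paste0("duplicated trials ", r[["duplicated"]]),
        if (nzchar(r[["extra"]])) paste0("out-of-range trials ", r[["extra"]])
      )
      paste0(key, ": ", paste(parts, collapse = "; "))
    })
    stop("incomplete trial series:\n  ", paste(desc, collapse = "\n  "),
         call. = FALSE)
  }

  tbl$magnitude <- vapply(tbl$epoch, extract_magnitude, numeric(1))
  tbl |>
    dplyr::select(dplyr::all_of(c(key_cols, "trial", "magnitude"))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(key_cols, "trial"))))
}
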