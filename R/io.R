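# CSV interfaces for trial-level response tables and qPCR CT tables.

TRIAL_COLS <- c("bird", "group", "hemisphere", "region", "site", "set",
                "stimulus", "stim_class", "trial", "magnitude")
CT_COLS <- c("bird", "group", "hemisphere", "region", "gene", "ct")

validate_trial_table <- function(trials) {
  check_columns(trials, TRIAL_COLS, "trial table")
  if (!all(trials$hemisphere %in% c("left", "right"))) {
    abort_field("hemisphere", 'must be "left" or "right"')
  }
  if (!all(trials$stim_class %in% c("F", "N"))) {
    abort_field("stim_class", 'must be "F" or "N"')
  }
  if (any(trials$trial < 1 | trials$trial != as.integer(trials$trial))) {
    abort_field("trial", "must be positive integers (1-based)")
  }
  if (any(!is.finite(trials$magnitude)) || any(trials$magnitude < 0)) {
    abort_field("magnitude", "must be finite and >= 0")
  }
  invisible(trials)
}

#' Read a trial-level response table
#'
#' Reads and validates the package's trial CSV dialect: one row per (bird,
#' group, hemisphere, region, site, set, stimulus, stim_class, trial) with
#' the response magnitude. `hemisphere` must be left/right, `stim_class`
#' F/N, `trial` 1-based.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_trial_table <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              bird = "c", group = "c", hemisphere = "c",
                              region = "c", site = "c", set = "i",
                              stimulus = "c", stim_class = "c",
                              trial = "i", magnitude = "d"
                            ))
  validate_trial_table(trials)
  trials
}

validate_ct_table <- function(ct) {
  check_columns(ct, CT_COLS, "CT table")
  if (!all(ct$hemisphere %in% c("left", "right"))) {
    abort_field("hemisphere", 'must be "left" or "right"')
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    abort_field("ct", "must be finite and > 0")
  }
  invisible(ct)
}

#' Read a qPCR CT table
#'
#' Reads and validates the CT CSV dialect: one row per (bird, group,
#' hemisphere, region, gene) with the threshold cycle.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_ct_table <- function(path) {
  ct <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          bird = "c", group = "c", hemisphere = "c",
                          region = "c", gene = "c", ct = "d"
                        ))
  validate_ct_table(ct)
  ct
}
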