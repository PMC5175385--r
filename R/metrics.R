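#' Participant-level relative-power spectra for a whole study
#'
#' For every participant: estimates the baseline spectrum from the 2-s
#' baseline segments (split into 1-s sub-windows), single-taper power for
#' every movement trial of every task, converts to percent change relative to
#' baseline per trial, and averages across trials. This is the order of
#' operations used throughout: per-trial percent change first, trial average
#' second.
#'
#' @param study an `erd_study` from [simulate_study()] (or assembled from
#'   imported recordings with the same structure).
#' @param freqs analysis bin centers in Hz.
#' @return tibble with columns `participant_id`, `group`, `task`, `channel`,
#'   `freq`, `rel_power` (participant-level percent change).
#' @export
participant_spectra <- function(study, freqs = analysis_freqs()) {
  stopifnot(inherits(study, "erd_study"))
  rows <- purrr::map(study$participants$participant_id, function(pid) {
    part <- study$data[[pid]]
    base <- baseline_power(part$baseline, freqs)
    purrr::imap(part$movement, function(ep, task) {
      rel <- average_trials(relative_power(epoch_power(ep, freqs), base))
      rel$participant_id <- pid
      rel$group <- ep$group
      rel$task <- task
      rel
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  out[, c("participant_id", "group", "task", "channel", "freq", "rel_power")]
}

#' Long metric table for group statistics
#'
#' Reduces participant-level spectra to the two scalar per-channel metrics
#' that enter the inferential layer: the band-mean relative power
#' (`"relative_power"`) and the normalized spectral entropy (`"entropy"`) of
#' the band-restricted spectrum.
#'
#' @param spectra output of [participant_spectra()].
#' @param band numeric `c(f_lo, f_hi)` Hz.
#' @return tibble with columns `participant_id`, `group`, `task`, `channel`,
#'   `metric`, `value`; one row per participant, task, channel and metric.
#' @export
metric_table <- function(spectra, band = c(8, 25)) {
  per <- dplyr::group_by(spectra, .data$participant_id, .data$group, .data$task)
  out <- dplyr::group_modify(per, function(d, key) {
    bm <- band_mean(d, band)
    em <- entropy_map(d, band)
    dplyr::bind_rows(
      tibble::tibble(channel = bm$channel, metric = "relative_power",
                     value = bm$value),
      tibble::tibble(channel = em$channel, metric = "entropy", value = em$H)
    )
  })
  out <- dplyr::ungroup(out)
  attr(out, "band") <- band
  out[, c("participant_id", "group", "task", "channel", "metric", "value")]
}
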