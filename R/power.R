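#' Analysis frequency grid
#'
#' The default sensor-level analysis grid: 8 to 25 Hz in steps of 1 Hz,
#' 18 bins. This multiplicity (18) is also the family size of the per-bin
#' false-discovery-rate correction.
#'
#' @param from,to,by grid limits and step in Hz.
#' @return numeric vector of bin centers.
#' @export
analysis_freqs <- function(from = 8, to = 25, by = 1) {
  seq(from, to, by = by)
}

# periodic Hanning taper
hann_taper <- function(n) {
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
}

#' Single-taper spectral power of epochs
#'
#' Power at the requested frequency bins for every trial and channel, from a
#' single-Hanning-taper FFT. Normalization is fixed as a one-sided power
#' spectral density, `P(f) = 2 |DFT(w x)_f|^2 / (fs * sum(w^2))`, which (a)
#' compensates the taper power so white noise of variance `s^2` gives a flat
#' density `2 s^2 / fs` across bins, and (b) makes a unit-amplitude sinusoid
#' at a bin center yield `T/3` (with `T` the epoch length in seconds) at any
#' sampling rate. The absolute scale is immaterial downstream: the percent
#' change of [relative_power()] cancels it.
#'
#' @param epochs an `epoch_set`.
#' @param freqs requested bin centers in Hz; every bin must lie on the DFT
#'   grid of the epoch (multiples of `1/duration`).
#' @return a `power_spectra` tibble with columns `trial`, `channel`, `freq`,
#'   `power`, and attributes `freqs`, `fs`, `channels`.
#' @export
epoch_power <- function(epochs, freqs = analysis_freqs()) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  n_trial <- d[1]; n_ch <- d[2]; n_samp <- d[3]
  duration <- n_samp / epochs$fs
  if (length(freqs) < 1 || any(freqs <= 0)) abort("freqs must be positive")
  on_grid <- abs(freqs * duration - round(freqs * duration)) < 1e-9
  if (!all(on_grid)) {
    abort(sprintf(
      "requested frequencies %s are off the DFT grid (resolution %.4g Hz for %.3g-s epochs)",
      paste(freqs[!on_grid], collapse = ", "), 1 / duration, duration
    ))
  }
  if (duration < 2 / min(freqs)) {
    abort(sprintf(
      "epoch length %.3g s is shorter than two cycles of the lowest bin (%g Hz)",
      duration, min(freqs)
    ))
  }
  if (any(freqs > epochs$fs / 2)) abort("requested frequency above Nyquist")
  w <- hann_taper(n_samp)
  norm <- 2 / (epochs$fs * sum(w^2))
  idx <- as.integer(round(freqs * duration)) + 1L
  channels <- epochs$montage$channel
  pw <- array(NA_real_, dim = c(n_trial, n_ch, length(freqs)))
  for (tr in seq_len(n_trial)) {
    x <- w * t(matrix(epochs$data[tr, , ], nrow = n_ch))
    X <- stats::mvfft(x)
    pw[tr, , ] <- t(abs(X[idx, , drop = FALSE])^2 * norm)
  }
  out <- tidyr::expand_grid(trial = seq_len(n_trial), channel = channels,
                            freq = freqs)
  out$power <- as.vector(aperm(pw, c(3, 2, 1)))
  attr(out, "freqs") <- freqs
  attr(out, "fs") <- epochs$fs
  attr(out, "channels") <- channels
  add_class(out, "power_spectra")
}

#' Baseline power spectrum
#'
#' Splits each baseline segment into non-overlapping sub-windows of
#' `window_len_s` seconds (1 s by default, so the bin grid matches 1-s
#' movement epochs exactly), estimates single-taper power per sub-window with
#' [epoch_power()], and averages over all sub-windows of all segments.
#'
#' @param baseline an `epoch_set` of baseline segments, each at least
#'   `window_len_s` long.
#' @param freqs requested bin centers in Hz.
#' @param window_len_s sub-window length in seconds.
#' @return a `baseline_spectrum` tibble with columns `channel`, `freq`,
#'   `power` (all strictly positive), one row per channel and bin.
#' @export
baseline_power <- function(baseline, freqs = analysis_freqs(),
                           window_len_s = 1) {
  stopifnot(inherits(baseline, "epoch_set"))
  d <- dim(baseline$data)
  n_win_samp <- as.integer(round(window_len_s * baseline$fs))
  if (d[3] < n_win_samp) {
    abort(sprintf(
      "baseline segments are %.3g s, shorter than the %.3g-s analysis window",
      d[3] / baseline$fs, window_len_s
    ))
  }
  n_win <- d[3] %/% n_win_samp
  # re-slice segments into sub-windows, stacked as pseudo-epochs
  sub <- array(NA_real_, dim = c(d[1] * n_win, d[2], n_win_samp))
  for (s in seq_len(d[1])) {
    for (wdw in seq_len(n_win)) {
      sub[(s - 1) * n_win + wdw, , ] <-
        baseline$data[s, , ((wdw - 1) * n_win_samp + 1):(wdw * n_win_samp)]
    }
  }
  windows <- baseline
  windows$data <- sub
  pw <- epoch_power(windows, freqs)
  out <- dplyr::summarise(dplyr::group_by(pw, .data$channel, .data$freq),
                          power = mean(.data$power), .groups = "drop")
  out <- dplyr::arrange(out, match(.data$channel, baseline$montage$channel),
                        .data$freq)
  if (any(out$power <= 0)) {
    abort("estimated baseline power is zero in at least one (channel, bin); it is the denominator of the percent-change spectrum")
  }
  attr(out, "freqs") <- freqs
  attr(out, "channels") <- baseline$montage$channel
  attr(out, "n_windows") <- d[1] * n_win
  add_class(out, "baseline_spectrum")
}

#' Baseline-relative percent power change
#'
#' The movement-related power change expressed as a percentage of baseline
#' power, per trial, channel and frequency bin:
#' `100 * (P_move - P_baseline) / P_baseline`. Values are bounded below by
#' -100 for valid (nonnegative) powers and are invariant to any common
#' rescaling of both spectra.
#'
#' @param move a `power_spectra` tibble from [epoch_power()].
#' @param base a `baseline_spectrum` tibble from [baseline_power()] on the
#'   identical frequency grid and channel set.
#' @return a `rel_power` tibble with columns `trial`, `channel`, `freq`,
#'   `rel_power` and attribute `level = "trial"`.
#' @export
relative_power <- function(move, base) {
  f_m <- sort(unique(move$freq)); f_b <- sort(unique(base$freq))
  if (length(f_m) != length(f_b) || any(abs(f_m - f_b) > 1e-9)) {
    abort("movement and baseline spectra are on different frequency grids")
  }
  ch_m <- unique(move$channel); ch_b <- unique(base$channel)
  if (!setequal(ch_m, ch_b)) {
    abort("movement and baseline spectra cover different channel sets")
  }
  out <- dplyr::left_join(move, dplyr::rename(base, base_power = "power"),
                          by = c("channel", "freq"))
  out <- dplyr::mutate(out,
                       rel_power = 100 * (.data$power - .data$base_power) /
                         .data$base_power)
  out <- dplyr::select(out, "trial", "channel", "freq", "rel_power")
  attr(out, "level") <- "trial"
  attr(out, "freqs") <- f_m
  add_class(tibble::as_tibble(out), "rel_power")
}

#' Average relative power over trials
#'
#' Arithmetic mean of the per-trial percent-change spectra per channel and
#' bin, giving the participant-level relative-power spectrum.
#'
#' @param rel a trial-level `rel_power` tibble.
#' @return a `rel_power` tibble with columns `channel`, `freq`, `rel_power`
#'   and attribute `level = "participant"`.
#' @export
average_trials <- function(rel) {
  if (!nrow(rel)) abort("cannot average an empty trial set")
  if (!"trial" %in% names(rel)) abort("expected a trial-level rel_power table")
  out <- dplyr::summarise(dplyr::group_by(rel, .data$channel, .data$freq),
                          rel_power = mean(.data$rel_power), .groups = "drop")
  attr(out, "level") <- "participant"
  attr(out, "freqs") <- sort(unique(out$freq))
  add_class(out, "rel_power")
}

#' Band-average of a relative-power spectrum
#'
#' Mean percent change over all bins inside `band` (both endpoints
#' inclusive), per channel. On the default 8-25 Hz grid the 8-25 band
#' averages all 18 bins.
#'
#' @param rel a participant-level `rel_power` tibble.
#' @param band numeric length-2, `c(f_lo, f_hi)` in Hz; both endpoints must
#'   lie on the grid.
#' @return tibble with columns `channel`, `value`.
#' @export
band_mean <- function(rel, band = c(8, 25)) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  freqs <- sort(unique(rel$freq))
  if (!any(abs(freqs - band[1]) < 1e-9) || !any(abs(freqs - band[2]) < 1e-9)) {
    abort(sprintf("band [%g, %g] Hz is not on the analysis grid (%g-%g Hz)",
                  band[1], band[2], min(freqs), max(freqs)))
  }
  sel <- dplyr::filter(rel, .data$freq >= band[1] - 1e-9,
                       .data$freq <= band[2] + 1e-9)
  dplyr::summarise(dplyr::group_by(sel, .data$channel),
                   value = mean(.data$rel_power), .groups = "drop")
}
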