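#' Normalize a relative-power spectrum to a probability vector
#'
#' The percent-change spectrum is turned into a discrete probability
#' distribution over bins by taking absolute magnitudes and normalizing:
#' `p_i = |x_i| / sum_j |x_j|`. The sign of the power change is deliberately
#' discarded; only how the change is distributed across bins matters.
#'
#' @param x numeric vector of per-bin relative power (>= 2 bins, not all
#'   zero).
#' @return probability vector summing to 1.
#' @export
normalize_spectrum <- function(x) {
  if (length(x) < 2) abort("need at least 2 frequency bins")
  if (any(!is.finite(x))) abort("relative-power spectrum contains non-finite values")
  total <- sum(abs(x))
  if (total == 0) abort("entropy undefined for null spectrum (all bins zero)")
  abs(x) / total
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the magnitude-normalized spectrum, scaled to `[0, 1]`:
#' `H = -(1 / ln N) * sum_i p_i ln p_i`, with `N` the number of bins and the
#' convention `0 * ln 0 = 0`. A flat spectrum (equal magnitude in every bin)
#' gives `H = 1`; a spectrum concentrated in a single bin gives `H = 0`.
#' High `H` therefore flags broadband, frequency-unspecific
#' desynchronization; low `H` flags a peaked, narrowband response.
#'
#' @inheritParams normalize_spectrum
#' @return entropy `H` in `[0, 1]`.
#' @examples
#' spectral_entropy(rep(-20, 18))                 # flat -> 1
#' spectral_entropy(c(60, rep(0, 17)))            # single bin -> 0
#' spectral_entropy(c(-50, -25, -12.5, -12.5))    # dyadic -> 0.875
#' @export
spectral_entropy <- function(x) {
  p <- normalize_spectrum(x)
  nz <- p > 0
  max(-sum(p[nz] * log(p[nz])) / log(length(p)), 0) + 0
}

#' Per-channel spectral entropy map
#'
#' Applies [spectral_entropy()] channel-wise to the band-restricted bins of a
#' participant-level relative-power spectrum. `N` in the entropy
#' normalization is the number of bins inside the band (18 for 8-25 Hz, 7 for
#' 13-19 Hz on the default grid).
#'
#' @param rel a participant-level `rel_power` tibble (see
#'   [average_trials()]); per-trial tables are accepted if `per_trial = TRUE`,
#'   in which case one entropy per trial and channel is returned.
#' @param band numeric `c(f_lo, f_hi)` in Hz, endpoints on the grid, at least
#'   2 bins wide.
#' @param per_trial compute entropy per trial instead of on the
#'   trial-averaged spectrum (non-default).
#' @return an `entropy_map` tibble with columns `channel` (and `trial` if
#'   `per_trial`), `H`, `n_bins`, `band_lo`, `band_hi`.
#' @export
entropy_map <- function(rel, band = c(8, 25), per_trial = FALSE) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  freqs <- sort(unique(rel$freq))
  in_band <- freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9
  n_bins <- sum(in_band)
  if (n_bins < 2) {
    abort(sprintf("band [%g, %g] Hz covers %d bin(s); entropy needs at least 2",
                  band[1], band[2], n_bins))
  }
  sel <- dplyr::filter(rel, .data$freq >= band[1] - 1e-9,
                       .data$freq <= band[2] + 1e-9)
  keys <- if (per_trial && "trial" %in% names(sel)) c("trial", "channel") else "channel"
  out <- dplyr::summarise(
    dplyr::group_by(sel, dplyr::across(dplyr::all_of(keys))),
    H = spectral_entropy(.data$rel_power), .groups = "drop"
  )
  out$n_bins <- n_bins
  out$band_lo <- band[1]
  out$band_hi <- band[2]
  add_class(out, "entropy_map")
}
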