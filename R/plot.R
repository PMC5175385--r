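#' Topographic channel map
#'
#' Schematic scalp plot of a per-channel quantity: one point per electrode at
#' its montage coordinate, filled by value, with significant channels (if a
#' `significant` column is present) marked by an asterisk, mirroring the
#' star-marked topographies conventionally used for sensor statistics.
#'
#' @param map tibble with a `channel` column and the value column.
#' @param montage a montage from [build_montage()] supplying coordinates.
#' @param value name of the column to display.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_topomap <- function(map, montage, value = "statistic", title = NULL) {
  if (!value %in% names(map)) {
    abort(sprintf("column '%s' not found in the map", value))
  }
  df <- dplyr::left_join(map, montage, by = "channel")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data[[value]]),
                        shape = 21, size = 9, colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), size = 2.3,
                       vjust = -2.2) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = value, title = title)
  if ("significant" %in% names(df)) {
    sig <- dplyr::filter(df, .data$significant)
    if (nrow(sig)) {
      p <- p + ggplot2::geom_text(data = sig, label = "*", size = 6,
                                  vjust = 0.8)
    }
  }
  p
}

#' Per-bin relative-power profile plot
#'
#' Group-mean percent power change per frequency bin, averaged over the ROI
#' channels, one bar pair per bin: the visual used to contrast a peaked
#' narrowband desynchronization profile with a flat broadband one.
#'
#' @param spectra participant-level spectra (see [participant_spectra()]).
#' @param roi channels to average over.
#' @param task optional task filter.
#' @return a ggplot object.
#' @export
plot_bin_spectrum <- function(spectra, roi = c("FC3", "C3", "CP3"),
                              task = NULL) {
  sel <- dplyr::filter(spectra, .data$channel %in% roi)
  if (!is.null(task)) sel <- dplyr::filter(sel, .data$task == .env$task)
  agg <- dplyr::summarise(
    dplyr::group_by(sel, .data$group, .data$freq),
    rel_power = mean(.data$rel_power), .groups = "drop"
  )
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$freq, y = .data$rel_power,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(elderly = "#b2182b",
                                          young = "#2166ac")) +
    ggplot2::labs(x = "frequency (Hz)", y = "relative power (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot channel_stat_map
#' @export
autoplot.channel_stat_map <- function(object, montage = NULL, ...) {
  if (is.null(montage)) {
    abort("supply the montage: autoplot(map, montage = build_montage(...))")
  }
  value <- if ("estimate" %in% names(object)) "estimate" else "statistic"
  plot_topomap(object, montage, value = value,
               title = attr(object, "metric"))
}

#' @method autoplot entropy_map
#' @export
autoplot.entropy_map <- function(object, montage = NULL, ...) {
  if (is.null(montage)) {
    abort("supply the montage: autoplot(map, montage = build_montage(...))")
  }
  plot_topomap(object, montage, value = "H",
               title = sprintf("spectral entropy %g-%g Hz",
                               object$band_lo[1], object$band_hi[1]))
}

#' @method autoplot bin_stat_map
#' @export
autoplot.bin_stat_map <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("freq", "mean_elderly", "mean_young")],
    cols = c("mean_elderly", "mean_young"),
    names_to = "group", values_to = "rel_power", names_prefix = "mean_"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$rel_power,
                                        fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(elderly = "#b2182b",
                                          young = "#2166ac")) +
    ggplot2::labs(x = "frequency (Hz)", y = "relative power (%)", fill = NULL) +
    ggplot2::theme_minimal()
  sig <- dplyr::filter(object, .data$significant)
  if (nrow(sig)) {
    p <- p + ggplot2::geom_point(
      data = sig, ggplot2::aes(x = .data$freq, y = 0), inherit.aes = FALSE,
      shape = 16, size = 1.5
    )
  }
  p
}
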