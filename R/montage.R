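#' Electrode montages
#'
#' Build a named electrode montage as a tibble of channel labels with schematic
#' 2-D head coordinates (arbitrary units, used only for topographic reporting).
#' Two presets are provided: `"full63"`, a 63-channel 10-10-style cap (a
#' standard 64-electrode layout with the Cz reference dropped), and `"toy16"`,
#' a 16-channel reduced cap for fast desk-scale runs. Both contain the left
#' (contralateral-to-right-hand) sensorimotor region of interest FC3, C3, CP3,
#' recorded in the `"roi_contralateral_sm"` attribute.
#'
#' @param preset montage name, `"toy16"` or `"full63"`.
#' @return A tibble with columns `channel`, `x`, `y` and attributes
#'   `roi_contralateral_sm` (character vector of ROI labels) and `preset`.
#' @examples
#' m <- build_montage("toy16")
#' nrow(m)
#' montage_roi(m)
#' @export
build_montage <- function(preset = c("toy16", "full63")) {
  if (!is.character(preset) || length(preset) != 1 ||
      !preset %in% c("toy16", "full63")) {
    abort(paste0(
      "unknown montage preset ", deparse(substitute(preset)), ": '",
      paste(as.character(preset), collapse = ","),
      "'; valid presets are 'toy16' and 'full63'"
    ))
  }
  labels <- montage_labels(preset)
  xy <- t(vapply(labels, channel_coord, numeric(2)))
  out <- tibble::tibble(channel = labels, x = unname(xy[, 1]),
                        y = unname(xy[, 2]))
  attr(out, "roi_contralateral_sm") <- c("FC3", "C3", "CP3")
  attr(out, "preset") <- preset
  add_class(out, "erd_montage")
}

#' @rdname build_montage
#' @param montage a montage tibble from [build_montage()].
#' @export
montage_roi <- function(montage) {
  roi <- attr(montage, "roi_contralateral_sm")
  if (is.null(roi)) roi <- c("FC3", "C3", "CP3")
  stopifnot(all(roi %in% montage$channel))
  roi
}

montage_labels <- function(preset) {
  if (preset == "toy16") {
    return(c(
      "Fp1", "Fz", "F3", "F4", "FC3", "FC4", "C3", "C4",
      "CP3", "CP4", "P3", "Pz", "P4", "O1", "Oz", "O2"
    ))
  }
  # 64-electrode 10-10 cap in vendor order, minus the Cz reference -> 63
  full <- c(
    "Fp1", "Fz", "F3", "F7", "FT9", "FC5", "FC1", "C3", "T7", "TP9",
    "CP5", "CP1", "Pz", "P3", "P7", "O1", "Oz", "O2", "P4", "P8",
    "TP10", "CP6", "CP2", "Cz", "C4", "T8", "FT10", "FC6", "FC2", "F4",
    "F8", "Fp2", "AF7", "AF3", "AFz", "F1", "F5", "FT7", "FC3", "C1",
    "C5", "TP7", "CP3", "P1", "P5", "PO7", "PO3", "POz", "PO4", "PO8",
    "P6", "P2", "CPz", "CP4", "TP8", "C6", "C2", "FC4", "FT8", "F6",
    "AF8", "AF4", "F2", "FCz"
  )
  setdiff(full, "Cz")
}

# schematic coordinates: anterior-posterior row from the label prefix,
# left-right from the 10-10 numbering (odd left, even right, z midline)
channel_coord <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+)$", label))[[1]]
  if (length(m) != 3) abort(paste0("cannot parse channel label '", label, "'"))
  prefix <- m[2]
  suffix <- m[3]
  rows <- c(
    Fp = 4, AF = 3.2, F = 2.4, FT = 1.2, FC = 1.2, T = 0, C = 0,
    TP = -1.2, CP = -1.2, P = -2.4, PO = -3.2, O = -4, I = -4.8
  )
  if (!prefix %in% names(rows)) {
    abort(paste0("unknown channel row prefix '", prefix, "' in '", label, "'"))
  }
  y <- unname(rows[prefix])
  if (suffix == "z") {
    x <- 0
  } else {
    n <- as.integer(suffix)
    x <- ceiling(n / 2) * if (n %% 2 == 1) -1 else 1
  }
  c(x, y)
}
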