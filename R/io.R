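#' Write and read a study directory
#'
#' A study is persisted as one little-endian float64 binary array per epoch
#' set plus a JSON sidecar per file (dimensions, sampling rate, state, group,
#' task, seed provenance) and a top-level `study.json` manifest (participant
#' table, montage, configuration summary). The round trip is bit-exact.
#'
#' @param study an `erd_study`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "erd_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_one <- function(ep, stem) {
    bin <- file.path(dir, paste0(stem, ".bin"))
    con <- file(bin, "wb")
    on.exit(close(con))
    writeBin(as.vector(ep$data), con, size = 8, endian = "little")
    jsonlite::write_json(
      list(dim = dim(ep$data), fs = ep$fs, state = ep$state,
           task = ep$task, participant_id = ep$participant_id,
           group = ep$group, channels = ep$montage$channel),
      file.path(dir, paste0(stem, ".json")),
      auto_unbox = TRUE, digits = NA
    )
    paste0(stem, ".bin")
  }
  files <- character()
  for (pid in study$participants$participant_id) {
    part <- study$data[[pid]]
    files <- c(files, write_one(part$baseline, paste0(pid, "_baseline")))
    for (task in names(part$movement)) {
      files <- c(files, write_one(part$movement[[task]],
                                  paste0(pid, "_task_", task)))
    }
  }
  cfg <- study$config
  jsonlite::write_json(
    list(
      participants = study$participants,
      montage = list(preset = attr(study$montage, "preset"),
                     channels = study$montage$channel,
                     x = study$montage$x, y = study$montage$y,
                     roi = montage_roi(study$montage)),
      config = list(seed = cfg$seed, fs = cfg$fs, tasks = cfg$tasks,
                    trials_per_task = cfg$trials_per_task,
                    epoch_len_s = cfg$epoch_len_s,
                    baseline_len_s = cfg$baseline_len_s,
                    n_baseline_segments = cfg$n_baseline_segments,
                    noise_exponent = cfg$noise_exponent,
                    between_subject_sd = cfg$between_subject_sd,
                    car = cfg$car),
      files = files
    ),
    file.path(dir, "study.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "study.json"),
                                  simplifyVector = TRUE)
  montage <- tibble::tibble(channel = manifest$montage$channels,
                            x = manifest$montage$x, y = manifest$montage$y)
  attr(montage, "roi_contralateral_sm") <- manifest$montage$roi
  attr(montage, "preset") <- manifest$montage$preset
  montage <- add_class(montage, "erd_montage")
  read_one <- function(stem) {
    side <- jsonlite::read_json(file.path(dir, paste0(stem, ".json")),
                                simplifyVector = TRUE)
    con <- file(file.path(dir, paste0(stem, ".bin")), "rb")
    on.exit(close(con))
    n <- prod(side$dim)
    vals <- readBin(con, "double", n = n, size = 8, endian = "little")
    structure(
      list(data = array(vals, dim = side$dim,
                        dimnames = list(NULL, side$channels, NULL)),
           fs = as.numeric(side$fs), montage = montage, state = side$state,
           task = if (is.null(side$task)) NULL else side$task,
           participant_id = side$participant_id, group = side$group),
      class = "epoch_set"
    )
  }
  participants <- tibble::as_tibble(manifest$participants)
  data <- list()
  for (pid in participants$participant_id) {
    bl <- read_one(paste0(pid, "_baseline"))
    task_stems <- grep(paste0("^", pid, "_task_"),
                       sub("\\.bin$", "", manifest$files), value = TRUE)
    mv <- list()
    for (stem in task_stems) {
      task <- sub(paste0("^", pid, "_task_"), "", stem)
      mv[[task]] <- read_one(stem)
    }
    data[[pid]] <- list(baseline = bl, movement = mv)
  }
  cfg <- manifest$config
  structure(
    list(participants = participants, montage = montage,
         config = c(cfg, list(montage = montage)), data = data),
    class = "erd_study"
  )
}

# ---- EDF (European Data Format) ---------------------------------------------
# Minimal continuous-EDF writer/reader: fixed-layout ASCII headers and 16-bit
# little-endian samples. Each epoch maps to one data record, each channel to
# one signal, so an epoch_set round-trips with only the 16-bit quantization
# error of the format.

edf_pad <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Export an epoch set to EDF
#'
#' Writes the epochs as a continuous EDF file: one data record per epoch, one
#' signal per channel, 16-bit samples scaled to the physical range of each
#' channel. EDF stores samples with 16-bit resolution, so values round-trip
#' only to within `(max - min) / 65535` per channel.
#'
#' @param epochs an `epoch_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
edf_write <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  n_rec <- d[1]; n_sig <- d[2]; n_samp <- d[3]
  duration <- n_samp / epochs$fs
  phys_min <- apply(epochs$data, 2, min)
  phys_max <- apply(epochs$data, 2, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1   # avoid zero scale for constant signals
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(paste("Startdate 01-JAN-2000", "X", "X", "X"), 80),
    "01.01.00", "00.00.00",
    edf_pad(256 * (1 + n_sig), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(format(duration, digits = 6), 8),
    edf_pad(n_sig, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(epochs$montage$channel, 16)
  field(rep("", n_sig), 80)
  field(rep("uV", n_sig), 8)
  field(formatC(phys_min, format = "g", digits = 6), 8)
  field(formatC(phys_max, format = "g", digits = 6), 8)
  field(rep(dig_min, n_sig), 8)
  field(rep(dig_max, n_sig), 8)
  field(rep("", n_sig), 80)
  field(rep(n_samp, n_sig), 8)
  field(rep("", n_sig), 32)

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      dig <- round((epochs$data[r, s, ] - phys_min[s]) / scale[s]) + dig_min
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a continuous uniformly sampled EDF file written by [edf_write()] or
#' any plain EDF with a common sampling rate across signals.
#'
#' @param path EDF file path.
#' @return list with `data` (records x signals x samples array), `fs`,
#'   `labels`, `record_duration_s`, `n_records`.
#' @export
edf_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  duration <- suppressWarnings(as.numeric(rd(8)))
  n_sig <- suppressWarnings(as.integer(rd(4)))
  bad <- length(n_rec) != 1 || length(n_sig) != 1 || length(duration) != 1 ||
    is.na(n_rec) || is.na(n_sig) || is.na(duration) || n_sig < 1
  if (bad) abort(paste0("'", path, "' is not a readable EDF file"))
  labels <- trimws(vapply(seq_len(n_sig), function(i) rd(16), ""))
  rd(80 * n_sig); rd(8 * n_sig)
  phys_min <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  rd(80 * n_sig)
  n_samp <- as.integer(vapply(seq_len(n_sig), function(i) rd(8), ""))
  rd(32 * n_sig)
  if (length(unique(n_samp)) != 1) {
    abort("EDF signals have differing sampling rates; uniform sampling required")
  }
  seek(con, header_bytes)
  ns <- n_samp[1]
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- array(NA_real_, dim = c(n_rec, n_sig, ns))
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * n_sig, size = 2, signed = TRUE,
                   endian = "little")
    if (length(raw) < ns * n_sig) abort("EDF file truncated (ragged records)")
    m <- matrix(raw, nrow = ns, ncol = n_sig)
    data[r, , ] <- t((m - rep(dig_min, each = ns)) * rep(scale, each = ns) +
                       rep(phys_min, each = ns))
  }
  list(data = data, fs = ns / duration, labels = labels,
       record_duration_s = duration, n_records = n_rec)
}

#' Import an EDF recording as an epoch set
#'
#' Reads a continuous EDF file, checks the sampling rate against the
#' configured value if given, and re-segments the signal into fixed-length
#' epochs: 1-s epochs for the movement state and 2-s segments for the
#' baseline state by default. If the left sensorimotor ROI channels are
#' missing, a warning is issued and the result is marked so ROI-based tests
#' can be skipped.
#'
#' @param path EDF file path.
#' @param state `"movement"` or `"baseline"`.
#' @param epoch_len_s segment length; default 1 s for movement, 2 s for
#'   baseline.
#' @param fs_expected if given, an error is raised when the file's sampling
#'   rate differs.
#' @param roi ROI channel labels to check for.
#' @return an `epoch_set`; attribute `roi_available` records whether all ROI
#'   channels are present.
#' @export
import_edf <- function(path, state = c("movement", "baseline"),
                       epoch_len_s = NULL, fs_expected = NULL,
                       roi = c("FC3", "C3", "CP3")) {
  state <- match.arg(state)
  raw <- edf_read(path)
  if (!is.null(fs_expected) && abs(raw$fs - fs_expected) > 1e-6) {
    abort(sprintf("EDF sampling rate %g Hz does not match configured %g Hz",
                  raw$fs, fs_expected))
  }
  if (is.null(epoch_len_s)) epoch_len_s <- if (state == "movement") 1 else 2
  n_ep_samp <- as.integer(round(epoch_len_s * raw$fs))
  d <- dim(raw$data)
  total <- d[1] * d[3]
  n_ep <- total %/% n_ep_samp
  if (n_ep < 1) abort("recording shorter than one epoch")
  # flatten records to a continuous signal, then cut fixed-length epochs
  cont <- matrix(NA_real_, nrow = d[2], ncol = total)
  for (r in seq_len(d[1])) {
    cont[, ((r - 1) * d[3] + 1):(r * d[3])] <- raw$data[r, , ]
  }
  data <- array(NA_real_, dim = c(n_ep, d[2], n_ep_samp),
                dimnames = list(NULL, raw$labels, NULL))
  for (e in seq_len(n_ep)) {
    data[e, , ] <- cont[, ((e - 1) * n_ep_samp + 1):(e * n_ep_samp)]
  }
  xy <- tryCatch(t(vapply(raw$labels, channel_coord, numeric(2))),
                 error = function(e) matrix(0, length(raw$labels), 2))
  montage <- tibble::tibble(channel = raw$labels, x = xy[, 1], y = xy[, 2])
  attr(montage, "roi_contralateral_sm") <- intersect(roi, raw$labels)
  montage <- add_class(montage, "erd_montage")
  roi_ok <- all(roi %in% raw$labels)
  if (!roi_ok) {
    warn(sprintf(
      "ROI channels missing from EDF (%s); ROI-based tests are disabled",
      paste(setdiff(roi, raw$labels), collapse = ", ")
    ))
  }
  out <- structure(
    list(data = data, fs = raw$fs, montage = montage, state = state,
         task = NULL, participant_id = NA_character_, group = NA_character_),
    class = "epoch_set"
  )
  attr(out, "roi_available") <- roi_ok
  out
}
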