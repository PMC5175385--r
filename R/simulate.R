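#' Simulate a set of EEG epochs
#'
#' Generates `n_epochs` independent multichannel epochs whose expected
#' one-sided power spectral density equals [psd_target()] for the given
#' profile and state. Epochs are synthesized in the frequency domain: each
#' positive-frequency DFT coefficient is drawn as a circular complex Gaussian
#' with `E|X_k|^2 = S(f_k) * fs * N / 2`, the spectrum is Hermitian-completed
#' and inverse-transformed, which yields a stationary Gaussian process with
#' exactly the target spectrum in expectation. Generation is fully seeded and
#' reproducible: identical arguments give bit-identical arrays.
#'
#' @param profile an `erd_profile` (see [modulation_profile()]).
#' @param montage a montage from [build_montage()].
#' @param state `"baseline"` or `"movement"`; in the movement state each
#'   oscillatory component's PSD is scaled by `1 - d`.
#' @param n_epochs number of epochs.
#' @param duration_s epoch duration in seconds; `duration_s * fs` must be an
#'   even integer.
#' @param fs sampling rate in Hz.
#' @param noise_exponent exponent of the `1/f^beta` background.
#' @param seed integer random seed (required).
#' @param task task name (used for per-task depth scaling and recorded in the
#'   result).
#' @param noise_scale background PSD at 1 Hz.
#' @param depth_multiplier per-participant depth jitter multiplier.
#' @param participant_id,group metadata carried into the result.
#' @return An `epoch_set`: list with `data` (array `n_epochs x n_channels x
#'   n_samples`), `fs`, `montage`, `state`, `task`, `participant_id`, `group`.
#' @examples
#' m <- build_montage("toy16")
#' ep <- simulate_epochs(modulation_preset("young"), m, "baseline",
#'                       n_epochs = 3, duration_s = 1, fs = 128, seed = 1)
#' dim(ep$data)
#' @export
simulate_epochs <- function(profile, montage, state = c("baseline", "movement"),
                            n_epochs, duration_s, fs = 1000,
                            noise_exponent = 1, seed, task = NULL,
                            noise_scale = 1, depth_multiplier = 1,
                            participant_id = NA_character_,
                            group = NA_character_) {
  state <- match.arg(state)
  if (missing(seed) || is.null(seed)) abort("simulate_epochs requires a seed")
  n_samp <- duration_s * fs
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    abort("duration_s * fs must be an integer number of samples")
  }
  n_samp <- as.integer(round(n_samp))
  if (n_samp %% 2L != 0L) abort("duration_s * fs must be even")
  if (n_epochs < 1) abort("n_epochs must be >= 1")
  channels <- montage$channel
  n_ch <- length(channels)

  # target one-sided PSD on the positive DFT grid (excludes DC)
  k <- seq_len(n_samp / 2)          # bins 1 .. N/2 (last = Nyquist)
  f_grid <- k / duration_s
  S <- psd_target(profile, channels, f_grid, state = state, task = task,
                  noise_exponent = noise_exponent, noise_scale = noise_scale,
                  depth_multiplier = depth_multiplier)
  amp <- sqrt(S * fs * n_samp / 2)  # channels x bins, sd of each DFT coeff

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  n_pos <- n_samp / 2 - 1L
  data <- array(NA_real_, dim = c(n_epochs, n_ch, n_samp),
                dimnames = list(NULL, channels, NULL))
  X <- matrix(0 + 0i, nrow = n_samp, ncol = n_ch)
  for (e in seq_len(n_epochs)) {
    # epoch-major, channel-column draw order (documented for reproducibility)
    z_re <- matrix(rnorm(n_pos * n_ch), n_pos, n_ch)
    z_im <- matrix(rnorm(n_pos * n_ch), n_pos, n_ch)
    z_ny <- rnorm(n_ch)
    X[2:(n_pos + 1L), ] <- t(amp[, seq_len(n_pos), drop = FALSE]) *
      complex(real = z_re, imaginary = z_im) / sqrt(2)
    X[n_samp / 2 + 1L, ] <- amp[, n_pos + 1L] * z_ny
    X[seq(n_samp, n_samp / 2 + 2L), ] <- Conj(X[2:(n_pos + 1L), ])
    x <- Re(stats::mvfft(X, inverse = TRUE)) / n_samp
    data[e, , ] <- t(x)
  }
  structure(
    list(data = data, fs = fs, montage = montage, state = state, task = task,
         participant_id = participant_id, group = group),
    class = "epoch_set"
  )
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples @ %g Hz (%s%s)\n",
    d[1], d[2], d[3], x$fs, x$state,
    if (!is.null(x$task) && !is.na(x$task[1])) paste0(", task ", x$task) else ""
  ))
  invisible(x)
}

#' Common average reference
#'
#' Re-references every channel to the instantaneous mean over all channels,
#' the reference used for all downstream sensor-level analyses.
#'
#' @param epochs an `epoch_set`.
#' @return the `epoch_set` with the channel mean subtracted at every sample.
#' @export
common_average_reference <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- epochs$data
  mean_sig <- colMeans(aperm(d, c(2, 1, 3)))  # epochs x samples
  for (ch in seq_len(dim(d)[2])) d[, ch, ] <- d[, ch, ] - mean_sig
  epochs$data <- d
  epochs
}

#' Amplitude-threshold epoch rejection
#'
#' Drops epochs whose absolute amplitude exceeds `threshold` on any channel.
#' Synthetic data are artifact-free, so this is off by default in the
#' pipeline; it exists for imported recordings.
#'
#' @param epochs an `epoch_set`.
#' @param threshold rejection threshold in the data's amplitude units.
#' @return the `epoch_set` restricted to retained epochs, with attribute
#'   `n_rejected`.
#' @export
reject_epochs <- function(epochs, threshold) {
  stopifnot(inherits(epochs, "epoch_set"), threshold > 0)
  peak <- apply(abs(epochs$data), 1, max)
  keep <- peak <= threshold
  if (!any(keep)) abort("amplitude threshold rejected every epoch")
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  attr(epochs, "n_rejected") <- sum(!keep)
  epochs
}

#' Study-level simulation configuration
#'
#' Bundles every knob of the synthetic study. Defaults emulate the recorded
#' cohort: 32 elderly and 34 young participants, two grip tasks with 64
#' trials each, 1000-Hz sampling, 1-s movement epochs, 2-s baseline segments
#' (60 of them, i.e. 2 minutes of rest), a `1/f` background, group presets
#' from [modulation_preset()], 10% between-participant jitter of
#' desynchronization depth, and common-average re-referencing.
#'
#' @param n_per_group participants per group; scalar or named vector with
#'   names `elderly` and `young`.
#' @param tasks character vector of task names.
#' @param trials_per_task movement epochs per participant and task.
#' @param fs sampling rate (Hz).
#' @param epoch_len_s movement epoch length (s).
#' @param baseline_len_s baseline segment length (s).
#' @param n_baseline_segments number of baseline segments per participant.
#' @param noise_exponent background `1/f^beta` exponent.
#' @param noise_scale background PSD at 1 Hz.
#' @param profiles named list of `erd_profile`s, one per group.
#' @param between_subject_sd SD of the per-participant multiplicative depth
#'   jitter (multiplier ~ Normal(1, sd), effective depth truncated to
#'   `[0, 0.95]`).
#' @param montage montage preset name or a montage tibble.
#' @param car apply common-average reference to every generated epoch set.
#' @param seed master seed; all per-participant sub-seeds derive from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_group = c(elderly = 32, young = 34),
                       tasks = c("pinch_grip", "whole_hand_grip"),
                       trials_per_task = 64,
                       fs = 1000, epoch_len_s = 1, baseline_len_s = 2,
                       n_baseline_segments = 60,
                       noise_exponent = 1, noise_scale = 1,
                       profiles = list(elderly = modulation_preset("elderly"),
                                       young = modulation_preset("young")),
                       between_subject_sd = 0.1,
                       montage = "full63", car = TRUE, seed = 1) {
  if (length(n_per_group) == 1) {
    n_per_group <- c(elderly = unname(n_per_group), young = unname(n_per_group))
  }
  stopifnot(all(c("elderly", "young") %in% names(n_per_group)),
            all(n_per_group >= 1), trials_per_task >= 1,
            epoch_len_s > 0, baseline_len_s > 0, n_baseline_segments >= 1,
            length(tasks) >= 1,
            all(c("elderly", "young") %in% names(profiles)))
  if (fs * epoch_len_s < 2 * 25) {
    abort("fs * epoch_len_s must be at least twice the highest analysis frequency (25 Hz)")
  }
  if (is.character(montage)) montage <- build_montage(montage)
  structure(
    list(n_per_group = n_per_group, tasks = tasks,
         trials_per_task = trials_per_task, fs = fs,
         epoch_len_s = epoch_len_s, baseline_len_s = baseline_len_s,
         n_baseline_segments = n_baseline_segments,
         noise_exponent = noise_exponent, noise_scale = noise_scale,
         profiles = profiles, between_subject_sd = between_subject_sd,
         montage = montage, car = car, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# deterministic sub-seed scheme: participant/block counters hashed with the
# master seed; independent of generation order, always < 2^31
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 48271 + counter * 1299709) %% 2147483647)
}

#' Simulate a full two-group study
#'
#' Draws a per-participant depth jitter multiplier, then generates one
#' baseline `epoch_set` and one movement `epoch_set` per task for every
#' participant, each from a deterministic sub-seed of the master seed.
#'
#' @param config a [sim_config()].
#' @return an `erd_study`: list with `participants` (tibble of
#'   `participant_id`, `group`, `depth_multiplier`, `seed_base`), `montage`,
#'   `config`, and `data` (per participant: `baseline` epoch_set, `movement`
#'   named list of epoch_sets by task, and the participant `profile`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  groups <- c(rep("elderly", config$n_per_group[["elderly"]]),
              rep("young", config$n_per_group[["young"]]))
  ids <- sprintf("%s_%02d", groups,
                 c(seq_len(config$n_per_group[["elderly"]]),
                   seq_len(config$n_per_group[["young"]])))
  n_part <- length(ids)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)
  mult <- if (config$between_subject_sd > 0) {
    rnorm(n_part, mean = 1, sd = config$between_subject_sd)
  } else {
    rep(1, n_part)
  }
  mult <- pmax(mult, 0)

  n_blocks <- length(config$tasks) + 1L
  data <- vector("list", n_part)
  names(data) <- ids
  for (p in seq_len(n_part)) {
    prof <- config$profiles[[groups[p]]]
    base_counter <- (p - 1L) * n_blocks
    bl <- simulate_epochs(
      prof, config$montage, "baseline",
      n_epochs = config$n_baseline_segments,
      duration_s = config$baseline_len_s, fs = config$fs,
      noise_exponent = config$noise_exponent,
      seed = derive_seed(config$seed, base_counter + 1L),
      noise_scale = config$noise_scale, depth_multiplier = mult[p],
      participant_id = ids[p], group = groups[p]
    )
    if (config$car) bl <- common_average_reference(bl)
    mv <- list()
    for (ti in seq_along(config$tasks)) {
      ep <- simulate_epochs(
        prof, config$montage, "movement",
        n_epochs = config$trials_per_task,
        duration_s = config$epoch_len_s, fs = config$fs,
        noise_exponent = config$noise_exponent,
        seed = derive_seed(config$seed, base_counter + 1L + ti),
        task = config$tasks[ti],
        noise_scale = config$noise_scale, depth_multiplier = mult[p],
        participant_id = ids[p], group = groups[p]
      )
      if (config$car) ep <- common_average_reference(ep)
      mv[[config$tasks[ti]]] <- ep
    }
    data[[p]] <- list(baseline = bl, movement = mv, profile = prof,
                      depth_multiplier = mult[p])
  }
  structure(
    list(
      participants = tibble::tibble(
        participant_id = ids, group = groups, depth_multiplier = mult,
        seed_base = derive_seed(config$seed,
                                (seq_len(n_part) - 1L) * n_blocks + 1L)
      ),
      montage = config$montage, config = config, data = data
    ),
    class = "erd_study"
  )
}

#' @export
print.erd_study <- function(x, ...) {
  cat(sprintf(
    "<erd_study> %d participants (%d elderly, %d young), tasks: %s, %d channels\n",
    nrow(x$participants), sum(x$participants$group == "elderly"),
    sum(x$participants$group == "young"),
    paste(x$config$tasks, collapse = ", "), nrow(x$montage)
  ))
  invisible(x)
}
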