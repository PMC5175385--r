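#' Movement-related modulation profiles
#'
#' A modulation profile describes the oscillatory content of the simulated EEG
#' and how it is suppressed during movement. Each component is a Gaussian
#' spectral bump with a center frequency, a full-width-at-half-maximum
#' bandwidth, a peak power spectral density (`amplitude`, arbitrary power
#' units per Hz), a set of affected channels, and a desynchronization depth
#' `d` in `[0, 1)`: during movement the component's PSD is multiplied by
#' `1 - d` (equivalently, its amplitude by `sqrt(1 - d)`), so `d` is exactly
#' the fractional power decrease at the component peak. An optional named
#' `task_scale` vector rescales `d` per task (tasks not named get scale 1),
#' which is how task-specific responses are expressed.
#'
#' @param components a tibble/data frame with columns `component`,
#'   `center_hz`, `bandwidth_hz`, `amplitude`, `depth`, `channels`
#'   (list-column of character vectors) and optionally `task_scale`
#'   (list-column of named numeric vectors, or `NULL` entries).
#' @param name profile label (e.g. the group it represents).
#' @return An `erd_profile` tibble.
#' @export
modulation_profile <- function(components, name = "custom") {
  comp <- tibble::as_tibble(components)
  needed <- c("component", "center_hz", "bandwidth_hz", "amplitude", "depth",
              "channels")
  missing <- setdiff(needed, names(comp))
  if (length(missing)) {
    abort(paste0("modulation profile lacks columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (!"task_scale" %in% names(comp)) {
    comp$task_scale <- vector("list", nrow(comp))
  }
  if (any(comp$depth < 0)) abort("desynchronization depth must be >= 0")
  if (any(comp$depth >= 1)) {
    abort("desynchronization depth must be < 1 (depth 1 would imply zero movement power)")
  }
  if (any(comp$amplitude < 0)) abort("component amplitude must be >= 0")
  if (any(comp$bandwidth_hz <= 0)) abort("component bandwidth must be > 0")
  attr(comp, "profile_name") <- name
  add_class(comp, "erd_profile")
}

#' Preset group profiles
#'
#' `"young"` concentrates deep desynchronization in two narrow components,
#' a mu rhythm near 10 Hz and a beta rhythm near 20 Hz, confined to the left
#' sensorimotor channels FC3/C3/CP3, with a task-dependent depth (the
#' whole-hand grip desynchronizes less than the pinch grip). `"elderly"`
#' spreads a shallower-per-bin but broadband (8-25 Hz) desynchronization over
#' a wider channel set that also covers frontal and ipsilateral sensorimotor
#' sites, identically in all tasks. `"none"` carries the same oscillatory
#' components as `"elderly"` but zero depth everywhere (a null group for
#' calibration studies).
#'
#' Component amplitudes are set roughly 4-6x the 1/f background at the
#' component peak so that the percent power change at an affected bin is
#' dominated by the oscillatory component.
#'
#' @param name `"young"`, `"elderly"` or `"none"`.
#' @return An `erd_profile` tibble.
#' @export
modulation_preset <- function(name = c("young", "elderly", "none")) {
  name <- match.arg(name)
  roi <- c("FC3", "C3", "CP3")
  wide <- c("F3", "Fz", "F4", "FC3", "FC4", "C3", "C4", "CP3", "CP4")
  ts_young <- c(pinch_grip = 1, whole_hand_grip = 0.65)
  comp <- switch(name,
    young = tibble::tibble(
      component = c("mu", "beta"),
      center_hz = c(10, 20),
      bandwidth_hz = c(2, 2.5),
      amplitude = c(0.6, 0.35),
      depth = c(0.75, 0.7),
      channels = list(roi, roi),
      task_scale = list(ts_young, ts_young)
    ),
    elderly = tibble::tibble(
      component = "broadband",
      center_hz = 16.5,
      bandwidth_hz = 17,
      amplitude = 0.4,
      depth = 0.45,
      channels = list(wide),
      task_scale = list(NULL)
    ),
    none = tibble::tibble(
      component = "broadband",
      center_hz = 16.5,
      bandwidth_hz = 17,
      amplitude = 0.4,
      depth = 0,
      channels = list(wide),
      task_scale = list(NULL)
    )
  )
  modulation_profile(comp, name = name)
}

# depth actually applied for a component in a given state/task, after the
# per-participant multiplicative jitter; truncated to [0, 0.95]
effective_depth <- function(depth, task_scale, task, depth_multiplier = 1) {
  sc <- 1
  if (!is.null(task_scale) && !is.null(task) && task %in% names(task_scale)) {
    sc <- unname(task_scale[[task]])
  }
  pmin(pmax(depth * sc * depth_multiplier, 0), 0.95)
}

#' Target power spectral density of the generator
#'
#' The one-sided PSD the synthetic-EEG generator aims at, per channel and
#' frequency: a `1/f^beta` colored background plus Gaussian oscillatory
#' components, the latter multiplied by `1 - d` in the movement state. This is
#' the analytic reference against which estimated spectra can be compared.
#'
#' @param profile an `erd_profile`.
#' @param channels character vector of channel labels.
#' @param freqs frequencies in Hz (> 0).
#' @param state `"baseline"` or `"movement"`.
#' @param task task name used to look up per-task depth scaling.
#' @param noise_exponent exponent beta of the `1/f^beta` background.
#' @param noise_scale background PSD at 1 Hz (arbitrary power units per Hz).
#' @param depth_multiplier per-participant multiplicative jitter on depth.
#' @return matrix `length(channels) x length(freqs)` of PSD values, with
#'   dimnames `(channel, freq)`.
#' @export
psd_target <- function(profile, channels, freqs,
                       state = c("baseline", "movement"), task = NULL,
                       noise_exponent = 1, noise_scale = 1,
                       depth_multiplier = 1) {
  state <- match.arg(state)
  stopifnot(all(freqs > 0))
  S <- matrix(rep(noise_scale / freqs^noise_exponent, each = length(channels)),
              nrow = length(channels),
              dimnames = list(channels, as.character(freqs)))
  for (i in seq_len(nrow(profile))) {
    ch <- intersect(profile$channels[[i]], channels)
    if (!length(ch)) next
    shape <- exp(-4 * log(2) * (freqs - profile$center_hz[i])^2 /
                   profile$bandwidth_hz[i]^2)
    gain <- 1
    if (state == "movement") {
      d <- effective_depth(profile$depth[i], profile$task_scale[[i]], task,
                           depth_multiplier)
      if (d >= 1) abort("effective desynchronization depth >= 1 is non-physical")
      gain <- 1 - d
    }
    S[ch, ] <- S[ch, , drop = FALSE] +
      rep(profile$amplitude[i] * gain * shape, each = length(ch))
  }
  S
}
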