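toy <- build_montage("toy16")

one_comp <- function(depth, amplitude = 0.5, channels = "C3") {
  modulation_profile(tibble::tibble(
    component = "osc", center_hz = 10, bandwidth_hz = 2,
    amplitude = amplitude, depth = depth, channels = list(channels)
  ))
}

mean_psd <- function(ep, freqs = analysis_freqs()) {
  pw <- epoch_power(ep, freqs)
  dplyr::summarise(dplyr::group_by(pw, .data$channel, .data$freq),
                   power = mean(power), .groups = "drop")
}

test_that("identical seeds reproduce epochs bit-for-bit and leave the RNG alone", {
  set.seed(99)
  before <- .Random.seed
  a <- simulate_epochs(one_comp(0.3), toy, "movement", n_epochs = 4,
                       duration_s = 1, fs = 128, seed = 7)
  expect_identical(before, .Random.seed)
  b <- simulate_epochs(one_comp(0.3), toy, "movement", n_epochs = 4,
                       duration_s = 1, fs = 128, seed = 7)
  expect_identical(a$data, b$data)
  c <- simulate_epochs(one_comp(0.3), toy, "movement", n_epochs = 4,
                       duration_s = 1, fs = 128, seed = 8)
  expect_false(identical(a$data, c$data))
  expect_true(all(is.finite(a$data)))
})

test_that("zero depth makes movement and baseline spectra indistinguishable", {
  prof <- one_comp(0)
  bl <- simulate_epochs(prof, toy, "baseline", n_epochs = 500,
                        duration_s = 1, fs = 128, seed = 11)
  mv <- simulate_epochs(prof, toy, "movement", n_epochs = 500,
                        duration_s = 1, fs = 128, seed = 12)
  pb <- mean_psd(bl); pm <- mean_psd(mv)
  # per bin, averaged over epochs and channels (identical statistics)
  bb <- dplyr::summarise(dplyr::group_by(pb, .data$freq),
                         power = mean(power), .groups = "drop")
  mm <- dplyr::summarise(dplyr::group_by(pm, .data$freq),
                         power = mean(power), .groups = "drop")
  rel_diff <- abs(mm$power - bb$power) / bb$power
  expect_lt(max(rel_diff), 0.05)
})

test_that("configured depth is recovered as the movement/baseline PSD ratio", {
  prof <- one_comp(0.5)
  bl <- simulate_epochs(prof, toy, "baseline", n_epochs = 500, duration_s = 1,
                        fs = 128, seed = 21, noise_scale = 1e-3)
  mv <- simulate_epochs(prof, toy, "movement", n_epochs = 500, duration_s = 1,
                        fs = 128, seed = 22, noise_scale = 1e-3)
  pb <- mean_psd(bl); pm <- mean_psd(mv)
  at10 <- function(p) p$power[p$channel == "C3" & p$freq == 10]
  expect_equal(at10(pm) / at10(pb), 0.5, tolerance = 0.1)
  # untouched channel is unchanged
  c4_ratio <- pm$power[pm$channel == "C4" & pm$freq == 10] /
    pb$power[pb$channel == "C4" & pb$freq == 10]
  expect_equal(c4_ratio, 1, tolerance = 0.15)
})

test_that("epoch-averaged PSD matches the analytic generator target", {
  prof <- one_comp(0.4, amplitude = 0.3)
  bl <- simulate_epochs(prof, toy, "baseline", n_epochs = 150,
                        duration_s = 2, fs = 128, seed = 31)
  bp <- baseline_power(bl)   # 300 one-second sub-windows
  target <- psd_target(prof, toy$channel, analysis_freqs(),
                       state = "baseline")
  # background-only channels: average over channels to beat estimator noise
  bg_ch <- setdiff(toy$channel, "C3")
  est <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(bp, .data$channel %in% bg_ch), .data$freq),
    power = mean(power), .groups = "drop"
  )
  expect_lt(max(abs(est$power - target["C4", ]) / target["C4", ]), 0.05)
  # the component peak on C3 is present at roughly the configured height
  c3 <- bp$power[bp$channel == "C3" & bp$freq == 10]
  expect_equal(c3, unname(target["C3", "10"]), tolerance = 0.2)
})

test_that("non-physical or malformed generator inputs error", {
  expect_error(one_comp(1.0), "depth")
  expect_error(one_comp(-0.1), "depth")
  expect_error(
    simulate_epochs(one_comp(0.3), toy, "movement", n_epochs = 2,
                    duration_s = 1.0007, fs = 128, seed = 1),
    "integer"
  )
  expect_error(
    simulate_epochs(one_comp(0.3), toy, "movement", n_epochs = 2,
                    duration_s = 1, fs = 128),
    "seed"
  )
})

test_that("common average reference zeroes the channel mean", {
  ep <- simulate_epochs(one_comp(0.3), toy, "baseline", n_epochs = 3,
                        duration_s = 1, fs = 128, seed = 5)
  car <- common_average_reference(ep)
  sums <- apply(car$data, c(1, 3), mean)
  expect_lt(max(abs(sums)), 1e-12)
})

test_that("amplitude-threshold rejection drops only extreme epochs", {
  ep <- simulate_epochs(one_comp(0), toy, "baseline", n_epochs = 10,
                        duration_s = 1, fs = 128, seed = 6)
  ep$data[3, 1, 5] <- 1e6
  kept <- reject_epochs(ep, threshold = 1e3)
  expect_equal(dim(kept$data)[1], 9)
  expect_equal(attr(kept, "n_rejected"), 1)
  expect_error(reject_epochs(ep, threshold = 1e-9), "every epoch")
})

small_cfg <- function(seed = 42, ...) {
  sim_config(n_per_group = 2, tasks = "grip", trials_per_task = 3,
             fs = 128, n_baseline_segments = 2, montage = "toy16",
             seed = seed, ...)
}

test_that("simulate_study produces the configured study layout", {
  study <- simulate_study(small_cfg())
  expect_s3_class(study, "erd_study")
  expect_equal(nrow(study$participants), 4)
  expect_equal(sort(unique(study$participants$group)), c("elderly", "young"))
  for (pid in study$participants$participant_id) {
    part <- study$data[[pid]]
    expect_equal(part$baseline$state, "baseline")
    expect_equal(names(part$movement), "grip")
    expect_equal(dim(part$movement$grip$data), c(3, 16, 128))
    expect_equal(dim(part$baseline$data), c(2, 16, 256))
  }
})

test_that("study generation is deterministic in the master seed", {
  a <- simulate_study(small_cfg())
  b <- simulate_study(small_cfg())
  expect_identical(
    a$data$elderly_01$movement$grip$data,
    b$data$elderly_01$movement$grip$data
  )
  expect_identical(a$participants, b$participants)
  c <- simulate_study(small_cfg(seed = 43))
  expect_false(identical(a$data$elderly_01$movement$grip$data,
                         c$data$elderly_01$movement$grip$data))
})

test_that("zero between-subject jitter gives identical within-group profiles", {
  study <- simulate_study(small_cfg(between_subject_sd = 0))
  expect_true(all(study$participants$depth_multiplier == 1))
  expect_identical(study$data$elderly_01$profile, study$data$elderly_02$profile)
})
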