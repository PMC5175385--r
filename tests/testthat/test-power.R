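toy <- build_montage("toy16")

# hand-built epoch_set around an arbitrary trials x channels x samples array
manual_epochs <- function(data, fs, montage = toy, state = "movement") {
  structure(list(data = data, fs = fs, montage = montage, state = state,
                 task = NULL, participant_id = "p1", group = "young"),
            class = "epoch_set")
}

test_that("a constant (DC) epoch carries no power in any analysis bin", {
  d <- array(3.7, dim = c(1, 16, 100))
  pw <- epoch_power(manual_epochs(d, fs = 100))
  expect_lt(max(pw$power), 1e-20)
})

test_that("a pure sinusoid concentrates power at its own bin", {
  t <- (0:999) / 1000
  x <- sin(2 * pi * 10 * t)
  d <- array(rep(x, each = 16), dim = c(1, 16, 1000))
  pw <- epoch_power(manual_epochs(d, fs = 1000))
  c3 <- dplyr::filter(pw, channel == "C3")
  expect_equal(c3$freq[which.max(c3$power)], 10)
})

test_that("the taper normalization makes a unit sinusoid fs-invariant", {
  val <- sapply(c(128, 500, 1000), function(fs) {
    t <- (0:(fs - 1)) / fs
    d <- array(rep(sin(2 * pi * 10 * t), each = 16), dim = c(1, 16, fs))
    pw <- epoch_power(manual_epochs(d, fs = fs))
    pw$power[pw$channel == "C3" & pw$freq == 10]
  })
  # one-sided PSD of a unit sinusoid at a bin center is T/3 for a 1-s epoch
  expect_equal(val, rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("epoch_power agrees with a naively coded DFT oracle", {
  set.seed(10)
  for (rep in 1:5) {
    x <- rnorm(100)
    d <- array(rep(x, each = 16), dim = c(1, 16, 100))
    pw <- epoch_power(manual_epochs(d, fs = 100))
    got <- pw$power[pw$channel == "C3"]
    want <- oracle_hann_power(x, analysis_freqs(), fs = 100)
    expect_lt(max(abs(got - want) / pmax(want, 1e-300)), 1e-9)
  }
})

test_that("white-noise epoch-averaged power is flat across bins", {
  set.seed(20)
  d <- array(rnorm(1000 * 1 * 100), dim = c(1000, 1, 100))
  m <- tibble::tibble(channel = "C3", x = -2, y = 0)
  attr(m, "roi_contralateral_sm") <- "C3"
  pw <- epoch_power(manual_epochs(d, fs = 100, montage = m))
  avg <- dplyr::summarise(dplyr::group_by(pw, freq), power = mean(power),
                          .groups = "drop")
  expect_lt(max(avg$power) / min(avg$power), 1.2)
})

test_that("off-grid or too-low frequencies are rejected with the resolution", {
  d <- array(rnorm(16 * 100), dim = c(1, 16, 100))
  ep <- manual_epochs(d, fs = 100)
  expect_error(epoch_power(ep, freqs = 10.5), "resolution")
  short <- manual_epochs(array(rnorm(16 * 50), dim = c(1, 16, 50)), fs = 100)
  expect_error(epoch_power(short, freqs = 2), "two cycles")
})

test_that("baseline segments are split into exact 1-s sub-windows and averaged", {
  set.seed(30)
  x1 <- rnorm(100); x2 <- rnorm(100)
  seg <- array(rep(c(x1, x2), each = 16), dim = c(1, 16, 200))
  bp <- baseline_power(manual_epochs(seg, fs = 100, state = "baseline"))
  expect_equal(attr(bp, "n_windows"), 2)
  want <- (oracle_hann_power(x1, analysis_freqs(), 100) +
             oracle_hann_power(x2, analysis_freqs(), 100)) / 2
  got <- bp$power[bp$channel == "C3"]
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("baseline segments shorter than the analysis window error", {
  seg <- array(rnorm(16 * 50), dim = c(1, 16, 50))
  expect_error(baseline_power(manual_epochs(seg, fs = 100)), "shorter")
})

test_that("relative power implements the percent-change identities", {
  base <- tibble::tibble(channel = rep(c("C3", "C4"), each = 2),
                         freq = rep(c(10, 11), 2), power = c(10, 10, 4, 4))
  move <- tidyr::expand_grid(trial = 1:2, channel = c("C3", "C4"),
                             freq = c(10, 11))
  move$power <- c(10, 10, 4, 4, 8, 0, 4, 4)  # trial2: C3 drops
  rel <- relative_power(move, base)
  expect_equal(rel$rel_power[rel$trial == 1], rep(0, 4))       # move == base
  r2 <- dplyr::filter(rel, trial == 2)
  expect_equal(r2$rel_power[r2$channel == "C3" & r2$freq == 10], -20)
  expect_equal(r2$rel_power[r2$channel == "C3" & r2$freq == 11], -100)
  expect_true(all(rel$rel_power >= -100))
})

test_that("percent change is invariant to common rescaling of both spectra", {
  set.seed(40)
  base <- tidyr::expand_grid(channel = c("C3", "C4"), freq = 8:25)
  base$power <- runif(nrow(base), 0.5, 2)
  move <- tidyr::expand_grid(trial = 1:3, channel = c("C3", "C4"), freq = 8:25)
  move$power <- runif(nrow(move), 0, 2)
  r1 <- relative_power(move, base)
  move2 <- move; move2$power <- move2$power * 7.3
  base2 <- base; base2$power <- base2$power * 7.3
  r2 <- relative_power(move2, base2)
  expect_equal(r1$rel_power, r2$rel_power, tolerance = 1e-12)
})

test_that("grid mismatches between movement and baseline are rejected", {
  base <- tibble::tibble(channel = "C3", freq = c(10, 11), power = c(1, 1))
  move <- tidyr::expand_grid(trial = 1, channel = "C3", freq = c(10, 12))
  move$power <- 1
  expect_error(relative_power(move, base), "grid")
})

test_that("trial averaging is the arithmetic mean and is order-invariant", {
  rel <- tidyr::expand_grid(trial = 1:2, channel = "C3", freq = c(10, 11))
  rel$rel_power <- c(-10, -40, -30, -20)
  avg <- average_trials(rel)
  expect_equal(avg$rel_power, c(-20, -30))
  perm <- rel[c(3, 1, 4, 2), ]
  expect_equal(average_trials(perm)$rel_power, avg$rel_power)
  one <- dplyr::filter(rel, trial == 1)
  expect_equal(average_trials(one)$rel_power, one$rel_power)
  expect_error(average_trials(rel[0, ]), "empty")
})

test_that("band_mean averages inclusive bins and knows the default 18-bin band", {
  rel <- tidyr::expand_grid(channel = c("C3", "C4"), freq = 8:25)
  rel$rel_power <- -15
  expect_equal(band_mean(rel, c(8, 25))$value, c(-15, -15))
  rel2 <- rel
  rel2$rel_power <- rep(seq(-18, -1), times = 2)[order(rep(1:2, each = 18))]
  rel2 <- dplyr::arrange(tidyr::expand_grid(channel = c("C3", "C4"), freq = 8:25))
  rel2$rel_power <- ifelse(rel2$freq == 13, -99, 1)
  expect_equal(band_mean(rel2, c(13, 13))$value, c(-99, -99))
  expect_equal(length(analysis_freqs()), 18)
  expect_error(band_mean(rel, c(5, 25)), "grid")
})
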