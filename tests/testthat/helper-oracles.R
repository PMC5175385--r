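# Independent oracles, deliberately written as plainly as possible and kept
# separate from the implementation paths they check.

# naive O(N^2) Hanning-taper DFT power at integer-multiple bins
oracle_hann_power <- function(x, freqs, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  xt <- x * w
  sapply(freqs, function(f) {
    k <- f * n / fs
    re <- sum(xt * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(xt * sin(-2 * pi * k * (0:(n - 1)) / n))
    2 * (re^2 + im^2) / (fs * sum(w^2))
  })
}

# direct high-precision entropy of a magnitude-normalized spectrum
oracle_entropy <- function(x) {
  p <- abs(x) / sum(abs(x))
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log(pi)
  s / log(length(p))
}

# brute-force Benjamini-Hochberg step-up adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(sapply(i:m, function(j) p[o[j]] * m / j))
  }
  adj <- numeric(m)
  adj[o] <- pmin(adj_sorted, 1)
  adj
}

# exhaustive two-sided exact Wilcoxon p via full enumeration of group labels
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  idx <- utils::combn(length(pooled), nx)
  sums <- apply(idx, 2, function(i) sum(r[i]))
  lo <- mean(sums <= w_obs + 1e-8)
  hi <- mean(sums >= w_obs - 1e-8)
  min(1, 2 * min(lo, hi))
}

# small balanced metric table with known group difference, for stats tests
make_metric_table <- function(n_per_group = 6, tasks = c("a", "b"),
                              channels = c("C3", "C4"), delta = 0,
                              sd_participant = 0.1, sd_e = 0.05, seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("elderly_%02d", seq_len(n_per_group)),
           sprintf("young_%02d", seq_len(n_per_group)))
  groups <- rep(c("elderly", "young"), each = n_per_group)
  u <- rnorm(length(ids), 0, sd_participant)
  rows <- list()
  for (i in seq_along(ids)) {
    for (task in tasks) {
      for (ch in channels) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          participant_id = ids[i], group = groups[i], task = task,
          channel = ch, metric = "entropy",
          value = (groups[i] == "elderly") * delta + u[i] + rnorm(1, 0, sd_e)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
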