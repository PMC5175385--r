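#' Unpaired two-sample t-test
#'
#' Student's pooled-variance two-sample t-test (the default used for
#' relative power, which is approximately normal); Welch's unequal-variance
#' variant is available behind a flag. Two-sided.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param welch use Welch's unequal-variance statistic instead of the pooled
#'   Student statistic.
#' @return one-row tibble: `method`, `statistic` (t, sign of `mean(x) -
#'   mean(y)`), `df`, `p_value`, `estimate` (mean difference), `n_x`, `n_y`.
#' @export
students_t_unpaired <- function(x, y, welch = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    abort("both samples need at least 2 observations")
  }
  if (!welch && var(x) + var(y) == 0) {
    abort("pooled variance is zero; the t statistic is undefined")
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  tibble::tibble(
    method = if (welch) "welch_t" else "student_t",
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    estimate = unname(ht$estimate[1] - ht$estimate[2]),
    n_x = length(x), n_y = length(y)
  )
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test, the default for spectral
#' entropy (bounded, non-normal). Ties receive midranks. For small samples
#' (`n_x + n_y <= max_exact`) the two-sided p-value is exact, computed by
#' exhaustive enumeration of all group assignments of the pooled midranks
#' (`p = min(1, 2 * min(P(W <= w), P(W >= w)))`); larger samples use the
#' normal approximation with the tie-corrected variance and a 0.5 continuity
#' correction.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param max_exact largest pooled size for which the exact path is used.
#' @return one-row tibble: `method`, `statistic` (rank sum `W` of `x`),
#'   `p_value`, `exact`, `n_x`, `n_y`.
#' @export
wilcoxon_rank_sum <- function(x, y, max_exact = 12) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx < 2 || ny < 2) abort("both samples need at least 2 observations")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (n <= max_exact) {
    sums <- combn(r, nx, FUN = sum)
    eps <- 1e-8
    p <- min(1, 2 * min(mean(sums <= w + eps), mean(sums >= w - eps)))
    exact <- TRUE
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  tibble::tibble(method = "wilcoxon", statistic = w, p_value = p,
                 exact = exact, n_x = nx, n_y = ny)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR control across a family of tests (channels or frequency
#' bins): the i-th smallest p-value is adjusted to
#' `min_{j >= i} p_(j) * m / j`, capped at 1, and a test is flagged
#' significant when its adjusted p-value is below `alpha`.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param alpha significance level for the rejection mask.
#' @return tibble with columns `p_value`, `p_adjusted`, `significant`, in the
#'   input order.
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p_value = p, p_adjusted = adj, significant = adj < alpha)
}

#' Channel-wise two-group test with FDR correction
#'
#' For one metric and task, tests elderly vs young participant-level values
#' separately at every channel with the chosen test, then adjusts the
#' resulting per-channel p-values for multiple comparisons across channels
#' with [fdr_bh()]. Statistic signs follow `elderly - young`.
#'
#' @param table a metric table (see [metric_table()]) with columns
#'   `participant_id`, `group`, `task`, `channel`, `metric`, `value`.
#' @param metric metric name to test (`"relative_power"` or `"entropy"`).
#' @param task task name to test.
#' @param test `"student_t"` or `"wilcoxon"`.
#' @param alpha FDR significance level.
#' @return a `channel_stat_map` tibble: `channel`, `statistic`, `p_value`,
#'   `p_adjusted`, `significant`, `mean_elderly`, `mean_young`; attributes
#'   `metric`, `task`, `test`, `alpha`.
#' @export
channelwise_group_test <- function(table, metric, task,
                                   test = c("student_t", "wilcoxon"),
                                   alpha = 0.05) {
  test <- match.arg(test)
  sel <- dplyr::filter(table, .data$metric == .env$metric,
                       .data$task == .env$task)
  if (!nrow(sel)) {
    abort(sprintf("no rows for metric '%s', task '%s'", metric, task))
  }
  if (!all(c("elderly", "young") %in% sel$group)) {
    abort("both groups must be present for a group contrast")
  }
  res <- dplyr::group_modify(
    dplyr::group_by(sel, .data$channel),
    function(d, key) {
      x <- d$value[d$group == "elderly"]
      y <- d$value[d$group == "young"]
      r <- if (test == "student_t") students_t_unpaired(x, y) else
        wilcoxon_rank_sum(x, y)
      tibble::tibble(statistic = r$statistic, p_value = r$p_value,
                     mean_elderly = mean(x), mean_young = mean(y))
    }
  )
  res <- dplyr::ungroup(res)
  adj <- fdr_bh(res$p_value, alpha = alpha)
  res$p_adjusted <- adj$p_adjusted
  res$significant <- adj$significant
  res <- res[, c("channel", "statistic", "p_value", "p_adjusted",
                 "significant", "mean_elderly", "mean_young")]
  attr(res, "metric") <- metric
  attr(res, "task") <- task
  attr(res, "test") <- test
  attr(res, "alpha") <- alpha
  add_class(res, "channel_stat_map")
}

#' Per-bin group test over a region of interest
#'
#' Averages the participant-level relative-power spectrum over the region-of-
#' interest channels (default: left sensorimotor FC3/C3/CP3), then tests
#' elderly vs young per frequency bin with Student's t-test and adjusts the
#' per-bin p-values across the (18 by default) bins with [fdr_bh()].
#'
#' @param spectra participant-level spectra with columns `participant_id`,
#'   `group`, `task`, `channel`, `freq`, `rel_power` (see
#'   [participant_spectra()]).
#' @param roi character vector of ROI channel labels; must all be present.
#' @param task task to test; `NULL` uses all rows (e.g. a single-task table).
#' @param alpha FDR significance level.
#' @return a `bin_stat_map` tibble: `freq`, `statistic`, `p_value`,
#'   `p_adjusted`, `significant`, `mean_elderly`, `mean_young`.
#' @export
binwise_roi_test <- function(spectra, roi = c("FC3", "C3", "CP3"),
                             task = NULL, alpha = 0.05) {
  have <- unique(spectra$channel)
  if (!all(roi %in% have)) {
    abort(sprintf("ROI channels not in the data: %s",
                  paste(setdiff(roi, have), collapse = ", ")))
  }
  sel <- spectra
  if (!is.null(task)) sel <- dplyr::filter(sel, .data$task == .env$task)
  if (!nrow(sel)) abort("no rows for the requested task")
  roi_mean <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(sel, .data$channel %in% roi),
                    .data$participant_id, .data$group, .data$freq),
    value = mean(.data$rel_power), .groups = "drop"
  )
  res <- dplyr::group_modify(
    dplyr::group_by(roi_mean, .data$freq),
    function(d, key) {
      x <- d$value[d$group == "elderly"]
      y <- d$value[d$group == "young"]
      r <- students_t_unpaired(x, y)
      tibble::tibble(statistic = r$statistic, p_value = r$p_value,
                     mean_elderly = mean(x), mean_young = mean(y))
    }
  )
  res <- dplyr::ungroup(res)
  adj <- fdr_bh(res$p_value, alpha = alpha)
  res$p_adjusted <- adj$p_adjusted
  res$significant <- adj$significant
  attr(res, "roi") <- roi
  attr(res, "alpha") <- alpha
  add_class(res, "bin_stat_map")
}
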