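# direct simulation from the random-intercept model, used for recovery and
# calibration checks
simulate_lmm_data <- function(n_per_group = 20, beta_group = 0,
                              sd_participant = 0.05, sd_e = 0.02,
                              tasks = c("t1", "t2"), beta_task = 0.01) {
  ids <- c(sprintf("e%02d", seq_len(n_per_group)),
           sprintf("y%02d", seq_len(n_per_group)))
  groups <- rep(c("elderly", "young"), each = n_per_group)
  u <- rnorm(length(ids), 0, sd_participant)
  df <- tidyr::expand_grid(participant_id = ids, task = tasks)
  df$group <- groups[match(df$participant_id, ids)]
  task_eff <- if (length(tasks) > 1) (df$task == tasks[2]) * beta_task else 0
  df$value <- 0.5 + (df$group == "young") * beta_group + task_eff +
    u[match(df$participant_id, ids)] + rnorm(nrow(df), 0, sd_e)
  df
}

test_that("with one task and no participant variance the model collapses to a two-group comparison", {
  set.seed(1)
  df <- simulate_lmm_data(n_per_group = 10, beta_group = 0.2,
                          sd_participant = 0, sd_e = 0.05, tasks = "t1",
                          beta_task = 0)
  f <- fit_random_intercept_model(df)
  gm <- tapply(df$value, df$group, mean)
  est <- f$fixed$estimate[f$fixed$term == "groupyoung"]
  expect_equal(est, unname(gm["young"] - gm["elderly"]), tolerance = 1e-6)
})

test_that("fixed-effect group estimates are recovered across replicates", {
  set.seed(2)
  # sampling SE of the group contrast from the closed form:
  # var = 2 (sd_p^2 + sd_e^2 / n_tasks) / n_per_group
  se <- sqrt(2 * (0.05^2 + 0.02^2 / 2) / 20)
  est <- replicate(100, {
    df <- simulate_lmm_data(n_per_group = 20, beta_group = 0.10,
                            sd_participant = 0.05, sd_e = 0.02)
    f <- fit_random_intercept_model(df)
    f$fixed$estimate[f$fixed$term == "groupyoung"]
  })
  expect_lt(abs(mean(est) - 0.10), 3 * se / sqrt(100))   # unbiased
  expect_gte(mean(abs(est - 0.10) <= 2 * se), 0.90)      # ~95% nominal
  expect_lt(sd(est), 1.5 * se)                           # no excess variance
})

test_that("variance components are reported, singular fits flagged not hidden", {
  set.seed(3)
  df <- simulate_lmm_data(sd_participant = 0.1, sd_e = 0.02)
  f <- fit_random_intercept_model(df)
  expect_gte(f$varcomp[["participant"]], 0)
  expect_gt(f$varcomp[["residual"]], 0)
  expect_equal(sqrt(f$varcomp[["participant"]]), 0.1, tolerance = 0.5)
  g <- glance(f)
  expect_true(all(c("sigma_participant", "p_group", "singular") %in% names(g)))
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std_error") %in% names(td)))
  expect_error(fit_random_intercept_model(df[df$group == "young", ]),
               "both groups")
})

test_that("balanced-design estimated marginal means equal raw cell means", {
  set.seed(4)
  df <- simulate_lmm_data(n_per_group = 8, beta_group = 0.1, beta_task = 0.05)
  f <- fit_random_intercept_model(df, include_interaction = TRUE)
  raw <- dplyr::summarise(dplyr::group_by(df, group, task),
                          m = mean(value), .groups = "drop")
  emm <- dplyr::arrange(f$emmeans, group, task)
  raw <- dplyr::arrange(raw, group, task)
  expect_equal(emm$emmean, raw$m, tolerance = 1e-6)
})

test_that("group effect map corrects one mixed-model p per channel", {
  tbl <- dplyr::bind_rows(
    make_metric_table(n_per_group = 8, delta = 0.3,
                      channels = paste0("ch", 1:6), seed = 5),
    make_metric_table(n_per_group = 8, delta = 0,
                      channels = paste0("nul", 1:2), seed = 6)
  )
  res <- group_effect_map(tbl, "entropy")
  expect_equal(nrow(res), 8)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_identical(res$significant, res$p_adjusted < 0.05)
  expect_true(all(res$significant[grepl("^ch", res$channel)]))
  # estimated marginal means reflect the injected elderly excess
  expect_true(all(res$emmean_elderly[grepl("^ch", res$channel)] >
                    res$emmean_young[grepl("^ch", res$channel)]))
  expect_error(group_effect_map(tbl, "nope"), "no rows")
})

test_that("post-hoc task contrasts detect a task effect only where present", {
  set.seed(7)
  # one channel with a genuine task difference in young only
  ids <- c(sprintf("e%02d", 1:12), sprintf("y%02d", 1:12))
  groups <- rep(c("elderly", "young"), each = 12)
  u <- rnorm(24, 0, 0.02)
  tbl <- tidyr::expand_grid(participant_id = ids, task = c("t1", "t2"),
                            channel = c("C3", "Oz"))
  tbl$group <- groups[match(tbl$participant_id, ids)]
  tbl$metric <- "relative_power"
  tbl$value <- u[match(tbl$participant_id, ids)] + rnorm(nrow(tbl), 0, 0.02) +
    ifelse(tbl$group == "young" & tbl$task == "t2" & tbl$channel == "C3",
           0.4, 0)
  res <- posthoc_task_contrasts(tbl, "relative_power")
  expect_true(all(c("channel", "group", "contrast", "estimate", "p_adjusted")
                  %in% names(res)))
  expect_equal(nrow(res), 4)   # 2 channels x 2 groups x 1 contrast
  young_c3 <- dplyr::filter(res, group == "young", channel == "C3")
  expect_true(young_c3$significant)
  expect_equal(young_c3$estimate, -0.4, tolerance = 0.05)
  eld <- dplyr::filter(res, group == "elderly")
  expect_false(any(eld$significant))
  expect_error(
    posthoc_task_contrasts(dplyr::filter(tbl, task == "t1"), "relative_power"),
    "at least 2 tasks"
  )
})

test_that("null task contrasts stay non-significant almost always", {
  set.seed(8)
  sig <- replicate(40, {
    tbl <- make_metric_table(n_per_group = 8, delta = 0, channels = "C3",
                             seed = sample.int(1e6, 1))
    tbl$metric <- "relative_power"
    any(posthoc_task_contrasts(tbl, "relative_power")$significant)
  })
  expect_lte(mean(sig), 0.05 + 0.05)
})
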