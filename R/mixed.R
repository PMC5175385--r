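#' Random-intercept linear mixed model for one channel
#'
#' Fits `value ~ group + task + (1 | participant_id)` (the task term is
#' dropped automatically for single-task data, and `group * task` is used
#' when `include_interaction = TRUE`) by REML with [lme4::lmer()]. The
#' participant random intercept absorbs repeated testing of the same
#' participants across tasks. The p-value for the group effect comes from a
#' likelihood-ratio test of maximum-likelihood refits with and without the
#' group main effect (always from the additive model: a main-effect LRT in
#' the presence of an interaction is not well defined). Estimated marginal
#' (least-square) means per group (x task) are computed with
#' \pkg{emmeans} using the asymptotic (z) reference distribution.
#'
#' Singular fits (a participant variance estimated at zero) are legitimate
#' outcomes and are reported as such, not hidden; genuine optimizer failures
#' raise an error carrying the optimizer diagnostics.
#'
#' @param data tibble with columns `value`, `group`, `task`,
#'   `participant_id` for a single channel and metric.
#' @param include_interaction model the group-by-task interaction (needed for
#'   post-hoc task contrasts).
#' @return an `erd_ri_fit` object: list with `fit` (the REML `lmerMod`),
#'   `fixed` (tibble of fixed effects), `varcomp` (participant and residual
#'   variances), `p_group`, `emmeans` (tibble of estimated marginal means),
#'   `singular`, `formula`.
#' @export
fit_random_intercept_model <- function(data, include_interaction = FALSE) {
  needed <- c("value", "group", "task", "participant_id")
  if (!all(needed %in% names(data))) {
    abort(paste("data must contain columns:", paste(needed, collapse = ", ")))
  }
  data <- dplyr::mutate(data,
                        group = factor(.data$group),
                        task = factor(.data$task),
                        participant_id = factor(.data$participant_id))
  if (nlevels(data$group) < 2) abort("both groups must be present")
  n_per <- table(unique(data[, c("participant_id", "group")])$group)
  if (any(n_per < 2)) abort("need at least 2 participants per group")
  multi_task <- nlevels(data$task) > 1
  rhs <- if (include_interaction && multi_task) "group * task"
         else if (multi_task) "group + task" else "group"
  f_full <- stats::as.formula(paste("value ~", rhs, "+ (1 | participant_id)"))
  ctrl <- lme4::lmerControl(
    check.nobs.vs.nlev = "ignore", check.nobs.vs.rankZ = "ignore",
    check.nobs.vs.nRE = "ignore", check.conv.singular = "ignore",
    calc.derivs = FALSE
  )
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(f_full, data = data, REML = TRUE, control = ctrl),
      error = function(e) {
        abort(paste0("mixed model failed to fit: ", conditionMessage(e)))
      }
    ),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage")
  )
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$code) && conv$code < 0) {
    abort(paste0("mixed model did not converge: ",
                 paste(unlist(conv$messages), collapse = "; ")))
  }

  # group LRT on ML refits of the additive model
  rhs_add <- if (multi_task) "group + task" else "group"
  rhs_red <- if (multi_task) "task" else "1"
  full_ml <- suppressWarnings(suppressMessages(lme4::lmer(
    stats::as.formula(paste("value ~", rhs_add, "+ (1 | participant_id)")),
    data = data, REML = FALSE, control = ctrl
  )))
  red_ml <- suppressWarnings(suppressMessages(lme4::lmer(
    stats::as.formula(paste("value ~", rhs_red, "+ (1 | participant_id)")),
    data = data, REML = FALSE, control = ctrl
  )))
  lr <- 2 * (as.numeric(logLik(full_ml)) - as.numeric(logLik(red_ml)))
  p_group <- pchisq(max(lr, 0), df = 1, lower.tail = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_participant <- vc$vcov[vc$grp == "participant_id"][1]
  var_residual <- vc$vcov[vc$grp == "Residual"][1]
  co <- summary(fit)$coefficients
  fixed <- tibble::tibble(term = rownames(co),
                          estimate = unname(co[, "Estimate"]),
                          std_error = unname(co[, "Std. Error"]),
                          statistic = unname(co[, "t value"]))
  # estimated marginal means directly from the fixed effects and their
  # covariance: with treatment contrasts the reference grid covers every
  # group x task cell, so emmean = X beta and SE = sqrt(diag(X V X'))
  grid <- expand.grid(group = levels(data$group), task = levels(data$task),
                      KEEP.OUT.ATTRS = FALSE)
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), grid)
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  emm <- tibble::tibble(
    group = as.character(grid$group), task = as.character(grid$task),
    emmean = as.vector(X %*% beta),
    se = sqrt(rowSums((X %*% V) * X))
  )
  structure(
    list(fit = fit, fixed = fixed,
         varcomp = c(participant = var_participant, residual = var_residual),
         p_group = p_group, emmeans = emm,
         singular = lme4::isSingular(fit), formula = f_full,
         include_interaction = include_interaction && multi_task,
         n_obs = nrow(data),
         n_participants = nlevels(data$participant_id)),
    class = "erd_ri_fit"
  )
}

#' @export
print.erd_ri_fit <- function(x, ...) {
  cat("<erd_ri_fit> ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  var(participant) = %.4g, var(residual) = %.4g%s\n",
              x$varcomp["participant"], x$varcomp["residual"],
              if (x$singular) " [singular]" else ""))
  cat(sprintf("  group effect LRT p = %.4g\n", x$p_group))
  invisible(x)
}

#' @method tidy erd_ri_fit
#' @export
tidy.erd_ri_fit <- function(x, effects = c("fixed", "emmeans"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$fixed else x$emmeans
}

#' @method glance erd_ri_fit
#' @export
glance.erd_ri_fit <- function(x, ...) {
  tibble::tibble(
    sigma_participant = sqrt(unname(x$varcomp["participant"])),
    sigma_residual = sqrt(unname(x$varcomp["residual"])),
    logLik = as.numeric(logLik(x$fit)),
    p_group = x$p_group,
    singular = x$singular,
    n_obs = x$n_obs,
    n_participants = x$n_participants
  )
}

#' Per-channel mixed-model group-effect map
#'
#' Fits the random-intercept model of [fit_random_intercept_model()] at every
#' channel for one metric (pooling tasks via the task fixed effect), extracts
#' the group-effect likelihood-ratio p-value per channel, and adjusts the
#' resulting family of per-channel p-values with [fdr_bh()].
#'
#' @param table a metric table (see [metric_table()]).
#' @param metric metric to model (`"relative_power"` or `"entropy"`).
#' @param alpha FDR significance level.
#' @return a `channel_stat_map` tibble: `channel`, `estimate` (fixed-effect
#'   group contrast, young minus elderly), `p_value`, `p_adjusted`,
#'   `significant`, `emmean_elderly`, `emmean_young` (marginal means averaged
#'   over tasks); attribute `fits` holds the per-channel `erd_ri_fit`s.
#' @export
group_effect_map <- function(table, metric, alpha = 0.05) {
  sel <- dplyr::filter(table, .data$metric == .env$metric)
  if (!nrow(sel)) abort(sprintf("no rows for metric '%s'", metric))
  channels <- unique(sel$channel)
  fits <- purrr::map(channels, function(ch) {
    fit_random_intercept_model(dplyr::filter(sel, .data$channel == ch))
  })
  names(fits) <- channels
  res <- purrr::map2_dfr(fits, channels, function(f, ch) {
    term <- grep("^group", f$fixed$term, value = TRUE)[1]
    emm_g <- dplyr::summarise(dplyr::group_by(f$emmeans, .data$group),
                              emmean = mean(.data$emmean), .groups = "drop")
    tibble::tibble(
      channel = ch,
      estimate = f$fixed$estimate[f$fixed$term == term],
      p_value = f$p_group,
      emmean_elderly = emm_g$emmean[emm_g$group == "elderly"],
      emmean_young = emm_g$emmean[emm_g$group == "young"]
    )
  })
  adj <- fdr_bh(res$p_value, alpha = alpha)
  res$p_adjusted <- adj$p_adjusted
  res$significant <- adj$significant
  res <- res[, c("channel", "estimate", "p_value", "p_adjusted", "significant",
                 "emmean_elderly", "emmean_young")]
  attr(res, "metric") <- metric
  attr(res, "alpha") <- alpha
  attr(res, "fits") <- fits
  add_class(res, "channel_stat_map")
}

#' Post-hoc pairwise task contrasts from the interaction model
#'
#' Fits the group-by-task interaction model per channel and compares the
#' estimated marginal (least-square) means of all task pairs within each
#' group, with standard errors from the fixed-effect covariance. P-values are
#' FDR-adjusted across channels within each (group, contrast) family.
#'
#' @param table a metric table (see [metric_table()]) covering >= 2 tasks.
#' @param metric metric to model.
#' @param group restrict output to one group (`"elderly"` or `"young"`);
#'   `NULL` keeps both.
#' @param alpha FDR significance level.
#' @return tibble: `channel`, `group`, `contrast`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `p_adjusted`, `significant`.
#' @export
posthoc_task_contrasts <- function(table, metric, group = NULL, alpha = 0.05) {
  sel <- dplyr::filter(table, .data$metric == .env$metric)
  if (!nrow(sel)) abort(sprintf("no rows for metric '%s'", metric))
  if (length(unique(sel$task)) < 2) {
    abort("post-hoc task contrasts need at least 2 tasks")
  }
  channels <- unique(sel$channel)
  res <- purrr::map_dfr(channels, function(ch) {
    f <- fit_random_intercept_model(dplyr::filter(sel, .data$channel == ch),
                                    include_interaction = TRUE)
    emm <- suppressMessages(
      emmeans::emmeans(f$fit, ~ task | group, lmer.df = "asymptotic")
    )
    ct <- tibble::as_tibble(as.data.frame(
      emmeans::contrast(emm, method = "pairwise", adjust = "none")
    ))
    tibble::tibble(
      channel = ch, group = as.character(ct$group),
      contrast = as.character(ct$contrast), estimate = ct$estimate,
      std_error = ct$SE,
      statistic = ct[[grep("ratio$", names(ct), value = TRUE)[1]]],
      p_value = ct$p.value
    )
  })
  if (!is.null(group)) {
    res <- dplyr::filter(res, .data$group == .env$group)
  }
  res <- dplyr::group_by(res, .data$group, .data$contrast)
  res <- dplyr::mutate(res,
                       p_adjusted = fdr_bh(.data$p_value, alpha)$p_adjusted,
                       significant = .data$p_adjusted < alpha)
  dplyr::ungroup(res)
}
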