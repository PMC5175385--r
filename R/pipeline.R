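#' Pipeline configuration
#'
#' Bundles the simulation configuration with the analysis settings: the
#' analysis bands (the broad 8-25 Hz band and the 13-19 Hz band in which
#' group differences of relative power are largest), the per-metric tests and
#' the FDR level. The pipeline default simulation is desk-scale: the 16-channel
#' montage, 10 participants per group, 40 trials per task and 30 baseline
#' segments; the full cohort-sized study is available by passing a
#' [sim_config()] with its own defaults.
#'
#' @param sim a [sim_config()].
#' @param bands named list of length-2 numeric bands (Hz).
#' @param alpha FDR significance level, in (0, 1).
#' @param power_test test for the relative-power metric.
#' @param entropy_test test for the entropy metric.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(montage = "toy16",
                                             n_per_group = 10,
                                             trials_per_task = 40,
                                             n_baseline_segments = 30),
                            bands = list(broadband = c(8, 25),
                                         beta = c(13, 19)),
                            alpha = 0.05,
                            power_test = "student_t",
                            entropy_test = "wilcoxon") {
  stopifnot(inherits(sim, "sim_config"), alpha > 0, alpha < 1,
            length(bands) >= 1)
  grid <- analysis_freqs()
  for (b in bands) {
    if (b[1] < min(grid) || b[2] > max(grid) || b[1] > b[2]) {
      abort(sprintf("band [%g, %g] lies outside the analyzable 8-25 Hz grid",
                    b[1], b[2]))
    }
  }
  structure(list(sim = sim, bands = bands, alpha = alpha,
                 power_test = power_test, entropy_test = entropy_test),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Accepts a file with top-level keys `sim` (fields of [sim_config()]; the
#' `profiles` entry may name presets, e.g. `elderly: elderly`), `bands`,
#' `alpha`, `power_test`, `entropy_test`. Missing keys fall back to defaults.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sim_args <- raw$sim %||% list()
  if (!is.null(sim_args$profiles)) {
    sim_args$profiles <- lapply(sim_args$profiles, function(p) {
      if (is.character(p)) modulation_preset(p) else modulation_profile(p)
    })
  }
  if (!is.null(sim_args$n_per_group)) {
    sim_args$n_per_group <- unlist(sim_args$n_per_group)
  }
  sim <- do.call(sim_config, sim_args)
  bands <- raw$bands %||% list(broadband = c(8, 25), beta = c(13, 19))
  bands <- lapply(bands, as.numeric)
  pipeline_config(
    sim = sim, bands = bands,
    alpha = raw$alpha %||% 0.05,
    power_test = raw$power_test %||% "student_t",
    entropy_test = raw$entropy_test %||% "wilcoxon"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> spectral power -> relative power -> entropy ->
#' statistics and writes every result table as TSV plus a JSON run manifest.
#' Outputs per band: the metric table, channel-wise group tests per task and
#' metric, the mixed-model group-effect map per metric, and (with >= 2
#' tasks) post-hoc task contrasts. The per-bin ROI test is run per task on
#' the full 8-25 Hz grid. Identical configurations produce byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param study optionally, a pre-built `erd_study` to analyze instead of
#'   simulating from `config$sim` (e.g. assembled from imported EDF data).
#' @return (invisibly) a list with `spectra`, per-band `metrics`,
#'   `channel_tests`, `group_effects`, `posthoc`, plus `binwise` and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, study = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(study)) study <- simulate_study(config$sim)
    roi <- montage_roi(study$montage)
    tasks <- config$sim$tasks

    stage <- "power"
    spectra <- participant_spectra(study)

    stage <- "statistics"
    bands_out <- list()
    for (bn in names(config$bands)) {
      band <- config$bands[[bn]]
      metrics <- metric_table(spectra, band)
      tests <- list()
      for (task in tasks) {
        tests[[paste0("relative_power_", task)]] <- channelwise_group_test(
          metrics, "relative_power", task, test = config$power_test,
          alpha = config$alpha
        )
        tests[[paste0("entropy_", task)]] <- channelwise_group_test(
          metrics, "entropy", task, test = config$entropy_test,
          alpha = config$alpha
        )
      }
      ge <- list(
        relative_power = group_effect_map(metrics, "relative_power",
                                          alpha = config$alpha),
        entropy = group_effect_map(metrics, "entropy", alpha = config$alpha)
      )
      ph <- NULL
      if (length(tasks) >= 2) {
        ph <- list(
          relative_power = posthoc_task_contrasts(metrics, "relative_power",
                                                  alpha = config$alpha),
          entropy = posthoc_task_contrasts(metrics, "entropy",
                                           alpha = config$alpha)
        )
      }
      bands_out[[bn]] <- list(band = band, metrics = metrics,
                              channel_tests = tests, group_effects = ge,
                              posthoc = ph)
    }
    binwise <- lapply(setNames(tasks, tasks), function(task) {
      binwise_roi_test(spectra, roi = roi, task = task, alpha = config$alpha)
    })
    list(study = study, spectra = spectra, bands = bands_out,
         binwise = binwise)
  }, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  })

  manifest <- list(
    package_version = as.character(packageVersion("erdentropy")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$sim$seed,
    config = config_summary(config),
    config_hash = config_hash(config),
    bands = config$bands,
    alpha = config$alpha
  )
  result$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, name) {
      readr::write_tsv(strip_for_tsv(x), file.path(out_dir, name))
    }
    wt(result$spectra, "spectra_participant.tsv")
    for (bn in names(result$bands)) {
      b <- result$bands[[bn]]
      tag <- sprintf("%s_%g_%g", bn, b$band[1], b$band[2])
      wt(b$metrics, paste0("metrics_", tag, ".tsv"))
      for (tn in names(b$channel_tests)) {
        wt(b$channel_tests[[tn]], paste0("channel_test_", tn, "_", tag, ".tsv"))
      }
      wt(b$group_effects$relative_power,
         paste0("group_effect_relative_power_", tag, ".tsv"))
      wt(b$group_effects$entropy, paste0("group_effect_entropy_", tag, ".tsv"))
      if (!is.null(b$posthoc)) {
        wt(b$posthoc$relative_power,
           paste0("posthoc_relative_power_", tag, ".tsv"))
        wt(b$posthoc$entropy, paste0("posthoc_entropy_", tag, ".tsv"))
      }
    }
    for (task in names(result$binwise)) {
      wt(result$binwise[[task]], paste0("binwise_roi_", task, ".tsv"))
    }
    manifest$files <- sort(list.files(out_dir, pattern = "\\.tsv$"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$manifest <- manifest
  }
  invisible(result)
}

strip_for_tsv <- function(x) {
  x <- tibble::as_tibble(x)
  attributes(x)[setdiff(names(attributes(x)),
                        c("names", "row.names", "class"))] <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

config_summary <- function(config) {
  s <- config$sim
  list(
    n_per_group = as.list(s$n_per_group), tasks = s$tasks,
    trials_per_task = s$trials_per_task, fs = s$fs,
    epoch_len_s = s$epoch_len_s, baseline_len_s = s$baseline_len_s,
    n_baseline_segments = s$n_baseline_segments,
    noise_exponent = s$noise_exponent, noise_scale = s$noise_scale,
    between_subject_sd = s$between_subject_sd,
    montage = attr(s$montage, "preset") %||% "custom",
    n_channels = nrow(s$montage), car = s$car, seed = s$seed,
    profiles = lapply(s$profiles, function(p) {
      list(name = attr(p, "profile_name"),
           components = strip_for_tsv(
             dplyr::mutate(
               p,
               channels = vapply(.data$channels, paste, "", collapse = ","),
               task_scale = vapply(.data$task_scale, function(ts) {
                 if (is.null(ts)) "" else
                   paste(names(ts), ts, sep = "=", collapse = ",")
               }, "")
             )
           ))
    })
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_summary(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}
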