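# One-command orchestration: simulate or ingest a dataset, run exclusions,
# signal detection, metacognition, the slope classifier (with permutation
# null and optional robustness grid), the mixed-model ladders and clinical
# correlations, and bundle the results with a reproducibility manifest.

#' Group statistics the synthetic generator is calibrated to
#'
#' The benchmark group-level statistics used as calibration targets for
#' [default_generative_params()] and as the reference column of the
#' pipeline summary: mean sensitivity, bias and metacognitive gamma per
#' group, the expected classifier accuracy band and the permutation-null
#' chance level.
#'
#' @return named list of reference values and tolerance bands.
#' @export
calibration_targets <- function() {
  list(
    d_prime = c(control = 1.8, psychosis = 0.76), d_prime_tol = 0.15,
    criterion_c = c(control = -0.43, psychosis = -0.73), criterion_tol = 0.15,
    gamma = c(control = 0.26, psychosis = 0.00), gamma_tol = 0.08,
    classifier_accuracy_band = c(0.80, 0.95),
    null_accuracy = 0.50, null_tol = 0.03
  )
}

#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"ingest"`
#'   (read `trials_path` / `participants_path` CSVs).
#' @param seed master seed; per-stage seeds are derived from it
#'   deterministically.
#' @param params [gen_params()] for simulate mode.
#' @param trials_path,participants_path input CSVs for ingest mode.
#' @param exclude_participants participant ids dropped before analysis.
#' @param classifier list of classifier settings: `leave_out_fraction`,
#'   `n_iterations` (2000 default at simulation scale; the study procedure
#'   used 10000), `n_trials_sampled`, `trial_pool`.
#' @param run_null,run_grid,run_models,run_correlations stage toggles.
#' @param out_dir optional directory for per-stage artifacts (CSV/JSON) and
#'   the run manifest.
#' @return list of class `soa_pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"), seed = 1,
                            params = NULL, trials_path = NULL,
                            participants_path = NULL,
                            exclude_participants = character(0),
                            classifier = list(), run_null = TRUE,
                            run_grid = FALSE, run_models = TRUE,
                            run_correlations = TRUE, out_dir = NULL) {
  mode <- match.arg(mode)
  cls <- utils::modifyList(
    list(leave_out_fraction = 0.2, n_iterations = 2000L,
         n_trials_sampled = "all", trial_pool = "whole_experiment"),
    classifier)
  structure(list(mode = mode, seed = seed, params = params,
                 trials_path = trials_path,
                 participants_path = participants_path,
                 exclude_participants = exclude_participants,
                 classifier = cls, run_null = run_null, run_grid = run_grid,
                 run_models = run_models, run_correlations = run_correlations,
                 out_dir = out_dir),
            class = "soa_pipeline_config")
}

read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$params)) cfg$params <- gen_params(cfg$params$control,
                                                     cfg$params$psychosis)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes every enabled stage on a simulated or ingested dataset:
#' exclusions, per-participant signal detection with Welch group tests,
#' Goodman-Kruskal gamma metacognition with group tests, the leave-p-out
#' slope classifier with permutation null and Kolmogorov-Smirnov comparison
#' (optionally the robustness grid), the BIC model ladders, and clinical
#' correlations. The summary juxtaposes the obtained group statistics with
#' the calibration targets ([calibration_targets()]) and flags each check.
#' Identical configuration and seed produce identical results; artifacts
#' are written under `config$out_dir` when set.
#'
#' @param config a [pipeline_config()] or a path to a YAML/JSON config file.
#' @return object of class `soa_pipeline`: stage results plus `summary` and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "soa_pipeline_config"))
  seeds <- derive_seeds(config$seed, 6L)
  stage <- "study_data"
  res <- list(config = config)
  out <- tryCatch({
    if (config$mode == "simulate") {
      params <- if (is.null(config$params)) default_generative_params()
                else config$params
      data_raw <- build_cohort(params, seed = seeds[1])
    } else {
      if (is.null(config$trials_path)) stop("ingest mode needs trials_path",
                                            call. = FALSE)
      data_raw <- read_trials(config$trials_path, config$participants_path)
    }
    stage <<- "preprocess"
    excl <- apply_exclusions(data_raw, config$exclude_participants)
    data <- excl$data
    res$exclusions <- excl$report

    stage <<- "sdt_analysis"
    res$sdt <- sdt_summary(data, by_aspect = TRUE)
    pooled <- res$sdt[res$sdt$aspect == "pooled", ]
    res$sdt_tests <- list(
      d_prime = group_compare(pooled$d_prime[pooled$group == "control"],
                              pooled$d_prime[pooled$group == "psychosis"]),
      criterion_c = group_compare(pooled$criterion_c[pooled$group == "control"],
                                  pooled$criterion_c[pooled$group == "psychosis"]))

    stage <<- "metacog_analysis"
    res$gamma <- suppressWarnings(gamma_summary(data, by_aspect = TRUE))
    res$gamma_tests <- gamma_group_tests(res$gamma)

    stage <<- "slope_classifier"
    cl <- config$classifier
    res$classifier <- run_classifier(
      data, leave_out_fraction = cl$leave_out_fraction,
      n_iterations = cl$n_iterations, n_trials_sampled = cl$n_trials_sampled,
      trial_pool = cl$trial_pool, seed = seeds[2])
    if (config$run_null) {
      res$null <- permutation_null(
        data, leave_out_fraction = cl$leave_out_fraction,
        n_iterations = cl$n_iterations, n_trials_sampled = cl$n_trials_sampled,
        trial_pool = cl$trial_pool, seed = seeds[3])
      res$ks <- ks_two_sample(res$classifier$accuracy, res$null$accuracy)
    }
    if (config$run_grid) {
      res$grid <- classifier_grid(data, n_iterations = cl$n_iterations,
                                  trial_pool = cl$trial_pool, seed = seeds[4])
    }

    if (config$run_models) {
      stage <<- "inferential_models"
      res$soa_models <- fit_soa_ladder(data)
      res$confidence_models <- fit_confidence_ladder(data)
    }
    if (config$run_correlations) {
      stage <<- "clinical_correlations"
      res$correlations <- clinical_correlations(data)
    }
    res$data <- data
    res
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  out$summary <- pipeline_summary(out)
  out$manifest <- list(package_version = as.character(utils::packageVersion("soameta")),
                       master_seed = config$seed,
                       stage_seeds = as.list(stats::setNames(
                         seeds, c("data", "classifier", "null", "grid",
                                  "models", "reserved"))),
                       mode = config$mode)
  class(out) <- "soa_pipeline"
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config$out_dir)
  out
}

group_means <- function(df, col) {
  vapply(split(df[[col]], df$group)[GROUPS], mean, numeric(1), na.rm = TRUE)
}

pipeline_summary <- function(res) {
  tg <- calibration_targets()
  pooled_sdt <- res$sdt[res$sdt$aspect == "pooled", ]
  pooled_gam <- res$gamma[res$gamma$aspect == "pooled", ]
  dp <- group_means(pooled_sdt, "d_prime")
  cc <- group_means(pooled_sdt, "criterion_c")
  gm <- group_means(pooled_gam, "gamma")
  acc <- res$classifier$summary
  acc <- acc$mean[acc$metric == "accuracy"]
  checks <- list(
    d_prime = all(abs(dp - tg$d_prime) <= tg$d_prime_tol),
    gamma = all(abs(gm - tg$gamma) <= tg$gamma_tol),
    classifier_accuracy = acc >= tg$classifier_accuracy_band[1] &&
      acc <= tg$classifier_accuracy_band[2])
  null_acc <- NA_real_
  if (!is.null(res$null)) {
    null_acc <- mean(res$null$accuracy)
    checks$permutation_null <- abs(null_acc - tg$null_accuracy) <= tg$null_tol
  }
  list(
    group_means = list(d_prime = dp, criterion_c = cc, gamma = gm),
    reference = list(d_prime = tg$d_prime, criterion_c = tg$criterion_c,
                     gamma = tg$gamma),
    classifier_accuracy = acc,
    null_accuracy = null_acc,
    ks_D = if (!is.null(res$ks)) res$ks$D else NA_real_,
    checks = checks,
    all_checks_pass = all(unlist(checks))
  )
}

#' @export
print.soa_pipeline <- function(x, ...) {
  s <- x$summary
  cat("Sense-of-agency analysis pipeline\n")
  cat(sprintf("  d'        control %.2f / psychosis %.2f   (reference %.2f / %.2f)\n",
              s$group_means$d_prime[1], s$group_means$d_prime[2],
              s$reference$d_prime[1], s$reference$d_prime[2]))
  cat(sprintf("  criterion control %.2f / psychosis %.2f  (reference %.2f / %.2f)\n",
              s$group_means$criterion_c[1], s$group_means$criterion_c[2],
              s$reference$criterion_c[1], s$reference$criterion_c[2]))
  cat(sprintf("  gamma     control %.2f / psychosis %.2f    (reference %.2f / %.2f)\n",
              s$group_means$gamma[1], s$group_means$gamma[2],
              s$reference$gamma[1], s$reference$gamma[2]))
  cat(sprintf("  classifier accuracy %.1f%%", 100 * s$classifier_accuracy))
  if (!is.na(s$null_accuracy)) {
    cat(sprintf(", permutation null %.1f%%, KS D = %.2f",
                100 * s$null_accuracy, s$ks_D))
  }
  cat("\n  calibration checks:",
      paste(sprintf("%s=%s", names(s$checks),
                    ifelse(unlist(s$checks), "PASS", "FAIL")), collapse = " "),
      "\n")
  invisible(x)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_trials(res$data, p("trials.csv"), participants = p("participants.csv"))
  utils::write.csv(res$sdt, p("sdt.csv"), row.names = FALSE)
  utils::write.csv(res$gamma, p("gamma.csv"), row.names = FALSE)
  utils::write.csv(res$classifier$per_participant,
                   p("classifier_participants.csv"), row.names = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(res$classifier$accuracy),
                              accuracy = res$classifier$accuracy,
                              sensitivity = res$classifier$sensitivity,
                              specificity = res$classifier$specificity),
                   p("classifier_iterations.csv"), row.names = FALSE)
  if (!is.null(res$grid)) {
    utils::write.csv(as.data.frame(res$grid), p("classifier_grid.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$correlations)) {
    utils::write.csv(as.data.frame(res$correlations), p("correlations.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$soa_models)) {
    utils::write.csv(res$soa_models$table, p("soa_models.csv"), row.names = FALSE)
    utils::write.csv(res$soa_models$coefficients, p("soa_coefficients.csv"),
                     row.names = FALSE)
    utils::write.csv(res$confidence_models$table, p("confidence_models.csv"),
                     row.names = FALSE)
    utils::write.csv(res$confidence_models$coefficients,
                     p("confidence_coefficients.csv"), row.names = FALSE)
  }
  jsonlite::write_json(list(exclusions = unclass(res$exclusions)),
                       p("exclusions.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
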