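#' Configure an end-to-end study run
#'
#' Defaults reproduce the full-scale protocol (published cohort size, 1000
#' bootstrap replicates for validation and imputation, Youden-J threshold,
#' analysis-mode SMSE). `profile = "test"` is the documented reduced
#' profile: non-case class shrunk to ~49.5k admissions with case counts
#' preserved, 200 bootstrap replicates.
#'
#' @param profile `"full"` or `"test"`.
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @param out_dir output directory (NULL = no files written).
#' @param n_boot_validation,n_boot_imputation bootstrap replicate counts.
#' @param alpha forward-selection retention threshold.
#' @param threshold_criterion `"youden_j"` or `"closest_to_corner"`.
#' @param smse_mode `"analysis"` or `"literal"`.
#' @param spec optional [cohort_spec()] overriding the profile's.
#' @param candidates candidate ranking, as [default_candidates()].
#' @param write_cohort write the generated cohort CSV (default TRUE when
#'   `out_dir` is set).
#' @return object of class `run_config`.
#' @export
run_config <- function(profile = c("full", "test"), seed = 1L,
                       out_dir = NULL,
                       n_boot_validation = NULL, n_boot_imputation = NULL,
                       alpha = 0.05,
                       threshold_criterion = c("youden_j", "closest_to_corner"),
                       smse_mode = c("analysis", "literal"),
                       spec = NULL, candidates = default_candidates(),
                       write_cohort = !is.null(out_dir)) {
  profile <- match.arg(profile)
  nb <- if (profile == "full") 1000L else 200L
  structure(list(
    profile = profile,
    seed = as.integer(seed),
    out_dir = out_dir,
    spec = spec %||%
      (if (profile == "full") cohort_spec() else test_profile_spec()),
    candidates = candidates,
    alpha = alpha,
    n_boot_validation = as.integer(n_boot_validation %||% nb),
    n_boot_imputation = as.integer(n_boot_imputation %||% nb),
    threshold_criterion = match.arg(threshold_criterion),
    smse_mode = match.arg(smse_mode),
    write_cohort = write_cohort,
    planning_n = 429000L,
    planning_events = 250L
  ), class = "run_config")
}

#' Load / save a run configuration as JSON
#'
#' The JSON form carries the profile name, seeds, bootstrap counts and
#' scalar options (not the full generative spec, which is reconstructed
#' from the profile plus any class-size overrides).
#' @param config a `run_config`; @param path file path.
#' @export
save_run_config <- function(config, path) {
  obj <- config[c("profile", "seed", "alpha", "n_boot_validation",
                  "n_boot_imputation", "threshold_criterion", "smse_mode")]
  obj$counts <- as.list(config$spec$counts)
  obj$scale_factor <- config$spec$scale_factor
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_run_config
#' @param out_dir optional output directory override.
#' @export
load_run_config <- function(path, out_dir = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- cohort_spec(
    n_incontinent = obj$counts$incontinent %||% 278L,
    n_continent = obj$counts$continent %||% 222L,
    n_none = obj$counts$none %||% 428197L,
    scale_factor = obj$scale_factor %||% 1
  )
  run_config(profile = obj$profile %||% "full", seed = obj$seed %||% 1L,
             out_dir = out_dir, spec = spec,
             n_boot_validation = obj$n_boot_validation,
             n_boot_imputation = obj$n_boot_imputation,
             alpha = obj$alpha %||% 0.05,
             threshold_criterion = obj$threshold_criterion %||% "youden_j",
             smse_mode = obj$smse_mode %||% "analysis")
}

#' Run the full misclassification-bias study
#'
#' simulate -> code accuracy -> fit -> validate -> threshold/assign ->
#' statistics under each assignment method -> SMSE -> method comparison.
#' Identical config and seed give identical numeric outputs. When
#' `config$out_dir` is set the bundle is also written to files (cohort and
#' tidy tables as CSV, model and reports as JSON, log as text).
#'
#' @param config a [run_config()].
#' @return report bundle (list), invisibly when written to disk.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- new_log()
  t0 <- Sys.time()
  stage <- function(name) run_log(sprintf("[%s] %s (%.1fs)", name,
    format(Sys.time(), "%H:%M:%S"), as.numeric(Sys.time() - t0, "secs")),
    log = log)
  fail <- function(name, e) stop("stage '", name, "' failed: ",
                                 conditionMessage(e), call. = FALSE)

  stage("simulate")
  cohort <- tryCatch(
    generate_cohort(config$spec, seed = derive_seed(config$seed, "cohort"),
                    log = log),
    error = function(e) fail("simulate", e))
  truth <- list(incontinent = cohort$true_status == "incontinent",
                continent = cohort$true_status == "continent")

  stage("accuracy")
  acc <- list()
  for (d in names(truth)) {
    acc[[paste0("code_", d)]] <-
      compute_accuracy(contingency_from_assignment(truth[[d]],
                                                   assign_by_code(cohort, d)))
  }

  stage("fit")
  # Planning-stage budget: the df allowance is a protocol design quantity,
  # fixed by the anticipated full-scale cohort (429,000 admissions, 250
  # events per diversion type), not recomputed on a scaled test cohort.
  budget <- compute_df_budget(n = config$planning_n,
                              events = config$planning_events)
  model <- tryCatch(
    forward_select(cohort, config$candidates, alpha = config$alpha,
                   budget = budget, log = log),
    error = function(e) fail("fit", e))

  stage("validate")
  validation <- tryCatch(
    internal_validate(model, cohort, n_boot = config$n_boot_validation,
                      seed = derive_seed(config$seed, "validate"), log = log),
    error = function(e) fail("validate", e))

  stage("assign")
  p_hat <- predict_probabilities(model, cohort)
  thresholds <- list(); assign_cat <- list()
  for (d in names(truth)) {
    rule <- find_threshold(p_hat[, paste0("p_", d)], truth[[d]],
                           criterion = config$threshold_criterion)
    thresholds[[d]] <- rule
    assign_cat[[d]] <- assign_by_threshold(p_hat[, paste0("p_", d)], rule)
    acc[[paste0("categorical_", d)]] <-
      compute_accuracy(contingency_from_assignment(truth[[d]], assign_cat[[d]]))
    run_log("threshold[", d, "]: tau=", signif(rule$tau, 4),
            " sens=", signif(rule$sensitivity, 4),
            " spec=", signif(rule$specificity, 4), log = log)
  }

  stage("bias")
  battery <- statistic_battery()
  bi <- bootstrap_impute(cohort, p_hat, battery,
                         n_boot = config$n_boot_imputation,
                         seed = derive_seed(config$seed, "impute"), log = log)
  stats_true <- list(); smse_tabs <- list(); comparisons <- list()
  for (d in names(truth)) {
    stats_true[[d]] <- compute_statistics(cohort, truth[[d]], battery)
    ests <- list(
      code = compute_statistics(cohort, assign_by_code(cohort, d), battery),
      categorical = compute_statistics(cohort, assign_cat[[d]], battery),
      bi = bi[bi$diversion == d, ]
    )
    smse_tabs[[d]] <- smse_table(ests, stats_true[[d]],
                                 mode = config$smse_mode)
    # a degenerate world (e.g. perfect codes) can leave < 2 methods with
    # log-usable SMSE; report the medians with no ANOVA instead of failing
    comparisons[[d]] <- tryCatch(
      compare_methods(smse_tabs[[d]]),
      degenerate_input_error = function(e)
        degenerate_comparison(smse_tabs[[d]], conditionMessage(e)))
  }

  stage("report")
  bundle <- list(config = config, cohort = cohort, accuracy = acc,
                 budget = budget, model = model, validation = validation,
                 p_hat = p_hat, thresholds = thresholds,
                 assignments_categorical = assign_cat,
                 statistics_true = stats_true, bi = bi,
                 smse = smse_tabs, comparison = comparisons,
                 log = log$lines)
  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir)
    return(invisible(bundle))
  }
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  save_run_config(cfg, file.path(dir, "config.json"))
  if (isTRUE(cfg$write_cohort))
    write_cohort(bundle$cohort, file.path(dir, "cohort.csv"))
  save_model(bundle$model, file.path(dir, "model.json"))

  acc_lines <- unlist(lapply(names(bundle$accuracy), function(nm)
    format_accuracy(bundle$accuracy[[nm]], label = nm)))
  writeLines(acc_lines, file.path(dir, "accuracy.txt"))

  v <- bundle$validation
  jsonlite::write_json(list(c_statistic = v$c_statistic, ici = v$ici,
                            n_boot = v$n_boot, seed = v$seed),
                       file.path(dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (d in names(v$calibration))
    utils::write.csv(v$calibration[[d]],
                     file.path(dir, paste0("calibration_", d, ".csv")),
                     row.names = FALSE)

  utils::write.csv(bundle$bi, file.path(dir, "bi_estimates.csv"),
                   row.names = FALSE)
  for (d in names(bundle$smse)) {
    utils::write.csv(bundle$smse[[d]],
                     file.path(dir, paste0("smse_", d, ".csv")),
                     row.names = FALSE)
    cmp <- bundle$comparison[[d]]
    jsonlite::write_json(list(summary = cmp$summary,
                              f_statistic = cmp$f_statistic,
                              p_value = cmp$p_value,
                              tukey = cbind(pair = rownames(cmp$tukey),
                                            cmp$tukey),
                              excluded = cmp$excluded),
                         file.path(dir, paste0("comparison_", d, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Command-line entry point
#'
#' `cli_main(c("run-all", "--profile", "test", "--seed", "7", "--out",
#' "results/"))`. Subcommands: `simulate` (cohort CSV only), `run-all`
#' (full bundle), `accuracy` (reference-table report). Installed as the
#' executable script `inst/cli/cystmisclass`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 = success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: cystmisclass <simulate|run-all|accuracy> [--profile full|test]\n",
    "                    [--seed N] [--out DIR] [--config FILE]")
  if (length(args) < 1L) { message(usage); return(invisible(2L)) }
  cmd <- args[[1L]]
  opt <- list(profile = "test", seed = 1L, out = "cystmisclass_out",
              config = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (!key %in% names(opt)) { message("unknown option --", key)
                                return(invisible(2L)) }
    opt[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opt$seed <- as.integer(opt$seed)
  cfg <- if (!is.null(opt$config)) load_run_config(opt$config, opt$out) else
    run_config(profile = opt$profile, seed = opt$seed, out_dir = opt$out)
  status <- tryCatch({
    switch(cmd,
      simulate = {
        dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
        tab <- generate_cohort(cfg$spec,
                               seed = derive_seed(cfg$seed, "cohort"))
        write_cohort(tab, file.path(opt$out, "cohort.csv"))
        message("wrote ", file.path(opt$out, "cohort.csv"),
                " (", nrow(tab), " rows)")
        0L
      },
      `run-all` = {
        run_study(cfg)
        message("bundle written to ", cfg$out_dir %||% opt$out)
        0L
      },
      accuracy = {
        counts <- reference_accuracy_counts()
        for (r in seq_len(nrow(counts))) {
          ct <- contingency_table(counts$tp[r], counts$fp[r],
                                  counts$fn[r], counts$tn[r])
          cat(format_accuracy(compute_accuracy(ct),
                              label = paste(counts$classifier[r],
                                            counts$diversion[r])), sep = "\n")
        }
        0L
      },
      { message(usage); 2L })
  }, specification_error = function(e) { message("config error: ",
      conditionMessage(e)); 3L },
     schema_error = function(e) { message("data error: ",
      conditionMessage(e)); 4L },
     error = function(e) { message("estimation error: ",
      conditionMessage(e)); 5L })
  invisible(status)
}
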