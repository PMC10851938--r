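#' Run configuration for an end-to-end study
#'
#' Collects the settings of every pipeline stage. `fast_config()` is the
#' reduced CI-scale configuration (20 casualties, 64 hidden nodes,
#' single-point hidden grid); `full_config()` mirrors the
#' full-scale study (160 casualties, hidden grid 128/256/512, 500-epoch
#' budget).
#'
#' @param seed master seed; every stage derives its stream from it.
#' @param outdir output directory.
#' @param n_f cohort size (divisible by 5).
#' @param pool_size candidate parameter sets per sampling round.
#' @param spread Latin-hypercube spread fraction.
#' @param hidden_grid hidden-size grid for nested cross-validation.
#' @param epochs,batch_size,patience,tf_frac,lr training settings (see
#'   [gru_config()]).
#' @param budgets allocation budgets to sweep.
#' @param group_sizes subgroup sizes for the ratio analysis; sizes not
#'   dividing `n_f / 5` are dropped.
#' @param fractions residual-bleeding fractions.
#' @return A named list (class `run_config`).
#' @export
run_config <- function(seed, outdir = tempfile("hemotriage_run_"),
                       n_f = 160, pool_size = 5000, spread = 0.70,
                       hidden_grid = c(128, 256, 512), epochs = 500,
                       batch_size = 32, patience = 25, tf_frac = 0.25,
                       lr = 1e-3, budgets = 0:42,
                       group_sizes = c(32, 16, 8, 4),
                       fractions = c(0.1, 0.2, 0.3, 0.4, 0.5)) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(seed = as.integer(seed), outdir = outdir, n_f = n_f,
              pool_size = pool_size, spread = spread,
              hidden_grid = hidden_grid, epochs = epochs,
              batch_size = batch_size, patience = patience,
              tf_frac = tf_frac, lr = lr, budgets = budgets,
              group_sizes = group_sizes[(n_f / 5) %% group_sizes == 0],
              fractions = fractions)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @export
fast_config <- function(seed, outdir = tempfile("hemotriage_fast_")) {
  run_config(seed = seed, outdir = outdir, n_f = 20, pool_size = 2000,
             hidden_grid = 64, epochs = 120, batch_size = 8, patience = 20,
             lr = 2e-3, tf_frac = 0.2, group_sizes = c(4, 2))
}

#' @rdname run_config
#' @export
full_config <- function(seed, outdir = tempfile("hemotriage_full_")) {
  run_config(seed = seed)
}

#' Load a run configuration from a YAML file
#'
#' Fields present in the file override [run_config()] defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}

write_provenance <- function(obj, config, path) {
  obj$provenance <- list(seed = config$seed, config_hash = config_hash(config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Pipeline stage: cohort generation
#'
#' @param config a [run_config()].
#' @return The cohort, invisibly; writes the cohort dataset under
#'   `outdir/cohort/`.
#' @export
cmd_generate <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  cohort <- build_cohort(n_f = config$n_f, pool_size = config$pool_size,
                         spread = config$spread)
  write_cohort(cohort, file.path(config$outdir, "cohort"))
  message(sprintf("cohort: %d casualties (attrition: %s)", cohort$n_f,
                  paste(colSums(cohort$attrition[, -1]), collapse = " -> ")))
  invisible(cohort)
}

#' Pipeline stage: forecaster training
#'
#' @param config a [run_config()].
#' @param cohort optional in-memory cohort; read from `outdir` otherwise.
#' @return The [nested_cv()] result, invisibly; writes training history and
#'   error reports under `outdir`.
#' @export
cmd_train <- function(config, cohort = NULL) {
  if (is.null(cohort)) cohort <- read_cohort(file.path(config$outdir,
                                                       "cohort"))
  gcfg <- gru_config(hidden = config$hidden_grid[1], lr = config$lr,
                     epochs = config$epochs, batch_size = config$batch_size,
                     patience = config$patience, tf_frac = config$tf_frac)
  cv <- nested_cv(cohort, gcfg, hidden_grid = config$hidden_grid,
                  seed = config$seed)
  utils::write.csv(cv$fits, file.path(config$outdir, "cv_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(cv$test_report, file.path(config$outdir,
                                             "cv_test_report.csv"),
                   row.names = FALSE)
  write_provenance(list(selected_hidden = cv$selected_hidden,
                        n_fits = cv$n_fits,
                        mean_val_eps = as.list(cv$mean_val_eps)),
                   config, file.path(config$outdir, "cv_summary.json"))
  invisible(cv)
}

#' Pipeline stage: allocation sweeps
#'
#' @param config a [run_config()].
#' @param cohort,cv optional in-memory artifacts from the earlier stages.
#' @return List with the [run_analysis2()] sweep and [run_analysis3()]
#'   table, invisibly; writes tidy CSVs and a JSON summary.
#' @export
cmd_allocate <- function(config, cohort = NULL, cv = NULL) {
  if (is.null(cohort)) cohort <- read_cohort(file.path(config$outdir,
                                                       "cohort"))
  if (is.null(cv)) stop("train the forecaster first (cmd_train)")
  sweep <- run_analysis2(cohort, cv$predictors, budgets = config$budgets)
  a3 <- run_analysis3(cohort, cv$predictors,
                      group_sizes = config$group_sizes,
                      budgets = config$budgets)
  utils::write.csv(sweep$results, file.path(config$outdir,
                                            "allocation_sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(a3, file.path(config$outdir, "allocation_ratios.csv"),
                   row.names = FALSE)
  zero <- sweep$results[sweep$results$budget == min(config$budgets), ]
  write_provenance(list(budgets = range(config$budgets),
                        zero_budget_restored = stats::setNames(
                          as.list(tapply(zero$restored, zero$method, sum)),
                          sort(unique(zero$method)))),
                   config, file.path(config$outdir, "allocation_summary.json"))
  invisible(list(sweep = sweep, analysis3 = a3))
}

#' Pipeline stage: residual-bleeding detection
#'
#' @param config a [run_config()].
#' @param cohort,cv optional in-memory artifacts.
#' @return The fitted [fit_ncb_svm()] classifier, invisibly; writes the
#'   feature table and a classification report.
#' @export
cmd_detect <- function(config, cohort = NULL, cv = NULL) {
  if (is.null(cohort)) cohort <- read_cohort(file.path(config$outdir,
                                                       "cohort"))
  if (is.null(cv)) stop("train the forecaster first (cmd_train)")
  set.seed(config$seed + 1L)
  ncb <- generate_ncb_trajectories(cohort, fractions = config$fractions)
  feats <- ncb_feature_table(cohort, cv$predictors, ncb)
  clf <- fit_ncb_svm(feats, cv_seed = config$seed)
  utils::write.csv(feats, file.path(config$outdir, "ncb_features.csv"),
                   row.names = FALSE)
  write_provenance(list(n_controlled = sum(feats$label == "controlled"),
                        n_ncb = sum(feats$label == "ncb"),
                        accuracy = as.list(clf$accuracy),
                        cv_accuracy = as.list(clf$cv_accuracy),
                        boundary = clf$boundary),
                   config, file.path(config$outdir, "ncb_report.json"))
  invisible(clf)
}

#' Pipeline stage: summary report
#'
#' Collates the stage outputs into a single JSON summary (restored-count
#' curves, ratio tables, classification accuracies).
#'
#' @param config a [run_config()].
#' @return The summary list, invisibly.
#' @export
cmd_report <- function(config) {
  od <- config$outdir
  need <- c("allocation_sweep.csv", "allocation_ratios.csv",
            "ncb_report.json")
  for (f in need) {
    if (!file.exists(file.path(od, f))) {
      stop("missing artifact '", f,
           "': run cmd_allocate / cmd_detect first")
    }
  }
  sweep <- utils::read.csv(file.path(od, "allocation_sweep.csv"))
  ratios <- utils::read.csv(file.path(od, "allocation_ratios.csv"))
  ncb <- jsonlite::read_json(file.path(od, "ncb_report.json"),
                             simplifyVector = TRUE)
  restored <- stats::aggregate(restored ~ budget + method, data = sweep,
                               FUN = mean)
  summary <- list(restored_curves = restored,
                  ratio_table = ratios,
                  ncb = ncb[c("n_controlled", "n_ncb", "accuracy",
                              "cv_accuracy")])
  write_provenance(summary, config, file.path(od, "report.json"))
  invisible(summary)
}

#' End-to-end pipeline run
#'
#' Generate, train, allocate, detect, report -- all stages in order under a
#' single configuration and seed.
#'
#' @param config a [run_config()].
#' @return List with `cohort`, `cv`, `allocation`, `ncb`, `report`,
#'   invisibly.
#' @examples
#' \donttest{
#' cfg <- fast_config(seed = 11)
#' cfg$n_f <- 10; cfg$hidden_grid <- 8; cfg$epochs <- 4
#' res <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config) {
  cohort <- cmd_generate(config)
  cv <- cmd_train(config, cohort)
  alloc <- cmd_allocate(config, cohort, cv)
  clf <- cmd_detect(config, cohort, cv)
  rep <- cmd_report(config)
  invisible(list(cohort = cohort, cv = cv, allocation = alloc, ncb = clf,
                 report = rep))
}
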