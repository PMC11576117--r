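#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: cohort source (a
#' directory of CSVs or a synthetic-cohort size), feature construction,
#' bias calibration, state-count selection, fitting, costing and scenario
#' simulation.  Can be loaded from YAML with [read_pipeline_config()].
#'
#' @param output_dir Directory for artifacts.
#' @param cohort_dir Directory with `visits.csv`/`patients.csv`, or `NULL`
#'   to simulate.
#' @param n_patients Synthetic cohort size when simulating.
#' @param seed Global integer seed.
#' @param n_states Number of states to fit, or `NULL` to select by
#'   cross-validation.
#' @param candidate_n_states Candidates for state-count selection.
#' @param n_folds Cross-validation folds.
#' @param features An `hd_feature_config`.
#' @param bias An `hd_bias_calibration`.
#' @param costs An `hd_cost_config`.
#' @param scenario_delay,scenario_from_state,scenario_n Delayed-transition
#'   scenario: delay (years), delayed state, and population size.
#' @param fit_maxit Optimiser iteration cap for the final fit.
#' @return A list of class `hd_pipeline_config`.
#' @export
pipeline_config <- function(output_dir = "hdprog-output",
                            cohort_dir = NULL,
                            n_patients = 500L,
                            seed = 1L,
                            n_states = 5L,
                            candidate_n_states = 3:7,
                            n_folds = 5L,
                            features = feature_config(),
                            bias = bias_calibration(),
                            costs = cost_config(),
                            scenario_delay = 10,
                            scenario_from_state = 2L,
                            scenario_n = 10000L,
                            fit_maxit = 500L) {
  structure(list(output_dir = output_dir, cohort_dir = cohort_dir,
                 n_patients = as.integer(n_patients), seed = as.integer(seed),
                 n_states = n_states,
                 candidate_n_states = as.integer(candidate_n_states),
                 n_folds = as.integer(n_folds), features = features,
                 bias = bias, costs = costs,
                 scenario_delay = scenario_delay,
                 scenario_from_state = as.integer(scenario_from_state),
                 scenario_n = as.integer(scenario_n),
                 fit_maxit = as.integer(fit_maxit)),
            class = "hd_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level YAML keys mirror the arguments of [pipeline_config()]; nested
#' `features`, `bias` and `costs` blocks override the corresponding
#' constructor defaults field by field.
#'
#' @param path YAML file.
#' @return An `hd_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  scal <- intersect(names(y),
                    c("output_dir", "cohort_dir", "n_patients", "seed",
                      "n_states", "candidate_n_states", "n_folds",
                      "scenario_delay", "scenario_from_state", "scenario_n",
                      "fit_maxit"))
  args[scal] <- y[scal]
  if (!is.null(y$features)) args$features <- do.call(feature_config, y$features)
  if (!is.null(y$bias)) args$bias <- do.call(bias_calibration, y$bias)
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  sprintf("%08x",
          stable_hash(paste(deparse(unclass(config)), collapse = "")))
}

pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ..., "\n")
  cat(msg, file = stderr())
  if (!is.null(con)) cat(msg, file = con, append = TRUE)
}

model_to_json <- function(fit, calibration, stamp, path) {
  m <- fit$model
  jsonlite::write_json(list(
    stamp = stamp,
    n_states = m$n_states,
    rates = m$rates,
    mean_sojourn_times = mean_sojourn_times(m),
    emission_means = m$emission_means,
    emission_sds = m$emission_sds,
    feature_names = m$feature_names,
    log_likelihood = fit$log_likelihood,
    converged = fit$converged,
    calibration = calibration),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

pca_to_json <- function(pcm, stamp, path) {
  jsonlite::write_json(list(
    stamp = stamp, grouping_kind = pcm$grouping_kind,
    variables = pcm$variables, n_pcs = pcm$n_pcs,
    groups = lapply(pcm$groups, function(g)
      list(center = g$center, scale = g$scale, loadings = g$loadings,
           explained_variance = g$explained_variance))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Simulate or ingest a cohort, calibrate the death-age upper bound, select
#' the number of states by cross-validation (optional), run the iterative
#' grouped-PCA/CTHMM fit, decode per-visit states, attach the cost model,
#' fit per-state cost distributions, and simulate the delayed-transition
#' scenario.  Every artifact is stamped with the seed and a configuration
#' hash; a failing stage aborts with its name, leaving earlier artifacts in
#' place.
#'
#' @param config An `hd_pipeline_config` or a path to a YAML file.
#' @return (Invisibly) a list with the in-memory results: `cohort`,
#'   `calibration`, `selection` (or `NULL`), `pipeline_fit`, `cost_table`,
#'   `cost_dist`, `scenario`, and `artifact_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "hd_pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$output_dir, "pipeline.log")
  stamp <- list(seed = config$seed, config_hash = config_hash(config))
  stage <- function(name, expr) {
    pipeline_log(logf, "stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("cohort", {
    if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)
    else generate_cohort(cohort_params(config$n_patients,
                                       seed = config$seed))
  })
  calib <- stage("calibrate", calibrate_upper_bound(cohort, config$bias))
  selection <- NULL
  n_states <- config$n_states
  if (is.null(n_states)) {
    selection <- stage("select", {
      trans <- log_transform(cohort$visits,
                             config$features$log_transformed_variables)
      X <- trans[, default_score_model()$vars]
      grp <- merge_small_groups(
        assign_age_brackets(cohort$visits$age_at_visit,
                            make_age_brackets(cohort$visits$age_at_visit,
                                              config$features$age_bracket_width)),
        ncol(X) + 2L)
      pcm <- fit_group_pca(X, grp, config$features$n_pcs)
      # state-count selection uses observed events only (visits + recorded
      # deaths); the censoring augmentation corrects rate bias and should
      # not drive model complexity
      ev <- build_events(cohort, project(X, pcm, grp), upper_bound = NULL)
      sel <- select_num_states(ev, selection_config(
        config$candidate_n_states, config$n_folds, seed = config$seed))
      utils::write.csv(sel$table,
                       file.path(config$output_dir, "selection.csv"),
                       row.names = FALSE)
      sel
    })
    n_states <- selection$chosen
  }
  pf <- stage("fit", iterative_fit(cohort, config$features, n_states,
                                   upper_bound = calib$upper_bound,
                                   maxit = config$fit_maxit))
  stage("persist-model", {
    model_to_json(pf$fit, calib, stamp,
                  file.path(config$output_dir, "model.json"))
    pca_to_json(pf$pc_model, stamp,
                file.path(config$output_dir, "pc_model.json"))
  })
  cost_table <- stage("costs", {
    ct <- cohort_costs(cohort, pf$states, config$costs,
                       seed = config$seed + 2L)
    utils::write.csv(ct, file.path(config$output_dir, "costs.csv"),
                     row.names = FALSE)
    ct
  })
  cost_dist <- stage("cost-distribution",
                     fit_state_cost_distribution(cost_table,
                                                 min_per_state = 10L))
  scen <- stage("scenario", {
    shares <- t(sapply(sort(unique(cost_table$fitted_state)), function(s) {
      m <- colMeans(cost_table[cost_table$fitted_state == s,
                               c("benefits", "therapies", "lost_gdp",
                                 "care")])
      if (sum(m) == 0) m <- rep(0.25, 4) else m <- m / sum(m)
      m
    }))
    sc <- compare_scenarios(
      pf$fit$model,
      intervention(config$scenario_from_state, config$scenario_delay),
      scenario_config(config$scenario_n, seed = config$seed + 3L,
                      cost_dist = cost_dist, category_shares = shares,
                      pension_age = config$costs$pension_age,
                      salary_quantile_table =
                        config$costs$salary_quantile_table))
    jsonlite::write_json(list(
      stamp = stamp, mean_saving = sc$mean_saving,
      ci_mean_saving = sc$ci_mean_saving,
      category_means = sc$category_means,
      category_saving = sc$category_saving, n = sc$n),
      file.path(config$output_dir, "scenario.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    sc
  })
  pipeline_log(logf, "done")
  invisible(list(cohort = cohort, calibration = calib,
                 selection = selection, pipeline_fit = pf,
                 cost_table = cost_table, cost_dist = cost_dist,
                 scenario = scen, artifact_dir = config$output_dir))
}

#' Human-readable report from pipeline artifacts
#'
#' Regenerates (idempotently) a plain-text summary from the JSON/CSV
#' artifacts of [run_pipeline()]: the sojourn-time table, the emission
#' summary, the per-state four-category cost table, and the scenario
#' summary.
#'
#' @param artifact_dir Directory written by [run_pipeline()].
#' @return The report as a character vector of lines (invisibly); the
#'   report is also printed and written to `report.txt`.
#' @export
pipeline_report <- function(artifact_dir) {
  mfile <- file.path(artifact_dir, "model.json")
  if (!file.exists(mfile)) stop("missing artifact: model.json")
  m <- jsonlite::read_json(mfile, simplifyVector = TRUE)
  lines <- c("== Disease progression model ==",
             paste0("states: ", m$n_states, " (",
                    m$n_states - 1, " living + death); log-likelihood ",
                    format(m$log_likelihood, digits = 10)),
             "mean sojourn times (years):",
             paste(sprintf("  state %d: %.1f", seq_along(m$mean_sojourn_times),
                           m$mean_sojourn_times), collapse = "\n"),
             "emission means (per state x feature):",
             utils::capture.output(print(round(
               matrix(unlist(m$emission_means),
                      nrow = m$n_states - 1), 3))))
  cfile <- file.path(artifact_dir, "costs.csv")
  if (!file.exists(cfile)) stop("missing artifact: costs.csv")
  ct <- utils::read.csv(cfile)
  agg <- stats::aggregate(ct[, c("benefits", "therapies", "lost_gdp",
                                 "care")],
                          list(state = ct$fitted_state), mean)
  lines <- c(lines, "", "== Mean monthly cost (GBP) by state ==",
             utils::capture.output(print(round(agg), row.names = FALSE)))
  sfile <- file.path(artifact_dir, "scenario.json")
  if (!file.exists(sfile)) stop("missing artifact: scenario.json")
  s <- jsonlite::read_json(sfile, simplifyVector = TRUE)
  lines <- c(lines, "", "== Intervention scenario ==",
             sprintf("mean lifetime saving: GBP %.0f (95%% CI %.0f to %.0f), n = %d",
                     s$mean_saving, s$ci_mean_saving[1], s$ci_mean_saving[2],
                     s$n),
             "mean saving by category (GBP):",
             utils::capture.output(print(round(unlist(s$category_saving)))))
  selfile <- file.path(artifact_dir, "selection.csv")
  if (file.exists(selfile)) {
    sel <- utils::read.csv(selfile)
    lines <- c(lines, "", "== State-count selection ==",
               utils::capture.output(print(sel, row.names = FALSE)))
  }
  writeLines(lines, file.path(artifact_dir, "report.txt"))
  cat(lines, sep = "\n")
  invisible(lines)
}
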