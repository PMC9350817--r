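# End-to-end driver: dashboard-style selections (outcome, aim, level,
# granularity, SDoH subset) as a config, writing all artifacts to disk.

.config_error <- function(...) {
  stop(structure(class = c("upho_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

.pipeline_error <- function(stage, parent) {
  stop(structure(class = c("upho_pipeline_error", "error", "condition"),
                 list(message = sprintf("[stage %s] %s", stage,
                                        conditionMessage(parent)),
                      call = NULL, stage = stage)))
}

#' Build and validate a run configuration
#'
#' Encodes the dashboard's selection menu: outcome of interest, analytics
#' aim, level of analysis (patient with a tract geoid, or population),
#' geographic granularity, and an optional SDoH feature subset. Only the
#' causal-pathway-analysis aim and census-tract granularity are implemented;
#' other menu selections are rejected with a clear message. Patient-level
#' analysis is neighborhood-proxy analysis: the patient inherits tract-level
#' exposures.
#'
#' @param output_dir directory where artifacts are written (created if
#'   needed).
#' @param outcome outcome of interest (only `"obesity_prev"` is available).
#' @param aim analytics aim (only `"causal_pathway_analysis"`).
#' @param level `"population"` or `"patient"`.
#' @param geoid tract FIPS of the patient's address (required when
#'   `level = "patient"`).
#' @param region_geoids optional geoids restricting a population-level run
#'   (default: all tracts in the input).
#' @param granularity only `"census_tract"`.
#' @param sdoh_domains optional subset of [tract_features()] restricting the
#'   model's features.
#' @param input `"synthetic"` or a path to a tract CSV.
#' @param column_map optional column mapping for [read_tracts()].
#' @param seed integer master seed (generator seed and split seed default to
#'   it).
#' @param generator list of overrides for [generator_config()].
#' @param analytics list of overrides for [analytics_config()].
#' @param top_k number of ML predictor edges to add (default 5).
#' @return A validated list of class `upho_run_config`.
#' @export
run_config <- function(output_dir, outcome = "obesity_prev",
                       aim = "causal_pathway_analysis",
                       level = c("population", "patient"), geoid = NULL,
                       region_geoids = NULL, granularity = "census_tract",
                       sdoh_domains = NULL, input = "synthetic",
                       column_map = NULL, seed = 1, generator = list(),
                       analytics = list(), top_k = 5) {
  if (missing(output_dir) || !is.character(output_dir)) {
    .config_error("output_dir is required")
  }
  if (!identical(outcome, "obesity_prev")) {
    .config_error("outcome '", outcome, "' is not available; ",
                  "this build implements obesity prevalence (obesity_prev)")
  }
  if (!identical(aim, "causal_pathway_analysis")) {
    .config_error("analytics aim '", aim, "' is not available; ",
                  "select causal_pathway_analysis")
  }
  if (!identical(granularity, "census_tract")) {
    .config_error("granularity '", granularity,
                  "' is not available; select census_tract")
  }
  level <- match.arg(level)
  if (level == "patient" && (is.null(geoid) || !grepl("^[0-9]{11}$", geoid))) {
    .config_error("patient-level analysis requires an 11-digit tract geoid")
  }
  if (!is.null(sdoh_domains)) {
    bad <- setdiff(sdoh_domains, tract_features())
    if (length(bad)) .config_error("unknown SDoH feature(s): ",
                                   paste(bad, collapse = ", "))
    if (length(sdoh_domains) < 2) {
      .config_error("sdoh_domains must keep at least 2 features")
    }
  }
  structure(list(outcome = outcome, aim = aim, level = level, geoid = geoid,
                 region_geoids = region_geoids, granularity = granularity,
                 sdoh_domains = sdoh_domains, input = input,
                 column_map = column_map, seed = as.integer(seed),
                 generator = generator, analytics = analytics,
                 top_k = top_k, output_dir = output_dir),
            class = "upho_run_config")
}

# Resolve a config given as a list / JSON path into an upho_run_config.
.resolve_config <- function(config) {
  if (inherits(config, "upho_run_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(config$column_map)) config$column_map <- unlist(config$column_map)
    if (!is.null(config$generator)) config$generator <- as.list(config$generator)
    if (!is.null(config$analytics)) config$analytics <- as.list(config$analytics)
  }
  if (!is.list(config)) .config_error("config must be a list or a JSON path")
  do.call(run_config, config)
}

#' Run the full pipeline and write the report bundle
#'
#' Executes generate/load, analytics, graph construction, ML and inference
#' enrichment, pathway tracing and explanation/recommendation rendering, and
#' writes `tracts.csv`, `analytics.json`, `graph.json`, `graph.graphml`,
#' `pathways.json`, `report.md` and `run.log` to the configured output
#' directory. With fixed seeds the JSON artifacts are byte-identical across
#' reruns.
#'
#' Configuration errors signal a condition of class `upho_config_error`;
#' failures inside a pipeline stage signal `upho_pipeline_error` with the
#' stage recorded (the CLI wrapper maps these to exit codes 2 and 1).
#'
#' @param config an [run_config()] object, a plain list of its arguments, or
#'   a path to a JSON file of them.
#' @return Invisibly, a list with the tract table, the analytics fit, the
#'   enriched graph, the traced pathways, the recommendations, and the output
#'   paths.
#' @export
upho_run <- function(config) {
  cfg <- .resolve_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("upho run (%s level, aim %s, granularity %s)",
                         cfg$level, cfg$aim, cfg$granularity),
                 sprintf("seed: %d", cfg$seed))
  stage <- function(name, expr) {
    log_lines <<- c(log_lines, sprintf("stage: %s", name))
    tryCatch(expr, error = function(e) {
      log_lines <<- c(log_lines, sprintf("ERROR in stage %s: %s", name,
                                         conditionMessage(e)))
      writeLines(log_lines, file.path(cfg$output_dir, "run.log"))
      .pipeline_error(name, e)
    })
  }

  table <- stage("input", {
    if (identical(cfg$input, "synthetic")) {
      gen_args <- modifyList(list(seed = cfg$seed), cfg$generator)
      gen <- do.call(generator_config, gen_args)
      log_lines <- c(log_lines,
                     sprintf("generator: n_tracts=%d seed=%d noise_sd=%.4g",
                             gen$n_tracts, gen$seed, gen$outcome_noise_sd))
      generate_tracts(gen)
    } else {
      read_tracts(cfg$input, cfg$column_map)
    }
  })
  if (cfg$level == "patient" && !cfg$geoid %in% table$geoid) {
    .config_error("patient geoid ", cfg$geoid, " not present in the input table")
  }
  if (!is.null(cfg$region_geoids)) {
    table <- table[table$geoid %in% cfg$region_geoids, , drop = FALSE]
  }

  features <- intersect(tract_features(), names(table))
  if (!is.null(cfg$sdoh_domains)) features <- intersect(features, cfg$sdoh_domains)

  acfg <- stage("analytics-config", {
    do.call(analytics_config,
            modifyList(list(split_seed = cfg$seed), cfg$analytics))
  })
  log_lines <- c(log_lines,
                 sprintf("analytics: train_fraction=%g cv_folds=%d split_seed=%d",
                         acfg$train_fraction, acfg$cv_folds, acfg$split_seed),
                 sprintf("grid: C={%s} epsilon={%s}",
                         paste(acfg$grid_C, collapse = ","),
                         paste(acfg$grid_epsilon, collapse = ",")),
                 sprintf("thresholds: vif=%g alpha=%g", acfg$vif_threshold,
                         acfg$significance_alpha))

  focus_geoid <- if (cfg$level == "patient") cfg$geoid else NULL
  fit <- stage("analytics", {
    run_analytics(table, outcome = cfg$outcome, features = features,
                  focus_geoid = focus_geoid, config = acfg)
  })

  focus <- if (cfg$level == "patient") {
    list(individual = "individual:patient", geoid = cfg$geoid)
  } else {
    list(population = "population:region", geoids = table$geoid)
  }
  source_node <- if (cfg$level == "patient") "individual:patient"
                 else "population:region"

  kg <- stage("graph", {
    kg <- build_graph(default_scheme(), table, focus)
    kg <- enrich_with_ml(kg, fit$importance, top_k = min(cfg$top_k,
                                                         nrow(fit$importance)))
    enrich_with_inference(kg, default_rules())
  })

  paths <- stage("pathways", {
    trace_pathways(kg, source_node, "DO:Obesity")
  })
  recs <- summarize_recommendations(kg, paths)

  out <- stage("write", {
    files <- list(
      tracts = file.path(cfg$output_dir, "tracts.csv"),
      analytics = file.path(cfg$output_dir, "analytics.json"),
      graph_json = file.path(cfg$output_dir, "graph.json"),
      graphml = file.path(cfg$output_dir, "graph.graphml"),
      pathways = file.path(cfg$output_dir, "pathways.json"),
      report = file.path(cfg$output_dir, "report.md"),
      log = file.path(cfg$output_dir, "run.log"))
    write_tracts(table, files$tracts)
    analytics_to_json(fit, files$analytics)
    write_graph_json(kg, files$graph_json)
    write_graphml(kg, files$graphml)
    pathways_to_json(paths, files$pathways)
    writeLines(.render_report(cfg, fit, kg, paths, table), files$report)
    files
  })
  log_lines <- c(log_lines, "status: ok")
  writeLines(log_lines, out$log)

  invisible(list(config = cfg, table = table, analytics = fit, graph = kg,
                 pathways = paths, recommendations = recs, files = out))
}

.render_report <- function(cfg, fit, kg, paths, table) {
  imp <- fit$importance[order(-fit$importance$scaled), ]
  lines <- c(
    "# Population health causal-pathway report", "",
    sprintf("- level: %s%s", cfg$level,
            if (cfg$level == "patient") paste0(" (tract ", cfg$geoid, ")") else ""),
    sprintf("- outcome: %s", fit$outcome),
    sprintf("- tracts analysed: %d", nrow(table)),
    sprintf("- model: linear-kernel epsilon-SVR, C = %g, epsilon = %g",
            fit$cv$best[["C"]], fit$cv$best[["epsilon"]]),
    sprintf("- RMSE train/test: %.3f / %.3f", fit$evaluation$rmse_train,
            fit$evaluation$rmse_test),
    sprintf("- R^2 train/test: %.3f / %.3f", fit$evaluation$r2_train,
            fit$evaluation$r2_test),
    "", "## Feature importance (0-100)", "",
    "| feature | scaled importance |", "|---|---|",
    sprintf("| %s | %.2f |", imp$feature, imp$scaled), "")
  if (!is.null(fit$attribution)) {
    phi <- sort(fit$attribution$phi, decreasing = TRUE)
    lines <- c(lines,
      sprintf("## Neighborhood attribution (tract %s)", fit$attribution$geoid), "",
      sprintf("Baseline (regional average) prediction: %.2f%%; tract prediction: %.2f%%.",
              fit$attribution$baseline_prediction,
              fit$attribution$instance_prediction), "",
      "| feature | contribution (percentage points) |", "|---|---|",
      sprintf("| %s | %+.2f |", names(phi), phi), "")
  }
  c(lines, pathways_to_markdown(kg, paths, reference_table = table))
}
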