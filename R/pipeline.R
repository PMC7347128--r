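#' Configure an end-to-end pipeline run
#'
#' Bundles every path and tuning parameter for [run_pipeline()]. Can be
#' loaded from a YAML file whose keys match the argument names.
#'
#' @param calls Path to the 311 CSV export (required).
#' @param mapping Path to the complaint-type/domain CSV (required).
#' @param tracts Optional path to tract polygons (GeoJSON).
#' @param vacancy Optional path to a HUD/USPS-layout vacancy CSV.
#' @param out_dir Output directory (created if needed).
#' @param model_id Which model to fit and evaluate (1, 2 or 3).
#' @param split_fraction Fit-set fraction for [split_calls()].
#' @param threshold Classification cutoff.
#' @param min_count High-frequency complaint threshold.
#' @param min_calls Minimum calls per summarized tract.
#' @param shared_ratio Optional skew-ratio rule for admitting shared tokens
#'   to the scoring vocabulary (see [build_lexicon()]); `NULL` (default)
#'   scores on blight-exclusive tokens only.
#' @param seed Integer seed recorded in every artifact.
#' @param normalization_map Named character vector for [text_config()].
#' @return A `blight_pipeline_config` list.
#' @export
pipeline_config <- function(calls, mapping, tracts = NULL, vacancy = NULL,
                            out_dir = "blight311_run", model_id = 3,
                            split_fraction = 0.5, threshold = 0.5,
                            min_count = 1000, min_calls = 1,
                            shared_ratio = NULL, seed = 1L,
                            normalization_map = character()) {
  if (missing(calls) || is.null(calls)) {
    stop_config("pipeline_config: 'calls' path is required")
  }
  if (missing(mapping) || is.null(mapping)) {
    stop_config("pipeline_config: 'mapping' path is required")
  }
  for (p in c(calls, mapping, tracts, vacancy)) {
    if (!is.null(p) && !file.exists(p)) {
      stop_config(sprintf("pipeline_config: input path does not exist: %s", p))
    }
  }
  structure(
    list(
      calls = calls, mapping = mapping, tracts = tracts, vacancy = vacancy,
      out_dir = out_dir, model_id = as.integer(model_id),
      split_fraction = split_fraction, threshold = threshold,
      min_count = min_count, min_calls = min_calls,
      shared_ratio = shared_ratio, seed = as.integer(seed),
      normalization_map = normalization_map
    ),
    class = "blight_pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `blight_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  nm <- raw$normalization_map
  if (!is.null(nm)) raw$normalization_map <- unlist(nm)
  do.call(pipeline_config, raw)
}

#' Run the full blight-identification pipeline
#'
#' Executes the stages in order — ingest, high-frequency filter, domain
#' labelling, text cleaning/tokenization, lexicon construction, fit/holdout
#' split, logistic fit, holdout evaluation, then (when tract polygons are
#' supplied) tract assignment/aggregation and (when a vacancy table is
#' supplied) the correlation battery — and writes every artifact to
#' `config$out_dir`: `lexicon.csv`, `model.json`, `evaluation.json`,
#' `tract_summaries.csv` (+ `.geojson`), `correlations.csv`, and a
#' `manifest.json` stamping the configuration hash, seed, and per-stage
#' record counts. Identical configuration and inputs give identical
#' outputs. Any stage failure propagates with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results: `calls`,
#'   `lexicon`, `model`, `evaluation`, `summaries`, `correlations`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "blight_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = class(e)[1], parent = e)
    })
  }
  counts <- list()

  calls <- stage("ingest", read_calls(config$calls))
  counts$ingested <- nrow(calls)
  hf <- stage("ingest", filter_high_frequency(calls, config$min_count))
  counts$high_frequency <- nrow(hf$calls)
  counts$high_frequency_types <- length(hf$complaint_types)
  mapping <- stage("ingest", read_domain_mapping(config$mapping))
  labelled <- stage("ingest", assign_domains(hf$calls, mapping))
  counts$labelled <- sum(!is.na(labelled$blight_label))

  tcfg <- text_config(normalization_map = config$normalization_map)
  tokened <- stage("textprep", tokenize_calls(labelled, tcfg))

  training <- tokened[!is.na(tokened$blight_label), ]
  parts <- stage("model", split_calls(training, config$split_fraction, config$seed))
  lexicon <- stage("lexicon", build_lexicon(parts$fit, shared_ratio = config$shared_ratio))
  write_lexicon(lexicon, file.path(config$out_dir, "lexicon.csv"))

  fit_scored <- stage("lexicon", score_calls(parts$fit, lexicon))
  model <- stage("model", fit_blight_model(fit_scored, config$model_id))
  write_model(model, file.path(config$out_dir, "model.json"),
              threshold = config$threshold, seed = config$seed)
  counts$fit <- nrow(fit_scored)

  holdout <- stage("lexicon", score_calls(parts$holdout, lexicon))
  evaluation <- NULL
  if (nrow(holdout) > 0L) {
    evaluation <- stage("evaluate", evaluate_model(model, holdout, config$threshold))
    jsonlite::write_json(
      c(as.list(evaluation$metrics), list(threshold = config$threshold)),
      file.path(config$out_dir, "evaluation.json"),
      auto_unbox = TRUE, digits = NA
    )
    counts$holdout <- nrow(holdout)
  }

  summaries <- NULL
  correlations <- NULL
  if (!is.null(config$tracts)) {
    tracts <- stage("spatial", read_tracts(config$tracts))
    scored_all <- stage("lexicon", score_calls(tokened, lexicon))
    scored_all$predicted_proba <- stage("model", predict_proba(model, scored_all))
    scored_all$predicted_label <- classify(scored_all$predicted_proba, config$threshold)
    located <- stage("spatial", assign_tracts(scored_all, tracts))
    agg <- stage("spatial", aggregate_tracts(located, config$min_calls))
    summaries <- agg$summaries
    counts$tracts_summarized <- nrow(summaries)
    readr::write_csv(summaries, file.path(config$out_dir, "tract_summaries.csv"))
    write_tract_geojson(summaries, tracts,
                        file.path(config$out_dir, "tract_summaries.geojson"))
    if (!is.null(config$vacancy)) {
      vac <- stage("spatial", read_vacancy(config$vacancy, "HUD_USPS"))
      correlations <- stage("spatial", vacancy_battery(summaries, vac))
      readr::write_csv(correlations, file.path(config$out_dir, "correlations.csv"))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("blight311")),
    seed = config$seed,
    threshold = config$threshold,
    model_id = config$model_id,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    record_counts = counts
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    calls = tokened, lexicon = lexicon, model = model,
    evaluation = evaluation, summaries = summaries,
    correlations = correlations, manifest = manifest
  ))
}
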