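# Thin orchestration of the full analysis: simulate or load -> curate ->
# rarity filter -> split -> (optional) nested selection -> train -> predict
# -> evaluate -> optional cohort analyses, with a JSON run manifest. Stage
# outputs are pure functions of (inputs, config, seeds): re-running with the
# same configuration yields byte-identical reports.

#' Build a run configuration
#'
#' Defaults carry the analysis constants in one place: rarity cutoff 0.001
#' (MAF < 0.1%), train fraction 2/3, clinical thresholds 0.9 / 0.1, outer
#' 10-fold / inner 5-fold selection, and the boosted-tree model settings.
#'
#' @param input Optional path to a labelled feature TSV; when `NULL`,
#'   `simulate` must supply a generator spec.
#' @param simulate Optional [feature_gen_spec()] used when `input` is `NULL`.
#' @param schema A [feature_schema()]; defaults to the 76-feature
#'   placeholder (ignored for simulated input, which carries its own).
#' @param maf_cutoff Rarity cutoff (default 0.001).
#' @param train_fraction Training share (default 2/3).
#' @param thresholds A [threshold_pair()].
#' @param selection List: `enabled` (default FALSE), `outer_k`, `inner_k`,
#'   `metric`, and optionally `registry` (defaults to [default_registry()]).
#' @param boost List: `n_rounds`, `tree_depth`.
#' @param seed Master integer seed.
#' @param out_dir Output directory for reports (default `tempdir()` subdir).
#' @return A list of class `pb_run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL,
                       schema = default_feature_schema(),
                       maf_cutoff = 0.001, train_fraction = 2 / 3,
                       thresholds = threshold_pair(),
                       selection = list(enabled = FALSE, outer_k = 10,
                                        inner_k = 5, metric = "pr_auc"),
                       boost = list(n_rounds = 500, tree_depth = 3),
                       seed = 1,
                       out_dir = file.path(tempdir(), "pathboost-run")) {
  structure(as.list(environment()), class = "pb_run_config")
}

#' Load a run configuration from YAML
#'
#' Recognised top-level keys mirror the arguments of [run_config()];
#' `simulate` holds [feature_gen_spec()] arguments.
#'
#' @param path YAML file path.
#' @return A `pb_run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  for (key in intersect(names(y), c("input", "maf_cutoff", "train_fraction",
                                    "seed", "out_dir"))) {
    cfg[[key]] <- y[[key]]
  }
  if (!is.null(y$thresholds)) {
    cfg$thresholds <- threshold_pair(upper = y$thresholds$upper %||% 0.9,
                                     lower = y$thresholds$lower %||% 0.1)
  }
  if (!is.null(y$simulate)) cfg$simulate <- do.call(feature_gen_spec, y$simulate)
  for (key in c("selection", "boost")) {
    if (!is.null(y[[key]])) cfg[[key]] <- utils::modifyList(cfg[[key]], y[[key]])
  }
  cfg
}

run_stage <- function(manifest, stage, code) {
  manifest$stages <- c(manifest$stages, stage)
  result <- tryCatch(code, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    write_manifest(manifest)
    pb_abort(paste0("Pipeline failed at stage '", stage, "': ",
                    conditionMessage(e)), "pb_pipeline_error")
  })
  result
}

write_manifest <- function(manifest) {
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "config")],
    file.path(manifest$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}

#' Run the end-to-end pipeline
#'
#' Executes the stages in order and writes `model.json`, `metrics.json`,
#' optionally `selection.json`, and `manifest.json` to the configured
#' output directory. Identical configurations (including seeds) produce
#' byte-identical reports.
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [load_run_config()]).
#' @return The manifest (list) invisibly, with elements `metrics` (one-row
#'   tibble), `model_path`, `selection` (report or NULL) and `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "pb_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "pathboost",
    version = as.character(utils::packageVersion("pathboost")),
    seed = config$seed, out_dir = config$out_dir, stages = character(0),
    config = config
  )

  data <- run_stage(manifest, "curate", {
    ds <- if (!is.null(config$input)) {
      read_feature_table(config$input, config$schema)
    } else if (!is.null(config$simulate)) {
      gen_feature_table(config$simulate)
    } else {
      pb_usage_error("Config must provide either `input` or `simulate`.")
    }
    counts <- table(ds$label)
    if (length(counts) < 2L) {
      pb_validation_error("Curated data must contain both pathogenic and benign variants.")
    }
    filter_rare(ds, config$maf_cutoff)
  })

  split <- run_stage(manifest, "split", {
    split_train_test(data, config$train_fraction, seed = derive_seed(config$seed, 1))
  })

  selection <- NULL
  if (isTRUE(config$selection$enabled)) {
    selection <- run_stage(manifest, "select", {
      registry <- config$selection$registry %||% default_registry()
      rep <- nested_select(
        registry, split$train,
        outer_k = config$selection$outer_k, inner_k = config$selection$inner_k,
        metric = config$selection$metric, seed = derive_seed(config$seed, 2)
      )
      selection_report_json(rep, file.path(config$out_dir, "selection.json"))
      rep
    })
  }

  model <- run_stage(manifest, "train", {
    m <- fit_adaboost(
      split$train, n_rounds = config$boost$n_rounds,
      tree_depth = config$boost$tree_depth, seed = derive_seed(config$seed, 3)
    )
    save_model(m, file.path(config$out_dir, "model.json"))
    m
  })

  metrics <- run_stage(manifest, "evaluate", {
    preds <- predict(model, split$test, thresholds = config$thresholds)
    met <- evaluate_predictions(
      dplyr::mutate(preds, label = split$test$label),
      thresholds = config$thresholds
    )
    jsonlite::write_json(as.list(met), file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_tsv(dplyr::mutate(preds, label = split$test$label),
                     file.path(config$out_dir, "predictions.tsv"))
    met
  })

  manifest$n_train <- nrow(split$train)
  manifest$n_test <- nrow(split$test)
  manifest$winner <- if (!is.null(selection)) selection$winner else NULL
  manifest$paths <- list(
    model = file.path(config$out_dir, "model.json"),
    metrics = file.path(config$out_dir, "metrics.json"),
    predictions = file.path(config$out_dir, "predictions.tsv"),
    selection = if (!is.null(selection)) file.path(config$out_dir, "selection.json") else NULL,
    manifest = file.path(config$out_dir, "manifest.json")
  )
  manifest$metrics_summary <- as.list(metrics)
  write_manifest(manifest)
  manifest$metrics <- metrics
  manifest$model <- model
  manifest$selection <- selection
  invisible(manifest)
}
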