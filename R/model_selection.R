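# Nested cross-validation: inner k-fold hyperparameter tuning per candidate
# algorithm, outer k-fold comparison, selection of the best algorithm by
# mean out-of-fold metric. Every stochastic step is driven by sub-seeds
# derived from one master seed, so a selection report is bit-reproducible.

#' Stratified fold assignment
#'
#' Assigns each row a fold index in `0 .. k-1`, stratified by class: within
#' each class, rows are shuffled and folds filled cyclically, so per-fold
#' class counts differ by at most one across folds. Deterministic under
#' `seed`.
#'
#' @param labels Per-row class vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `0:(k-1)`.
#' @export
make_folds <- function(labels, k, seed = 1) {
  if (k < 2) pb_usage_error("`k` must be >= 2.")
  counts <- table(labels)
  if (any(counts < k)) {
    small <- names(counts)[which(counts < k)[1]]
    pb_abort(paste0(
      "Class '", small, "' has fewer rows (", counts[[small]],
      ") than folds (", k, ")."
    ), "pb_stratification_error")
  }
  folds <- integer(length(labels))
  pb_with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      folds[sample(idx)] <- rep_len(sample(seq_len(k) - 1L), length(idx))
    }
  })
  folds
}

#' Define a candidate algorithm
#'
#' A candidate is a name, a finite hyperparameter grid, and a fit/predict
#' pair: `fit(data, params, schema)` trains on a labelled variant tibble and
#' returns any model object; `predict(model, data)` returns the per-row
#' probability of the pathogenic class.
#'
#' @param name Algorithm name.
#' @param grid Named list of finite value vectors; the grid is expanded in
#'   row-major order (first parameter varying fastest) and ties in tuning are
#'   broken by that order.
#' @param fit,predict Functions as described above.
#' @return A list of class `pb_candidate`.
#' @export
candidate <- function(name, grid, fit, predict) {
  if (!is.list(grid) || length(grid) == 0L || any(lengths(grid) == 0L)) {
    pb_usage_error("A candidate's hyperparameter grid must be a non-empty named list.")
  }
  structure(list(name = name, grid = grid, fit = fit, predict = predict),
            class = "pb_candidate")
}

expand_param_grid <- function(grid) {
  g <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

# Metric registry used by tuning and selection; all metrics are maximised
# (Brier is negated).
selection_metric <- function(name) {
  switch(name,
    pr_auc = function(labels, scores) pr_auc(labels, scores),
    roc_auc = function(labels, scores) roc_auc(labels, scores),
    neg_brier = function(labels, scores) -brier(labels, scores),
    pb_usage_error(paste0("Unknown selection metric '", name, "'."))
  )
}

# Mean out-of-fold metric of one (candidate, parameter setting) under a fixed
# fold assignment. A fit or predict failure scores -Inf (logged, not fatal).
cv_score <- function(alg, data, params, folds, metric_fn, schema) {
  scores <- vapply(sort(unique(folds)), function(f) {
    tryCatch({
      fit <- alg$fit(data[folds != f, , drop = FALSE], params, schema)
      pr <- alg$predict(fit, data[folds == f, , drop = FALSE])
      metric_fn(data$label[folds == f], pr)
    }, error = function(e) {
      warn(paste0("Candidate '", alg$name, "' failed on a fold (",
                  conditionMessage(e), "); scored -Inf."))
      -Inf
    })
  }, numeric(1))
  mean(scores)
}

#' Inner-loop hyperparameter tuning
#'
#' Scores every grid point of one candidate by stratified k-fold
#' cross-validation on `train` and returns the grid point with maximal mean
#' out-of-fold metric. Ties are broken by grid order (first wins); a fit
#' failure scores that point `-Inf` rather than aborting.
#'
#' @param alg A [candidate()].
#' @param train Labelled variant tibble.
#' @param k Number of inner folds (default 5).
#' @param metric Metric name: `"pr_auc"` (default), `"roc_auc"`, `"neg_brier"`.
#' @param seed Integer seed (drives the fold assignment).
#' @param schema Optional feature schema.
#' @return A list: `params` (best setting), `score` (its mean metric),
#'   `grid_scores` (tibble of all settings and scores).
#' @export
inner_tune <- function(alg, train, k = 5, metric = "pr_auc", seed = 1,
                       schema = NULL) {
  schema <- dataset_schema(train, schema)
  metric_fn <- selection_metric(metric)
  settings <- expand_param_grid(alg$grid)
  folds <- make_folds(train$label, k, seed)
  scores <- vapply(settings, function(p) cv_score(alg, train, p, folds, metric_fn, schema),
                   numeric(1))
  best <- which.max(scores)
  list(
    params = settings[[best]],
    score = scores[[best]],
    grid_scores = tibble(
      setting = vapply(settings, function(p) paste(names(p), unlist(p), sep = "=", collapse = ","), character(1)),
      score = scores
    )
  )
}

#' Nested cross-validation algorithm selection
#'
#' For each outer fold: tune every candidate's hyperparameters by inner
#' k-fold cross-validation on the outer-training part only, refit at the
#' chosen setting, and score on the held-out outer fold. The winner is the
#' candidate with the maximal mean outer-fold metric (ties: first in
#' registry order). Outer-fold rows are never visible to the inner loop.
#'
#' @param registry Non-empty list of [candidate()] objects.
#' @param train Labelled variant tibble.
#' @param outer_k,inner_k Outer/inner fold counts (defaults 10 and 5).
#' @param metric Selection metric name (default `"pr_auc"`).
#' @param seed Master integer seed; all fold assignments and per-fold tuning
#'   seeds derive from it.
#' @param schema Optional feature schema.
#' @return A `pb_selection_report`: per-algorithm outer-fold scores, means
#'   and standard deviations, chosen hyperparameters per fold, the winner,
#'   and the seed.
#' @export
nested_select <- function(registry, train, outer_k = 10, inner_k = 5,
                          metric = "pr_auc", seed = 1, schema = NULL) {
  if (!is.list(registry) || length(registry) == 0L) {
    pb_usage_error("`registry` must be a non-empty list of candidates.")
  }
  if (inherits(registry, "pb_candidate")) registry <- list(registry)
  schema <- dataset_schema(train, schema)
  metric_fn <- selection_metric(metric)
  outer_folds <- make_folds(train$label, outer_k, seed)

  rows <- list()
  for (ai in seq_along(registry)) {
    alg <- registry[[ai]]
    for (f in sort(unique(outer_folds))) {
      outer_train <- train[outer_folds != f, , drop = FALSE]
      tuned <- inner_tune(alg, outer_train, k = inner_k, metric = metric,
                          seed = derive_seed(seed, ai * 1000L + f), schema = schema)
      score <- tryCatch({
        fit <- alg$fit(outer_train, tuned$params, schema)
        pr <- alg$predict(fit, train[outer_folds == f, , drop = FALSE])
        metric_fn(train$label[outer_folds == f], pr)
      }, error = function(e) {
        warn(paste0("Candidate '", alg$name, "' failed on outer fold ", f,
                    " (", conditionMessage(e), "); scored -Inf."))
        -Inf
      })
      rows[[length(rows) + 1L]] <- tibble(
        algorithm = alg$name, fold = f, score = score,
        params = list(tuned$params)
      )
    }
  }
  scores <- dplyr::bind_rows(rows)
  summary <- scores |>
    group_by(.data$algorithm) |>
    summarise(mean_score = mean(.data$score), sd_score = stats::sd(.data$score),
              .groups = "drop")
  # preserve registry order for the tie rule
  summary <- summary[match(vapply(registry, `[[`, character(1), "name"),
                           summary$algorithm), ]
  winner <- summary$algorithm[[which.max(summary$mean_score)]]
  structure(
    list(
      scores = scores, summary = summary, winner = winner,
      metric = metric, outer_k = outer_k, inner_k = inner_k,
      seed = as.integer(seed)
    ),
    class = "pb_selection_report"
  )
}

#' @export
print.pb_selection_report <- function(x, ...) {
  cat("Nested cross-validation selection (", x$metric, ", outer ", x$outer_k,
      "-fold / inner ", x$inner_k, "-fold, seed ", x$seed, ")\n", sep = "")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat("Winner:", x$winner, "\n")
  invisible(x)
}

#' Serialize a selection report to JSON
#'
#' @param report A `pb_selection_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
selection_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "pb_selection_report"))
  payload <- list(
    metric = report$metric, outer_k = report$outer_k, inner_k = report$inner_k,
    seed = report$seed, winner = report$winner,
    summary = report$summary,
    scores = dplyr::mutate(report$scores, params = purrr::map(.data$params, identity))
  )
  txt <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                          digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
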