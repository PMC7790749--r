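#' Fit an AdaBoost pathogenicity classifier
#'
#' Discrete AdaBoost over depth-limited decision trees, the core model:
#' sample weights start uniform; each round fits a tree to the weighted
#' training data, computes its weighted misclassification error
#' \eqn{\epsilon_m}, receives the round weight
#' \eqn{\alpha_m = \frac{1}{2}\log((1-\epsilon_m)/\epsilon_m)}, and the
#' weights of misclassified variants are multiplied by
#' \eqn{e^{2\alpha_m}} (the standard exponential-loss update) and
#' renormalised. Boosting stops early when a round fits perfectly
#' (\eqn{\epsilon_m = 0}; the round is kept with its weight capped at
#' `alpha_cap`) or when the weak learner is no better than chance
#' (\eqn{\epsilon_m \ge 1/2}; the round is discarded). Missing feature
#' values are imputed by the training median, which is stored in the model
#' and reused at prediction time.
#'
#' @param data A labelled variant tibble (both classes present).
#' @param n_rounds Maximum number of boosting rounds (default 500).
#' @param tree_depth Maximum depth of each tree (default 3; 1 = stumps).
#' @param seed Integer seed recorded in the model metadata (tree fitting is
#'   deterministic; the seed documents provenance for pipelines).
#' @param schema Optional [feature_schema()]; defaults to the schema
#'   travelling with `data`.
#' @param alpha_cap Upper bound on any round weight, applied when a round has
#'   zero weighted error. Default `log(1e6)`.
#' @return An object of class `pb_boost`.
#' @export
#' @examples
#' ds <- gen_feature_table(feature_gen_spec(
#'   n_pathogenic = 40, n_benign = 40, n_features = 6, separation = 3, seed = 1
#' ))
#' fit <- fit_adaboost(ds, n_rounds = 10, tree_depth = 1, seed = 1)
#' head(predict(fit, ds))
fit_adaboost <- function(data, n_rounds = 500, tree_depth = 3, seed = 1,
                         schema = NULL, alpha_cap = log(1e6)) {
  if (n_rounds < 1 || tree_depth < 1) {
    pb_usage_error("`n_rounds` and `tree_depth` must be >= 1.")
  }
  schema <- dataset_schema(data, schema)
  y <- as.integer(data$label == "pathogenic")
  if (length(unique(y)) < 2L) {
    pb_usage_error("Training data must contain both pathogenic and benign variants.")
  }
  X <- feature_matrix(data, schema)
  imputation <- apply(X, 2, function(v) {
    m <- median(v, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
  X <- impute_matrix(X, imputation)
  if (all(apply(X, 2, function(v) length(unique(v)) == 1L))) {
    warn("All features are constant; the fitted trees will be trivial.")
  }

  n <- nrow(X)
  w <- rep(1 / n, n)
  ord <- presort_features(X)
  trees <- list()
  alphas <- numeric(0)
  errors <- numeric(0)
  stopping <- "n_rounds_reached"
  for (m in seq_len(n_rounds)) {
    tree <- fit_tree(X, y, w, tree_depth, ord)
    pred <- predict_tree(tree, X)
    miss <- pred != y
    eps <- sum(w[miss])
    if (eps >= 0.5 - 1e-12) {
      if (length(trees) == 0L) {
        pb_usage_error(paste0(
          "No weak learner better than chance on this data (weighted error ",
          format(eps), " in round 1); cannot fit a boosted model."
        ))
      }
      stopping <- "weak_learner_at_chance"
      break
    }
    if (eps < 1e-12) {
      trees[[length(trees) + 1L]] <- tree
      alphas <- c(alphas, alpha_cap)
      errors <- c(errors, 0)
      stopping <- "zero_training_error"
      break
    }
    alpha <- min(alpha_from_error(eps), alpha_cap)
    trees[[length(trees) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    errors <- c(errors, eps)
    w[miss] <- w[miss] * exp(2 * alpha)
    w <- w / sum(w)
  }

  structure(
    list(
      schema = schema,
      imputation = imputation,
      trees = trees,
      alphas = alphas,
      round_errors = errors,
      metadata = list(
        n_rounds_requested = as.integer(n_rounds),
        tree_depth = as.integer(tree_depth),
        seed = as.integer(seed),
        alpha_cap = alpha_cap,
        stopping = stopping,
        n_train = n,
        n_pathogenic = sum(y),
        n_benign = n - sum(y)
      )
    ),
    class = "pb_boost"
  )
}

# Round weight from weighted error: the closed form of the exponential-loss
# coordinate step. alpha_from_error(0.25) == 0.5 * log(3).
alpha_from_error <- function(eps) 0.5 * log((1 - eps) / eps)

impute_matrix <- function(X, imputation) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- imputation[[j]]
  }
  X
}

#' Probability of pathogenicity from a fitted ensemble
#'
#' Two transforms of the ensemble's weighted votes are available; both are
#' bounded in \[0, 1\], monotone in any single tree's vote (flipping one
#' tree from benign to pathogenic never decreases Pr), deterministic, and
#' agree on which side of 0.5 a variant falls.
#'
#' * `"logistic_margin"` (default): the exponential-loss probability
#'   \eqn{\Pr = \sigma(2F)} with the signed margin
#'   \eqn{F = \sum_m \alpha_m (2 h_m - 1)}, \eqn{h_m \in \{0, 1\}} the tree
#'   votes. Confidently classified variants receive probabilities near 0 or
#'   1, which is what the bimodal score distributions and three-way clinical
#'   thresholding assume.
#' * `"vote_share"`: the normalised weighted vote
#'   \eqn{\sum_m \alpha_m h_m / \sum_m \alpha_m}. Simple and exactly 1 under
#'   unanimity, but boosted trees disagree by construction (each round
#'   concentrates on the previous round's mistakes), so vote shares crowd
#'   into the middle of \[0, 1\] and rarely reach clinical confidence bands;
#'   retained for diagnostics.
#'
#' Missing features are imputed with the training medians stored in the
#' model.
#'
#' @param model A `pb_boost` model.
#' @param data A tibble (or data frame) with the model's feature columns;
#'   rows in any order.
#' @param transform `"logistic_margin"` (default) or `"vote_share"`.
#' @return A numeric vector of probabilities, one per row.
#' @export
predict_pr <- function(model, data,
                       transform = c("logistic_margin", "vote_share")) {
  stopifnot(inherits(model, "pb_boost"))
  transform <- match.arg(transform)
  X <- impute_matrix(feature_matrix(data, model$schema), model$imputation)
  votes <- vapply(model$trees, function(tr) predict_tree(tr, X), integer(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  weighted <- as.numeric(votes %*% model$alphas)
  if (transform == "vote_share") {
    weighted / sum(model$alphas)
  } else {
    stats::plogis(2 * (2 * weighted - sum(model$alphas)))
  }
}

#' @describeIn fit_adaboost Predict method: returns a tibble with `pr` (the
#'   probability of pathogenicity) and the three-way `clinical_call` at the
#'   supplied thresholds; `variant_id` is carried through when present.
#' @param object A `pb_boost` model.
#' @param new_data Data to predict on.
#' @param thresholds A [threshold_pair()].
#' @param ... Unused.
#' @export
predict.pb_boost <- function(object, new_data, thresholds = threshold_pair(), ...) {
  pr <- predict_pr(object, new_data)
  out <- tibble(pr = pr, clinical_call = classify_three_way(pr, thresholds))
  if ("variant_id" %in% names(new_data)) {
    out <- tibble(variant_id = new_data$variant_id, !!!out)
  }
  out
}

#' @export
print.pb_boost <- function(x, ...) {
  md <- x$metadata
  cat("AdaBoost pathogenicity classifier\n")
  cat(sprintf("  rounds: %d (requested %d, stop: %s)\n",
              length(x$trees), md$n_rounds_requested, md$stopping))
  cat(sprintf("  tree depth: %d   features: %d\n",
              md$tree_depth, nrow(x$schema)))
  cat(sprintf("  trained on %d variants (%d pathogenic, %d benign)\n",
              md$n_train, md$n_pathogenic, md$n_benign))
  invisible(x)
}

MODEL_FORMAT <- "pathboost-model-1"

#' Save / load a fitted model as versioned JSON
#'
#' The model file stores the schema, per-feature imputation constants, the
#' trees as nested split nodes (feature index, threshold, leaf votes), the
#' round weights and metadata at full double precision, so
#' `load_model(save_model(m, path))` yields bitwise-identical predictions.
#'
#' @param model A `pb_boost` model.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pb_boost"))
  payload <- list(
    format = MODEL_FORMAT,
    schema = list(
      feature = model$schema$feature,
      kind = model$schema$kind,
      missing_allowed = model$schema$missing_allowed
    ),
    imputation = as.list(model$imputation),
    alphas = model$alphas,
    trees = model$trees,
    round_errors = model$round_errors,
    metadata = model$metadata
  )
  # digits = I(17): full significant-digit precision so doubles round-trip
  # exactly and reloaded models predict bitwise-identically
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) pb_validation_error(paste0(
      "Cannot read model file '", path, "': ", conditionMessage(e)
    ))
  )
  required <- c("format", "schema", "imputation", "alphas", "trees", "metadata")
  if (!is.list(payload) || !all(required %in% names(payload))) {
    pb_validation_error("Model file is truncated or not a pathboost model.")
  }
  if (!identical(payload$format, MODEL_FORMAT)) {
    pb_validation_error(paste0(
      "Unsupported model format '", payload$format, "' (expected ", MODEL_FORMAT, ")."
    ))
  }
  schema <- feature_schema(
    unlist(payload$schema$feature),
    kind = unlist(payload$schema$kind),
    missing_allowed = unlist(payload$schema$missing_allowed)
  )
  imputation <- unlist(payload$imputation)
  if (!identical(names(imputation), schema$feature)) {
    pb_validation_error("Model imputation values do not match the schema features.")
  }
  alphas <- as.numeric(unlist(payload$alphas))
  trees <- lapply(payload$trees, deserialize_tree)
  if (length(trees) < 1L || length(trees) != length(alphas) ||
      any(!is.finite(alphas)) || any(alphas < 0)) {
    pb_validation_error("Model rounds are invalid: need >= 1 tree with finite non-negative weights.")
  }
  for (tr in trees) check_tree(tr, nrow(schema))
  structure(
    list(
      schema = schema,
      imputation = imputation,
      trees = trees,
      alphas = alphas,
      round_errors = as.numeric(unlist(payload$round_errors)),
      metadata = lapply(payload$metadata, function(x) if (is.list(x)) unlist(x) else x)
    ),
    class = "pb_boost"
  )
}
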