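#' Feature schemas
#'
#' A feature schema fixes the ordered list of functional-annotation features
#' a classifier consumes: one row per feature with its name, kind and whether
#' missing values are allowed. Feature order is part of a fitted model and is
#' persisted with it.
#'
#' Kinds:
#' * `unit_score` -- a bounded score in \[0, 1\] (e.g. a per-variant
#'   deleteriousness score from an upstream tool);
#' * `continuous` -- an unbounded numeric annotation (e.g. a conservation
#'   statistic);
#' * `categorical` -- an integer-coded category.
#'
#' @param feature Character vector of unique feature names.
#' @param kind Character vector (recycled) in
#'   `c("unit_score", "continuous", "categorical")`.
#' @param missing_allowed Logical vector (recycled).
#' @return A tibble of class `pb_schema` with columns `feature`, `kind`,
#'   `missing_allowed`.
#' @export
#' @examples
#' feature_schema(c("phylop", "cadd_norm"), kind = c("continuous", "unit_score"))
feature_schema <- function(feature, kind = "continuous", missing_allowed = TRUE) {
  if (anyDuplicated(feature)) {
    pb_schema_error("Feature names must be unique.")
  }
  ok <- kind %in% c("unit_score", "continuous", "categorical")
  if (!all(ok)) {
    pb_schema_error(paste0("Unknown feature kind: ", paste(unique(kind[!ok]), collapse = ", ")))
  }
  out <- tibble(
    feature = as.character(feature),
    kind = rep_len(kind, length(feature)),
    missing_allowed = rep_len(missing_allowed, length(feature))
  )
  class(out) <- c("pb_schema", class(out))
  out
}

#' Default 76-feature annotation schema
#'
#' Placeholder schema with the width used throughout: 76 features, half
#' bounded unit scores (`score_01` ... ) and half unbounded continuous
#' annotations (`anno_01` ...). Real analyses substitute their own schema;
#' everything downstream only depends on names, kinds and order.
#'
#' @param n_features Total number of features (default 76).
#' @param unit_fraction Fraction of features that are bounded unit scores.
#' @return A `pb_schema` tibble.
#' @export
default_feature_schema <- function(n_features = 76, unit_fraction = 0.5) {
  if (n_features < 1) pb_usage_error("`n_features` must be >= 1.")
  n_unit <- round(n_features * unit_fraction)
  nm <- c(
    sprintf("score_%02d", seq_len(n_unit)),
    sprintf("anno_%02d", seq_len(n_features - n_unit))
  )
  feature_schema(nm, kind = rep(c("unit_score", "continuous"), c(n_unit, n_features - n_unit)))
}

# Columns every labelled variant table carries ahead of its features.
META_COLS <- c("variant_id", "gene", "chrom", "pos", "ref", "alt", "label", "maf")

schema_features <- function(schema) schema$feature

# Recover the schema travelling with a dataset, or infer one from the
# non-meta numeric columns (unit_score iff all observed values lie in [0,1]).
dataset_schema <- function(data, schema = NULL) {
  if (!is.null(schema)) return(schema)
  sc <- attr(data, "pb_schema", exact = TRUE)
  if (!is.null(sc)) return(sc)
  feats <- setdiff(names(data), META_COLS)
  feats <- feats[vapply(data[feats], is.numeric, logical(1))]
  if (length(feats) == 0L) pb_schema_error("No feature columns found to infer a schema from.")
  kinds <- vapply(feats, function(f) {
    v <- data[[f]]
    v <- v[!is.na(v)]
    if (length(v) && all(v >= 0 & v <= 1)) "unit_score" else "continuous"
  }, character(1))
  feature_schema(feats, kind = kinds)
}

set_schema <- function(data, schema) {
  attr(data, "pb_schema") <- schema
  data
}

# Extract the n x p numeric feature matrix in schema order.
feature_matrix <- function(data, schema) {
  missing_cols <- setdiff(schema_features(schema), names(data))
  if (length(missing_cols)) {
    pb_schema_error(paste0("Missing feature column: ", missing_cols[[1]]))
  }
  m <- as.matrix(as.data.frame(lapply(data[schema_features(schema)], as.numeric)))
  colnames(m) <- schema_features(schema)
  m
}
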