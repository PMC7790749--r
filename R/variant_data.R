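#' Read a labelled variant feature table
#'
#' Canonical input: a UTF-8 tab-separated table with a header naming at least
#' `variant_id`, `gene`, `chrom`, `pos`, `ref`, `alt`, `label`, `maf` and every
#' feature in `schema`, one row per unique rare missense variant. `"NA"` and
#' empty cells are missing; numeric cells that fail to parse also become
#' missing. Labels must be `"pathogenic"` or `"benign"` (conflict resolution
#' from raw clinical assertions happens upstream via [curate_label()]).
#'
#' @param path Path to the TSV file.
#' @param schema A [feature_schema()]. When `NULL` (default) every non-meta
#'   column is read as a feature and the schema is inferred (unit score iff
#'   all observed values lie in \[0, 1\]).
#' @return A validated tibble (one row per variant, features in schema order)
#'   carrying the schema as an attribute.
#' @seealso [read_feature_vcf()] for the read-only VCF dialect.
#' @export
read_feature_table <- function(path, schema = NULL) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("NA", ""), progress = FALSE
  )
  feats <- if (is.null(schema)) setdiff(names(raw), META_COLS) else schema_features(schema)
  mandatory <- c(META_COLS, feats)
  absent <- setdiff(mandatory, names(raw))
  if (length(absent)) {
    pb_schema_error(paste0("Missing mandatory column: ", absent[[1]]))
  }
  out <- raw[mandatory]
  num_cols <- c("pos", "maf", feats)
  out[num_cols] <- lapply(out[num_cols], function(x) suppressWarnings(as.numeric(x)))
  out$pos <- as.integer(out$pos)
  if (is.null(schema)) schema <- dataset_schema(out)
  validate_variant_data(out, schema)
}

#' Read variants from a VCF with INFO-encoded features (read-only dialect)
#'
#' Minimal VCF (v4.2) support: one biallelic record per variant; the feature
#' values, MAF and label are taken from INFO keys named in `info_map`, a named
#' list/vector mapping column names (`maf`, `label`, `gene`, and each schema
#' feature) to INFO keys. Multiallelic records are rejected.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param schema A [feature_schema()].
#' @param info_map Named character vector: names are table columns, values are
#'   INFO keys. May also be a path to a YAML file holding that mapping.
#' @return A validated tibble as from [read_feature_table()].
#' @export
read_feature_vcf <- function(path, schema, info_map) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    pb_usage_error("VCF input requires the 'vcfR' package.")
  }
  if (is.character(info_map) && length(info_map) == 1L && file.exists(info_map)) {
    info_map <- unlist(yaml::read_yaml(info_map))
  }
  info_map <- unlist(info_map)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    pb_validation_error("Multiallelic VCF records are not supported; split them first.")
  }
  out <- tibble(
    variant_id = paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = "-"),
    gene = NA_character_, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, label = NA_character_, maf = NA_real_
  )
  for (col in names(info_map)) {
    vals <- vcfR::extract.info(v, element = info_map[[col]])
    out[[col]] <- if (col %in% c("gene", "label")) as.character(vals) else suppressWarnings(as.numeric(vals))
  }
  validate_variant_data(out[c(META_COLS, intersect(schema_features(schema), names(out)))], schema)
}

#' Validate a labelled variant table against its schema
#'
#' Enforces the dataset invariants: unique `variant_id`, `pos >= 1`,
#' `ref != alt`, `maf` in \[0, 1\] or missing, labels restricted to
#' `pathogenic`/`benign`, and unit-score features inside \[0, 1\] where
#' observed.
#'
#' @param data A variant tibble.
#' @param schema A [feature_schema()].
#' @return `data`, invisibly validated, with the schema attached.
#' @export
validate_variant_data <- function(data, schema = dataset_schema(data)) {
  dup <- unique(data$variant_id[duplicated(data$variant_id)])
  if (length(dup)) {
    pb_validation_error(paste0(
      "Duplicate variant_id: ", paste(head(dup, 5), collapse = ", ")
    ))
  }
  bad_label <- which(!data$label %in% c("pathogenic", "benign"))
  if (length(bad_label)) {
    pb_validation_error(paste0(
      "Label outside {pathogenic, benign} at row ", bad_label[[1]],
      " ('", data$label[bad_label[[1]]], "')"
    ))
  }
  if (any(!is.na(data$pos) & data$pos < 1)) pb_validation_error("`pos` must be >= 1.")
  if (any(data$ref == data$alt, na.rm = TRUE)) pb_validation_error("`ref` must differ from `alt`.")
  if (any(!is.na(data$maf) & (data$maf < 0 | data$maf > 1))) {
    pb_validation_error("`maf` must lie in [0, 1] or be missing.")
  }
  unit <- schema$feature[schema$kind == "unit_score"]
  for (f in intersect(unit, names(data))) {
    v <- data[[f]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      pb_validation_error(paste0("Unit-score feature '", f, "' has values outside [0, 1]."))
    }
  }
  set_schema(data, schema)
}

#' Keep rare variants
#'
#' Retains variants with population minor allele frequency strictly below
#' `maf_cutoff`, and variants absent from the reference population (missing
#' MAF): a large fraction of disease-cohort variants are unobserved in
#' reference controls and are treated as rare. Row order is preserved;
#' the operation is idempotent.
#'
#' @param data A variant tibble with a `maf` column.
#' @param maf_cutoff Rarity cutoff as a fraction; default 0.001 (0.1%).
#'   Use 0.0001 for an ultrarare (<0.01%) filter.
#' @return The filtered tibble.
#' @export
filter_rare <- function(data, maf_cutoff = 0.001) {
  if (!is.numeric(maf_cutoff) || length(maf_cutoff) != 1L || is.na(maf_cutoff) ||
      maf_cutoff <= 0 || maf_cutoff > 1) {
    pb_usage_error("`maf_cutoff` must be a single fraction in (0, 1].")
  }
  sc <- attr(data, "pb_schema", exact = TRUE)
  out <- dplyr::filter(data, is.na(.data$maf) | .data$maf < maf_cutoff)
  if (!is.null(sc)) out <- set_schema(out, sc)
  out
}

#' Resolve clinical assertions into a training label
#'
#' Applies the conflict-exclusion rule used to assemble gold-standard sets:
#' a variant is `pathogenic` only if every assertion is P or LP, `benign`
#' only if every assertion is B or LB, and `excluded` otherwise -- any
#' mixture of opposing classes, or any VUS assertion, is a conflict.
#' The result depends only on the set of assertions, not their order or
#' multiplicity.
#'
#' @param assertions A character vector (one assertion set) or a list of
#'   character vectors, with tokens in `c("P", "LP", "B", "LB", "VUS")`.
#' @return A character vector in `c("pathogenic", "benign", "excluded")`,
#'   one element per assertion set.
#' @export
#' @examples
#' curate_label(c("P", "LP"))          # "pathogenic"
#' curate_label(c("LP", "VUS"))        # "excluded"
#' curate_label(list(c("B", "LB"), "VUS"))
curate_label <- function(assertions) {
  if (!is.list(assertions)) assertions <- list(assertions)
  vapply(assertions, function(a) {
    if (length(a) == 0L) pb_usage_error("An assertion set must be non-empty.")
    bad <- setdiff(a, c("P", "LP", "B", "LB", "VUS"))
    if (length(bad)) {
      pb_validation_error(paste0("Unknown clinical assertion token: ", bad[[1]]))
    }
    if (all(a %in% c("P", "LP"))) return("pathogenic")
    if (all(a %in% c("B", "LB"))) return("benign")
    "excluded"
  }, character(1))
}

#' Stratified train/test split
#'
#' Randomly partitions a labelled dataset into training and holdout sets,
#' stratified by label so each class's training share deviates from
#' `train_fraction` by at most one variant (per-class ceiling allocation:
#' the fractional remainder goes to training). Deterministic for a fixed
#' seed.
#'
#' @param data A labelled variant tibble.
#' @param train_fraction Fraction allocated to training; default 2/3.
#' @param seed Integer seed.
#' @return A list with elements `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(data, train_fraction = 2 / 3, seed = 1) {
  if (!is_fraction(train_fraction)) {
    pb_usage_error("`train_fraction` must lie strictly between 0 and 1.")
  }
  counts <- table(data$label)
  if (any(counts < 2)) {
    pb_abort(paste0(
      "Each class needs at least 2 rows to stratify; got ",
      paste(names(counts), counts, sep = "=", collapse = ", ")
    ), "pb_stratification_error")
  }
  sc <- attr(data, "pb_schema", exact = TRUE)
  idx_train <- pb_with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(data)), data$label), function(idx) {
      n_tr <- min(max(ceiling(train_fraction * length(idx)), 1L), length(idx) - 1L)
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  idx_train <- sort(idx_train)
  train <- data[idx_train, , drop = FALSE]
  test <- data[setdiff(seq_len(nrow(data)), idx_train), , drop = FALSE]
  if (!is.null(sc)) {
    train <- set_schema(train, sc)
    test <- set_schema(test, sc)
  }
  list(train = train, test = test)
}
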