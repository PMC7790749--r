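# Shared fixtures and independent oracles, built in code.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# Small labelled dataset via the package generator.
tiny_dataset <- function(n_path = 30, n_ben = 30, p = 6, sep = 3, seed = 1,
                         missing_rate = 0) {
  gen_feature_table(feature_gen_spec(
    n_pathogenic = n_path, n_benign = n_ben, n_features = p,
    separation = sep, missing_rate = missing_rate, seed = seed
  ))
}

# One-feature dataset where the classes are separated by a gap around 0.
separable_1d <- function(n_per_class = 10) {
  x <- c(seq(-2, -0.5, length.out = n_per_class),
         seq(0.5, 2, length.out = n_per_class))
  tibble(
    variant_id = sprintf("1-%d-A-C", seq_along(x)),
    gene = "G1", chrom = "1", pos = seq_along(x), ref = "A", alt = "C",
    label = rep(c("benign", "pathogenic"), each = n_per_class),
    maf = NA_real_, x1 = x
  )
}

# Hand-assembled ensemble whose trees are bare leaves, for exact
# weighted-vote arithmetic.
manual_boost_model <- function(alphas, votes) {
  stopifnot(length(alphas) == length(votes))
  structure(
    list(
      schema = feature_schema("x1", kind = "continuous"),
      imputation = c(x1 = 0),
      trees = lapply(votes, pathboost:::tree_leaf),
      alphas = alphas,
      round_errors = rep(0.3, length(alphas)),
      metadata = list(n_rounds_requested = length(alphas), tree_depth = 1L,
                      seed = 1L, alpha_cap = log(1e6), stopping = "n_rounds_reached",
                      n_train = 2L, n_pathogenic = 1L, n_benign = 1L)
    ),
    class = "pb_boost"
  )
}

# Brute-force ROC-AUC: count concordant pathogenic/benign pairs, ties one half.
brute_roc <- function(labels, scores) {
  sp <- scores[labels == "pathogenic"]
  sb <- scores[labels == "benign"]
  tot <- 0
  for (a in sp) for (b in sb) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sb))
}

# Exhaustive paired swap test, written independently of the package path.
brute_swap_test <- function(metric_fn, labels, a, b) {
  n <- length(labels)
  obs <- metric_fn(labels, a) - metric_fn(labels, b)
  diffs <- numeric(2^n)
  for (i in seq_len(2^n)) {
    swap <- as.logical(bitwAnd(rep(i - 1L, n), bitwShiftL(1L, seq_len(n) - 1L)))
    aa <- ifelse(swap, b, a)
    bb <- ifelse(swap, a, b)
    diffs[i] <- metric_fn(labels, aa) - metric_fn(labels, bb)
  }
  mean(abs(diffs) >= abs(obs) - 1e-12)
}

# Two-group log-rank chi-square via the hypergeometric terms, by hand.
brute_logrank <- function(age, event, group) {
  g1 <- unique(group)[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(age[event == 1]))) {
    at_risk <- age >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & age == t)
    d1 <- sum(event == 1 & age == t & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# A TSV feature table written from a tibble, for reader tests.
write_feature_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, na = "NA")
  path
}
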