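# Seeded generators for the three input kinds: labelled variant feature
# tables, per-gene case/control carrier counts, and per-patient survival
# records. Every generator is a pure function of (spec, seed): identical
# specs give identical tables.

#' Specification for a synthetic labelled variant feature table
#'
#' Defaults mirror a single-condition curated training set: 356 pathogenic
#' and 302 benign rare missense variants across 16 disease genes with 76
#' annotation features, and 45% of variants unobserved in the population
#' reference (missing MAF).
#'
#' `separation` is the aggregate class-separation effect size: the
#' per-feature mean shift between classes is `separation / sqrt(n_features)`
#' (on the logit scale for bounded unit scores, in standard-deviation units
#' for continuous annotations), so the overall difficulty of the learning
#' problem is governed by `separation` independent of schema width.
#' `separation = 0` gives exchangeable classes (a null dataset).
#'
#' @param n_pathogenic,n_benign Class sizes.
#' @param n_features Number of annotation features (default 76).
#' @param separation Aggregate effect size `d >= 0`.
#' @param unit_fraction Fraction of features generated as Beta-distributed
#'   unit scores; the rest are Gaussian continuous annotations.
#' @param missing_rate Fraction of feature cells set missing, uniformly.
#' @param n_genes Number of genes, assigned round-robin.
#' @param maf_absent_prob Probability a variant has no reference-population
#'   MAF (default 0.45); otherwise the MAF is log-uniform below `maf_cutoff`.
#' @param maf_cutoff Rarity cutoff bounding generated MAFs (default 0.001).
#' @param seed Integer seed.
#' @return A list of class `pb_feature_gen_spec`.
#' @export
feature_gen_spec <- function(n_pathogenic = 356, n_benign = 302,
                             n_features = 76, separation = 2,
                             unit_fraction = 0.5, missing_rate = 0.05,
                             n_genes = 16, maf_absent_prob = 0.45,
                             maf_cutoff = 0.001, seed = 1) {
  if (separation < 0) pb_domain_error("`separation` must be >= 0.")
  for (f in c(unit_fraction, missing_rate, maf_absent_prob)) {
    if (f < 0 || f > 1) pb_domain_error("Fractions in a generator spec must lie in [0, 1].")
  }
  if (n_pathogenic < 1 || n_benign < 1 || n_features < 1 || n_genes < 1) {
    pb_domain_error("Counts in a generator spec must be >= 1.")
  }
  structure(as.list(environment()), class = "pb_feature_gen_spec")
}

#' Generate a labelled variant feature table
#'
#' Unit-score features are Beta-distributed with class means separated on the
#' logit scale; continuous features are unit-variance Gaussians with the
#' pathogenic class shifted. Missing cells are introduced uniformly at the
#' spec's rate, genes are assigned round-robin, and MAFs follow the spec's
#' point-mass-at-absent / log-uniform-below-cutoff model. The output passes
#' [validate_variant_data()] unchanged.
#'
#' @param spec A [feature_gen_spec()].
#' @return A labelled variant tibble carrying its schema.
#' @export
#' @examples
#' ds <- gen_feature_table(feature_gen_spec(
#'   n_pathogenic = 30, n_benign = 30, n_features = 8, separation = 2, seed = 7
#' ))
#' dplyr::count(ds, label)
gen_feature_table <- function(spec) {
  stopifnot(inherits(spec, "pb_feature_gen_spec"))
  schema <- default_feature_schema(spec$n_features, spec$unit_fraction)
  n <- spec$n_pathogenic + spec$n_benign
  y <- rep(c(1L, 0L), c(spec$n_pathogenic, spec$n_benign))
  shift <- spec$separation / sqrt(spec$n_features)
  kappa <- 8  # Beta concentration: keeps unit scores away from degenerate 0/1

  pb_with_seed(spec$seed, {
    feats <- lapply(seq_len(nrow(schema)), function(j) {
      if (schema$kind[j] == "unit_score") {
        mu <- stats::plogis(ifelse(y == 1L, shift / 2, -shift / 2))
        v <- rbeta(n, mu * kappa, (1 - mu) * kappa)
        # guard exact endpoints so unit-score validation is strict
        pmin(pmax(v, 1e-9), 1 - 1e-9)
      } else {
        rnorm(n, mean = ifelse(y == 1L, shift, 0), sd = 1)
      }
    })
    names(feats) <- schema$feature
    feat_tbl <- as_tibble(feats)
    if (spec$missing_rate > 0) {
      mask <- matrix(runif(n * nrow(schema)) < spec$missing_rate, nrow = n)
      for (j in seq_len(ncol(feat_tbl))) {
        feat_tbl[[j]][mask[, j]] <- NA_real_
      }
    }
    maf <- ifelse(
      runif(n) < spec$maf_absent_prob,
      NA_real_,
      10^runif(n, log10(1e-6), log10(spec$maf_cutoff)) * (1 - 1e-9)
    )
    gene <- sprintf("GENE%02d", (seq_len(n) - 1L) %% spec$n_genes + 1L)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    pos <- seq_len(n) * 100L
    chrom <- as.character((seq_len(n) - 1L) %% spec$n_genes + 1L)
    out <- tibble(
      variant_id = paste(chrom, pos, ref, alt, sep = "-"),
      gene = gene, chrom = chrom, pos = pos, ref = unname(ref), alt = alt,
      label = ifelse(y == 1L, "pathogenic", "benign"), maf = maf
    )
    validate_variant_data(dplyr::bind_cols(out, feat_tbl), schema)
  })
}

#' Specification for synthetic per-gene carrier counts
#'
#' One row of `genes` per (gene, stratum): reference-cohort carrier frequency
#' and the true case/control odds ratio for that stratum. Defaults emulate a
#' sarcomere-gene case-control comparison: 6327 cases vs 138,632 reference
#' samples, eight genes, and three strata per gene -- all rare variants
#' (OR 5), variants predicted disease-causing (OR 15, enriched) and variants
#' predicted benign (OR 1, depleted to baseline).
#'
#' @param genes A tibble with columns `gene`, `stratum`, `true_or`,
#'   `carrier_freq`.
#' @param n_cases,n_controls Cohort sizes.
#' @param seed Integer seed.
#' @return A list of class `pb_cohort_gen_spec`.
#' @export
cohort_gen_spec <- function(genes = NULL, n_cases = 6327, n_controls = 138632,
                            seed = 1) {
  if (is.null(genes)) {
    gene_names <- c("MYH7", "MYBPC3", "TNNT2", "TNNI3", "TPM1", "ACTC1", "MYL2", "MYL3")
    genes <- tidyr::expand_grid(
      gene = gene_names,
      tibble(
        stratum = c("all-rare", "predicted-disease-causing", "predicted-benign"),
        true_or = c(5, 15, 1)
      )
    )
    genes$carrier_freq <- 0.002
  }
  genes <- as_tibble(genes)
  stopifnot(all(c("gene", "stratum", "true_or", "carrier_freq") %in% names(genes)))
  if (any(genes$true_or <= 0)) pb_domain_error("True odds ratios must be > 0.")
  if (any(genes$carrier_freq <= 0 | genes$carrier_freq >= 1)) {
    pb_domain_error("Carrier frequencies must lie in (0, 1).")
  }
  if (n_cases < 1 || n_controls < 1) pb_domain_error("Cohort sizes must be positive.")
  structure(list(genes = genes, n_cases = n_cases, n_controls = n_controls,
                 seed = seed), class = "pb_cohort_gen_spec")
}

#' Generate per-gene case/control carrier-count tables
#'
#' Reference carriers are Binomial(`n_controls`, f); case carriers are
#' Binomial(`n_cases`, f') with f' chosen so the true carrier odds ratio
#' equals the stratum's `true_or` (odds are multiplied by the OR).
#'
#' @param spec A [cohort_gen_spec()].
#' @return A tibble with columns `gene`, `stratum`, `true_or`, `a` (case
#'   carriers), `b` (case non-carriers), `c` (reference carriers), `d`
#'   (reference non-carriers).
#' @export
gen_cohort_counts <- function(spec) {
  stopifnot(inherits(spec, "pb_cohort_gen_spec"))
  g <- spec$genes
  odds <- g$carrier_freq / (1 - g$carrier_freq)
  f_case <- g$true_or * odds / (1 + g$true_or * odds)
  if (any(f_case >= 1)) pb_domain_error("Implied case carrier frequency reaches 1.")
  pb_with_seed(spec$seed, {
    a <- rbinom(nrow(g), spec$n_cases, f_case)
    c_ <- rbinom(nrow(g), spec$n_controls, g$carrier_freq)
    tibble(
      gene = g$gene, stratum = g$stratum, true_or = g$true_or,
      a = a, b = spec$n_cases - a, c = c_, d = spec$n_controls - c_
    )
  })
}

#' Specification for a synthetic survival cohort
#'
#' Exponential event ages with group-specific hazard multipliers and
#' independent uniform censoring ages. Defaults emulate outcome
#' stratification of a cardiomyopathy registry by predicted genotype class:
#' a genotype-negative reference group (hazard ratio 1), carriers of
#' predicted-benign variants (HR 1.12) and carriers of predicted
#' disease-causing variants (HR 1.9), 2000 patients each; the baseline rate
#' is set so the reference group reaches 33% cumulative incidence of the
#' composite endpoint by age 60.
#'
#' @param groups Tibble with columns `group`, `n`, `hr` (hazard ratio vs the
#'   baseline rate; the first row is conventionally the reference).
#' @param baseline_rate Baseline exponential event rate per year.
#' @param censor_lower,censor_upper Uniform censoring-age bounds (years).
#' @param seed Integer seed.
#' @return A list of class `pb_survival_gen_spec`.
#' @export
survival_gen_spec <- function(groups = NULL,
                              baseline_rate = -log(1 - 0.33) / 60,
                              censor_lower = 40, censor_upper = 80,
                              seed = 1) {
  if (is.null(groups)) {
    groups <- tibble(
      group = c("genotype-negative", "predicted-benign", "predicted-disease-causing"),
      n = 2000L,
      hr = c(1, 1.12, 1.9)
    )
  }
  groups <- as_tibble(groups)
  stopifnot(all(c("group", "n", "hr") %in% names(groups)))
  if (any(groups$hr <= 0) || baseline_rate <= 0) {
    pb_domain_error("Hazard ratios and the baseline rate must be > 0.")
  }
  if (censor_lower < 0 || censor_upper <= censor_lower) {
    pb_domain_error("Censoring bounds must satisfy 0 <= lower < upper.")
  }
  structure(list(groups = groups, baseline_rate = baseline_rate,
                 censor_lower = censor_lower, censor_upper = censor_upper,
                 seed = seed), class = "pb_survival_gen_spec")
}

#' Generate per-patient survival records
#'
#' @param spec A [survival_gen_spec()].
#' @return A tibble with columns `patient_id`, `age` (years at first
#'   composite event or censoring), `event` (0/1) and `group`.
#' @export
gen_survival_cohort <- function(spec) {
  stopifnot(inherits(spec, "pb_survival_gen_spec"))
  g <- spec$groups
  pb_with_seed(spec$seed, {
    recs <- purrr::pmap(g, function(group, n, hr, ...) {
      t_event <- rexp(n, rate = spec$baseline_rate * hr)
      t_cens <- runif(n, spec$censor_lower, spec$censor_upper)
      tibble(
        age = pmax(pmin(t_event, t_cens), 1e-6),
        event = as.integer(t_event <= t_cens),
        group = group
      )
    })
    out <- dplyr::bind_rows(recs)
    tibble(patient_id = sprintf("PT%05d", seq_len(nrow(out))), out)
  })
}
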