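#' Clinical classification thresholds
#'
#' The double threshold used for clinically actionable calls: a variant is
#' called disease-causing when its probability of pathogenicity is at least
#' `upper` (default 0.9) and benign when at most `lower` (default 0.1);
#' everything in between is clinically indeterminate, mirroring the >=90%
#' certainty ACMG/AMP-style likely-pathogenic / likely-benign levels.
#'
#' @param upper,lower Probabilities with `0 < lower < upper < 1`.
#' @return A list of class `pb_thresholds`.
#' @export
threshold_pair <- function(upper = 0.9, lower = 0.1) {
  if (!is.numeric(upper) || !is.numeric(lower) ||
      !(lower > 0 && lower < upper && upper < 1)) {
    pb_usage_error("Thresholds must satisfy 0 < lower < upper < 1.")
  }
  structure(list(upper = upper, lower = lower), class = "pb_thresholds")
}

#' Three-way clinical call from a probability of pathogenicity
#'
#' Boundaries are inclusive toward the confident calls: `pr >= upper` is
#' disease-causing, `pr <= lower` is benign, otherwise indeterminate.
#'
#' @param pr Numeric vector of probabilities in \[0, 1\].
#' @param thresholds A [threshold_pair()].
#' @return A factor with levels `disease-causing`, `indeterminate`, `benign`.
#' @export
#' @examples
#' classify_three_way(c(0.95, 0.9, 0.5, 0.1, 0.02))
classify_three_way <- function(pr, thresholds = threshold_pair()) {
  if (any(is.na(pr)) || any(pr < 0 | pr > 1)) {
    pb_domain_error("Probabilities must lie in [0, 1].")
  }
  factor(
    ifelse(pr >= thresholds$upper, "disease-causing",
           ifelse(pr <= thresholds$lower, "benign", "indeterminate")),
    levels = c("disease-causing", "indeterminate", "benign")
  )
}

#' Thresholded confusion summary
#'
#' All quantities derived from one set of labels, probabilities and a
#' threshold pair. High-confidence calls are those outside the indeterminate
#' band; TPR/TNR keep the full class sizes in their denominators (an
#' indeterminate pathogenic variant counts against sensitivity), while
#' PPV/NPV condition on the high-confidence calls. Undefined rates (zero
#' denominators) are `NA`, never silently zero. By construction
#' `overall_accuracy = proportion_high_confidence * accuracy_high_confidence`
#' and `proportion_indeterminate = 1 - proportion_high_confidence`.
#'
#' @param labels Character/factor vector in `c("pathogenic", "benign")`.
#' @param pr Aligned numeric vector of probabilities of pathogenicity.
#' @param thresholds A [threshold_pair()].
#' @return A one-row tibble with counts (`tp`, `fp`, `tn`, `fn`,
#'   `indeterminate_pathogenic`, `indeterminate_benign`), rates (`tpr`,
#'   `tnr`, `ppv`, `npv`) and the summary proportions.
#' @export
confusion_summary <- function(labels, pr, thresholds = threshold_pair()) {
  if (length(labels) != length(pr)) {
    pb_usage_error("`labels` and `pr` must have the same length.")
  }
  if (length(labels) < 1L) pb_usage_error("Need at least one variant.")
  call <- classify_three_way(pr, thresholds)
  is_path <- labels == "pathogenic"
  tp <- sum(is_path & call == "disease-causing")
  fn <- sum(is_path & call == "benign")
  ip <- sum(is_path & call == "indeterminate")
  tn <- sum(!is_path & call == "benign")
  fp <- sum(!is_path & call == "disease-causing")
  ib <- sum(!is_path & call == "indeterminate")
  n <- length(labels)
  hc <- tp + fp + tn + fn
  tibble(
    n = n, n_pathogenic = sum(is_path), n_benign = n - sum(is_path),
    tp = tp, fp = fp, tn = tn, fn = fn,
    indeterminate_pathogenic = ip, indeterminate_benign = ib,
    tpr = safe_div(tp, sum(is_path)),
    tnr = safe_div(tn, n - sum(is_path)),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    overall_accuracy = (tp + tn) / n,
    proportion_high_confidence = hc / n,
    accuracy_high_confidence = safe_div(tp + tn, hc),
    proportion_indeterminate = 1 - hc / n
  )
}

#' Pipe-friendly clinical summary of a predictions table
#'
#' Data-frame-first wrapper around [confusion_summary()].
#'
#' @param data A tibble of predictions.
#' @param truth,pr Columns holding the true label and the probability of
#'   pathogenicity (unquoted; defaults `label` and `pr`).
#' @param thresholds A [threshold_pair()].
#' @return A one-row tibble, as [confusion_summary()].
#' @export
#' @examples
#' tibble::tibble(label = c("pathogenic", "benign"), pr = c(0.97, 0.03)) |>
#'   clinical_summary()
clinical_summary <- function(data, truth = label, pr = pr,
                             thresholds = threshold_pair()) {
  confusion_summary(
    dplyr::pull(data, {{ truth }}), dplyr::pull(data, {{ pr }}), thresholds
  )
}

#' Area under the ROC curve
#'
#' Computed in the Mann-Whitney form: the probability that a random
#' pathogenic variant scores above a random benign one, counting ties as
#' one half.
#'
#' @param labels Vector in `c("pathogenic", "benign")`.
#' @param scores Aligned numeric scores (higher = more pathogenic).
#' @return AUC in \[0, 1\]; `NA` when either class is absent.
#' @export
roc_auc <- function(labels, scores) {
  pos <- labels == "pathogenic"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    warn("ROC-AUC undefined: one class is absent.")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' The step-function (average-precision) form
#' \eqn{\sum_k (R_k - R_{k-1}) P_k} over descending unique score thresholds,
#' with tied scores processed as one block; no trapezoidal interpolation.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in \[0, 1\]; `NA` when no pathogenic variant is present.
#' @export
pr_auc <- function(labels, scores) {
  pos <- labels == "pathogenic"
  P <- sum(pos)
  if (P == 0L) {
    warn("PR-AUC undefined: no pathogenic variants.")
    return(NA_real_)
  }
  o <- order(scores, decreasing = TRUE)
  y <- as.integer(pos[o])
  s <- scores[o]
  block_end <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[block_end]
  k <- block_end  # predictions made at or above each threshold
  recall <- tp / P
  precision <- tp / k
  sum(diff(c(0, recall)) * precision)
}

#' Brier score
#'
#' Mean squared difference between the predicted probability of
#' pathogenicity and the 0/1 truth; lower is better (0 = perfect).
#'
#' @inheritParams roc_auc
#' @param pr Probabilities in \[0, 1\].
#' @return The Brier score in \[0, 1\].
#' @export
brier <- function(labels, pr) {
  if (any(pr < 0 | pr > 1)) pb_domain_error("Probabilities must lie in [0, 1].")
  mean((pr - as.integer(labels == "pathogenic"))^2)
}

#' Paired permutation test comparing two classifiers
#'
#' Tests whether a metric differs between two probability vectors evaluated
#' on the same variants, by randomly swapping the pair
#' `(pr_a[i], pr_b[i])` per variant under the null of exchangeability. When
#' `n <= 12` all `2^n` swap patterns are enumerated (an exact p-value);
#' otherwise `n_perm` Monte-Carlo swaps are drawn with the add-one
#' correction `p = (b + 1) / (n_perm + 1)`. Two-sided.
#'
#' @param metric Metric name: `"pr_auc"`, `"roc_auc"`, `"neg_brier"`.
#' @param labels True labels.
#' @param pr_a,pr_b Aligned probability/score vectors for the two
#'   classifiers.
#' @param n_perm Monte-Carlo permutations (default 2000).
#' @param seed Integer seed.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default enumerates iff `n <= 12`.
#' @return A one-row tibble: `metric`, `estimate` (observed metric
#'   difference a - b), `p.value`, `method`, `n_swaps`.
#' @export
paired_permutation_test <- function(metric, labels, pr_a, pr_b,
                                    n_perm = 2000, seed = 1, exact = NULL) {
  if (length(labels) != length(pr_a) || length(labels) != length(pr_b)) {
    pb_usage_error("`labels`, `pr_a` and `pr_b` must be aligned.")
  }
  if (n_perm < 1) pb_usage_error("`n_perm` must be >= 1.")
  mfun <- selection_metric(metric)
  n <- length(labels)
  obs <- mfun(labels, pr_a) - mfun(labels, pr_b)
  diff_for <- function(swap) {
    a <- ifelse(swap, pr_b, pr_a)
    b <- ifelse(swap, pr_a, pr_b)
    mfun(labels, a) - mfun(labels, b)
  }
  if (is.null(exact)) exact <- n <= 12
  if (exact) {
    patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    diffs <- apply(patterns, 1, diff_for)
    p <- mean(abs(diffs) >= abs(obs) - 1e-12)
    method <- "exhaustive"
    n_swaps <- nrow(patterns)
  } else {
    diffs <- pb_with_seed(seed, {
      vapply(seq_len(n_perm), function(i) diff_for(runif(n) < 0.5), numeric(1))
    })
    p <- (sum(abs(diffs) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
    method <- "monte-carlo"
    n_swaps <- n_perm
  }
  tibble(metric = metric, estimate = obs, p.value = p,
         method = method, n_swaps = n_swaps)
}

#' DeLong test for paired ROC-AUC difference
#'
#' Two-sided comparison of correlated AUCs via the DeLong placement-value
#' variance. When both score vectors are identical (zero variance of the
#' difference) the p-value is 1 by convention; a zero variance with a
#' non-zero AUC difference yields p = 0 with a warning.
#'
#' @param labels True labels (both classes present).
#' @param scores_a,scores_b Aligned score vectors.
#' @return A one-row tibble: `auc_a`, `auc_b`, `delta_auc`, `statistic`
#'   (z), `p.value`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  if (length(unique(labels)) < 2L) {
    pb_usage_error("DeLong test needs both classes present.")
  }
  if (length(labels) != length(scores_a) || length(labels) != length(scores_b)) {
    pb_usage_error("`labels` and the score vectors must be aligned.")
  }
  auc_a <- roc_auc(labels, scores_a)
  auc_b <- roc_auc(labels, scores_b)
  delta <- auc_a - auc_b
  if (identical(as.numeric(scores_a), as.numeric(scores_b))) {
    return(tibble(auc_a = auc_a, auc_b = auc_b, delta_auc = 0,
                  statistic = 0, p.value = 1))
  }
  resp <- factor(labels, levels = c("benign", "pathogenic"))
  ra <- pROC::roc(resp, scores_a, levels = c("benign", "pathogenic"),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(resp, scores_b, levels = c("benign", "pathogenic"),
                  direction = "<", quiet = TRUE)
  res <- tryCatch(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$statistic)) {
    if (abs(delta) < 1e-12) {
      return(tibble(auc_a = auc_a, auc_b = auc_b, delta_auc = delta,
                    statistic = 0, p.value = 1))
    }
    warn("DeLong variance is zero with a non-zero AUC difference; p = 0.")
    return(tibble(auc_a = auc_a, auc_b = auc_b, delta_auc = delta,
                  statistic = Inf, p.value = 0))
  }
  tibble(auc_a = auc_a, auc_b = auc_b, delta_auc = delta,
         statistic = as.numeric(res$statistic), p.value = as.numeric(res$p.value))
}

#' Prevalence-adjusted predictive values
#'
#' Projects the high-confidence call rates measured on a labelled test set
#' onto a population with a different prior probability of pathogenicity
#' \eqn{\pi} (e.g. a diagnostic referral series) via Bayes' rule:
#' \deqn{PPV = \pi TPR / (\pi TPR + (1-\pi) FPR)}
#' \deqn{NPV = (1-\pi) TNR / ((1-\pi) TNR + \pi FNR)}
#' FNR is the rate of pathogenic variants confidently called benign and FPR
#' the rate of benign variants confidently called disease-causing; the
#' remainders up to 1 are indeterminate calls, which drop out of both
#' predictive values.
#'
#' @param rates A list / one-row data frame with `tpr`, `fnr`, `tnr`, `fpr`
#'   (see [predictive_rates()]).
#' @param prevalence Prior probability (or vector of priors) in (0, 1).
#' @return A tibble with one row per prevalence: `prevalence`, `ppv`, `npv`
#'   (`NA` when a denominator is zero).
#' @export
#' @examples
#' predictive_values_at_prevalence(
#'   list(tpr = 0.695, fnr = 0.01, tnr = 0.56, fpr = 0.03),
#'   prevalence = c(0.1, 0.6)
#' )
predictive_values_at_prevalence <- function(rates, prevalence) {
  r <- as.list(rates)
  need <- c("tpr", "fnr", "tnr", "fpr")
  if (!all(need %in% names(r))) {
    pb_usage_error("`rates` must provide tpr, fnr, tnr and fpr.")
  }
  v <- unlist(r[need])
  if (any(is.na(v)) || any(v < 0 | v > 1) ||
      r$tpr + r$fnr > 1 + 1e-9 || r$tnr + r$fpr > 1 + 1e-9) {
    pb_domain_error("Rates must lie in [0, 1] with tpr+fnr <= 1 and tnr+fpr <= 1.")
  }
  if (any(prevalence <= 0 | prevalence >= 1)) {
    pb_domain_error("`prevalence` must lie strictly in (0, 1).")
  }
  ppv <- safe_div(prevalence * r$tpr, prevalence * r$tpr + (1 - prevalence) * r$fpr)
  npv <- safe_div((1 - prevalence) * r$tnr, (1 - prevalence) * r$tnr + prevalence * r$fnr)
  tibble(prevalence = prevalence, ppv = ppv, npv = npv)
}

#' High-confidence call rates from a confusion summary
#'
#' @param suite A one-row tibble from [confusion_summary()].
#' @return A one-row tibble with `tpr`, `fnr`, `tnr`, `fpr` (full-class
#'   denominators; indeterminate calls make the pairs sum below 1).
#' @export
predictive_rates <- function(suite) {
  tibble(
    tpr = safe_div(suite$tp, suite$n_pathogenic),
    fnr = safe_div(suite$fn, suite$n_pathogenic),
    tnr = safe_div(suite$tn, suite$n_benign),
    fpr = safe_div(suite$fp, suite$n_benign)
  )
}

#' Compare the clinical metric suite between two subgroups
#'
#' Computes the full confusion summary per subgroup and a two-sided
#' permutation p-value for the difference in overall accuracy under random
#' shuffles of the subgroup assignment (e.g. variants seen vs unseen by an
#' upstream resource). Enumerates all assignments when feasible, otherwise
#' Monte-Carlo with the add-one correction.
#'
#' @param labels True labels.
#' @param pr Aligned probabilities.
#' @param group Aligned two-level grouping vector (both groups non-empty).
#' @param thresholds A [threshold_pair()].
#' @param n_perm Monte-Carlo permutations (default 2000).
#' @param seed Integer seed.
#' @return A list: `by_group` (tibble, one metric-suite row per group),
#'   `estimate` (accuracy difference, first group minus second),
#'   `p.value`, `method`.
#' @export
evaluate_subgroups <- function(labels, pr, group, thresholds = threshold_pair(),
                               n_perm = 2000, seed = 1) {
  lev <- unique(group)
  if (length(lev) != 2L) pb_usage_error("`group` must have exactly two non-empty levels.")
  if (length(labels) != length(pr) || length(labels) != length(group)) {
    pb_usage_error("`labels`, `pr` and `group` must be aligned.")
  }
  by_group <- dplyr::bind_rows(lapply(lev, function(g) {
    dplyr::bind_cols(tibble(group = g),
                     confusion_summary(labels[group == g], pr[group == g], thresholds))
  }))
  acc_diff <- function(g1_idx) {
    in1 <- seq_along(labels) %in% g1_idx
    mean((pr[in1] >= thresholds$upper & labels[in1] == "pathogenic") |
         (pr[in1] <= thresholds$lower & labels[in1] == "benign")) -
      mean((pr[!in1] >= thresholds$upper & labels[!in1] == "pathogenic") |
           (pr[!in1] <= thresholds$lower & labels[!in1] == "benign"))
  }
  n <- length(labels)
  n1 <- sum(group == lev[[1]])
  obs <- acc_diff(which(group == lev[[1]]))
  if (choose(n, n1) <= 4096) {
    diffs <- apply(combn(n, n1), 2, acc_diff)
    p <- mean(abs(diffs) >= abs(obs) - 1e-12)
    method <- "exhaustive"
  } else {
    diffs <- pb_with_seed(seed, {
      vapply(seq_len(n_perm), function(i) acc_diff(sample(n, n1)), numeric(1))
    })
    p <- (sum(abs(diffs) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
    method <- "monte-carlo"
  }
  list(by_group = by_group, estimate = obs, p.value = p, method = method)
}

#' One-stop evaluation of a predictions table
#'
#' Combines the thresholded confusion summary with the threshold-free
#' curve metrics (ROC-AUC, PR-AUC, Brier score).
#'
#' @inheritParams clinical_summary
#' @return A one-row tibble.
#' @export
evaluate_predictions <- function(data, truth = label, pr = pr,
                                 thresholds = threshold_pair()) {
  labels <- dplyr::pull(data, {{ truth }})
  p <- dplyr::pull(data, {{ pr }})
  dplyr::bind_cols(
    confusion_summary(labels, p, thresholds),
    tibble(roc_auc = roc_auc(labels, p), pr_auc = pr_auc(labels, p),
           brier = brier(labels, p))
  )
}
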