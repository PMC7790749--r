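test_that("three-way calls are inclusive toward confident classes", {
  calls <- classify_three_way(c(0.95, 0.9, 0.5, 0.1, 0.02))
  expect_equal(as.character(calls),
               c("disease-causing", "disease-causing", "indeterminate",
                 "benign", "benign"))
  t95 <- threshold_pair(0.95, 0.05)
  expect_equal(as.character(classify_three_way(0.92, t95)), "indeterminate")
  expect_error(classify_three_way(1.2), class = "pb_domain_error")
  expect_error(threshold_pair(0.1, 0.9), class = "pb_usage_error")
})

test_that("confusion summary reproduces a hand-counted composition", {
  labels <- rep(c("pathogenic", "benign"), each = 10)
  pr <- c(rep(0.95, 7), 0.05, rep(0.5, 2),      # 7 DC, 1 benign-call, 2 indet
          rep(0.05, 5), 0.95, rep(0.5, 4))      # 5 benign-call, 1 DC, 4 indet
  s <- confusion_summary(labels, pr)
  expect_equal(s$tp, 7); expect_equal(s$fn, 1)
  expect_equal(s$tn, 5); expect_equal(s$fp, 1)
  expect_equal(s$indeterminate_pathogenic, 2)
  expect_equal(s$indeterminate_benign, 4)
  expect_equal(s$tpr, 0.70)
  expect_equal(s$tnr, 0.50)
  expect_equal(s$ppv, 0.875)
  expect_equal(s$npv, 5 / 6)
  expect_equal(s$overall_accuracy, 0.60)
  expect_equal(s$proportion_high_confidence, 0.70)
  expect_equal(s$accuracy_high_confidence, 12 / 14)
  expect_equal(s$proportion_indeterminate, 0.30)

  perfect <- confusion_summary(labels, rep(c(1, 0), each = 10))
  expect_equal(perfect$tpr, 1); expect_equal(perfect$tnr, 1)
  expect_equal(perfect$ppv, 1); expect_equal(perfect$npv, 1)
  expect_equal(perfect$proportion_indeterminate, 0)

  # undefined rates are NA-flagged, never silently zero
  only_path <- confusion_summary(rep("pathogenic", 4), rep(0.5, 4))
  expect_true(is.na(only_path$tnr))
  expect_true(is.na(only_path$accuracy_high_confidence))
  expect_error(confusion_summary("pathogenic", c(0.5, 0.6)), class = "pb_usage_error")
})

test_that("clinical_summary is the pipe-friendly face of confusion_summary", {
  ds <- tibble(label = c("pathogenic", "benign", "benign"),
               pr = c(0.99, 0.01, 0.4))
  piped <- ds |> clinical_summary()
  expect_equal(piped, confusion_summary(ds$label, ds$pr))
  renamed <- ds |> dplyr::rename(truth = label, prob = pr) |>
    clinical_summary(truth = truth, pr = prob)
  expect_equal(renamed, piped)
})

test_that("ROC-AUC equals the Mann-Whitney pair count", {
  expect_equal(roc_auc(c("pathogenic", "benign"), c(1, 0)), 1)
  expect_equal(
    roc_auc(rep(c("pathogenic", "benign"), each = 2), c(0.9, 0.6, 0.7, 0.2)),
    0.75
  )
  expect_equal(roc_auc(rep(c("pathogenic", "benign"), 3), rep(0.4, 6)), 0.5)
  expect_warning(out <- roc_auc(rep("benign", 3), runif(3)))
  expect_true(is.na(out))

  # cross-check against pROC on a random instance with ties
  set.seed(7)
  labels <- sample(c("pathogenic", "benign"), 40, replace = TRUE, prob = c(.4, .6))
  scores <- round(runif(40), 1)
  expect_equal(
    roc_auc(labels, scores),
    as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("benign", "pathogenic"),
                                   direction = "<", quiet = TRUE)))
  )
})

test_that("PR-AUC uses the average-precision step form with tie blocks", {
  expect_equal(pr_auc(c("pathogenic", "benign"), c(0.9, 0.1)), 1)
  expect_equal(pr_auc(c("pathogenic", "pathogenic", "benign"), c(0.9, 0.8, 0.5)), 1)
  # all scores tied: precision = prevalence at recall 1
  expect_equal(pr_auc(rep(c("pathogenic", "benign"), c(3, 7)), rep(0.2, 10)), 0.3)
  # worked step case: scores 0.9(P), 0.8(B), 0.7(P) -> AP = 1/2 + (2/3)/2
  expect_equal(
    pr_auc(c("pathogenic", "benign", "pathogenic"), c(0.9, 0.8, 0.7)),
    0.5 * 1 + 0.5 * (2 / 3)
  )
  expect_warning(out <- pr_auc(rep("benign", 3), runif(3)))
  expect_true(is.na(out))
})

test_that("Brier score is the mean squared probability error", {
  expect_equal(brier(rep(c("pathogenic", "benign"), 2), rep(0.5, 4)), 0.25)
  expect_equal(brier(c("pathogenic", "benign"), c(0.9, 0.2)), 0.025)
  expect_equal(brier(c("pathogenic", "benign"), c(1, 0)), 0)
  expect_error(brier("pathogenic", 1.4), class = "pb_domain_error")
})

test_that("paired swap test matches exhaustive enumeration and is seeded", {
  labels <- c("pathogenic", "benign", "pathogenic")
  a <- c(0.9, 0.3, 0.7)
  b <- c(0.6, 0.4, 0.8)
  res <- paired_permutation_test("roc_auc", labels, a, b)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$n_swaps, 8)
  expect_equal(res$p.value, brute_swap_test(roc_auc, labels, a, b))

  ident <- paired_permutation_test("pr_auc", labels, a, a)
  expect_equal(ident$estimate, 0)
  expect_equal(ident$p.value, 1)

  # Monte-Carlo path approaches the exhaustive value
  mc <- paired_permutation_test("roc_auc", labels, a, b, n_perm = 4000,
                                seed = 2, exact = FALSE)
  expect_equal(mc$method, "monte-carlo")
  expect_lt(abs(mc$p.value - res$p.value), 0.05)
  mc2 <- paired_permutation_test("roc_auc", labels, a, b, n_perm = 4000,
                                 seed = 2, exact = FALSE)
  expect_identical(mc$p.value, mc2$p.value)

  expect_error(paired_permutation_test("no_such_metric", labels, a, b),
               class = "pb_usage_error")
})

test_that("DeLong comparison behaves at the edges and matches a bootstrap variance", {
  labels <- rep(c("pathogenic", "benign"), each = 4)
  a <- c(0.9, 0.8, 0.6, 0.55, 0.7, 0.4, 0.3, 0.2)
  b <- c(0.8, 0.5, 0.45, 0.3, 0.75, 0.6, 0.35, 0.25)

  same <- delong_test(labels, a, a)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p.value, 1)

  # label flip with negated scores leaves the AUC difference unchanged
  flipped <- ifelse(labels == "pathogenic", "benign", "pathogenic")
  res <- delong_test(labels, a, b)
  res_flip <- delong_test(flipped, -a, -b)
  expect_equal(res$delta_auc, res_flip$delta_auc, tolerance = 1e-12)
  expect_equal(res$p.value, res_flip$p.value, tolerance = 1e-9)

  # stratified paired bootstrap variance of the AUC difference (oracle)
  set.seed(31)
  pos <- which(labels == "pathogenic"); neg <- which(labels == "benign")
  boot <- replicate(1e5, {
    i <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    roc_auc(labels[i], a[i]) - roc_auc(labels[i], b[i])
  })
  var_delong <- (res$delta_auc / res$statistic)^2
  expect_lt(abs(var_delong - var(boot)) / var(boot), 0.25)

  expect_error(delong_test(rep("benign", 4), runif(4), runif(4)),
               class = "pb_usage_error")
})

test_that("prevalence projection follows Bayes' rule and is monotone", {
  expect_equal(
    predictive_values_at_prevalence(
      list(tpr = 0.8, fnr = 0.1, tnr = 0.7, fpr = 0.2), 0.5
    )$ppv,
    0.8
  )
  perfect_fpr <- predictive_values_at_prevalence(
    list(tpr = 0.6, fnr = 0.2, tnr = 0.9, fpr = 0), c(0.05, 0.5, 0.95)
  )
  expect_true(all(perfect_fpr$ppv == 1))

  grid <- predictive_values_at_prevalence(
    list(tpr = 0.695, fnr = 0.01, tnr = 0.56, fpr = 0.03),
    prevalence = seq(0.05, 0.95, by = 0.05)
  )
  expect_true(all(diff(grid$ppv) > 0))   # PPV strictly increasing in prevalence
  expect_true(all(diff(grid$npv) < 0))   # NPV strictly decreasing
  near_one <- predictive_values_at_prevalence(
    list(tpr = 0.8, fnr = 0.2, tnr = 0.8, fpr = 0.1), 0.999
  )
  expect_lt(near_one$npv, 0.01)

  expect_error(
    predictive_values_at_prevalence(list(tpr = 0.9, fnr = 0.3, tnr = 1, fpr = 0), 0.5),
    class = "pb_domain_error"
  )
  expect_error(
    predictive_values_at_prevalence(list(tpr = 0.9, fnr = 0.1, tnr = 1, fpr = 0), 1),
    class = "pb_domain_error"
  )
})

test_that("subgroup comparison returns per-group suites and an enumeration-exact p", {
  labels <- rep(c("pathogenic", "benign"), 5)
  pr <- rep(c(0.95, 0.05), 5)
  group <- rep(c("seen", "unseen"), each = 5)
  res <- evaluate_subgroups(labels, pr, group)
  expect_equal(res$estimate, 0)
  expect_equal(res$p.value, 1)
  expect_equal(res$method, "exhaustive")
  expect_equal(nrow(res$by_group), 2)
  expect_equal(res$by_group$overall_accuracy, c(1, 1))

  # against a test-side enumeration on an uneven instance
  set.seed(5)
  labels2 <- sample(rep(c("pathogenic", "benign"), 5))
  pr2 <- ifelse(labels2 == "pathogenic", runif(10, 0.3, 1), runif(10, 0, 0.7))
  group2 <- rep(c("g1", "g2"), c(4, 6))
  res2 <- evaluate_subgroups(labels2, pr2, group2)
  correct <- (pr2 >= 0.9 & labels2 == "pathogenic") |
    (pr2 <= 0.1 & labels2 == "benign")
  obs <- mean(correct[1:4]) - mean(correct[5:10])
  diffs <- apply(combn(10, 4), 2, function(i) {
    mean(correct[i]) - mean(correct[-i])
  })
  expect_equal(res2$estimate, obs)
  expect_equal(res2$p.value, mean(abs(diffs) >= abs(obs) - 1e-12))

  expect_error(evaluate_subgroups(labels, pr, rep("one", 10)),
               class = "pb_usage_error")
})

test_that("evaluate_predictions combines thresholded and curve metrics", {
  ds <- tiny_dataset(40, 40, p = 4, sep = 3, seed = 2)
  fit <- fit_adaboost(ds, n_rounds = 10, tree_depth = 2, seed = 1)
  out <- predict(fit, ds) |>
    dplyr::mutate(label = ds$label) |>
    evaluate_predictions()
  expect_true(all(c("tpr", "roc_auc", "pr_auc", "brier") %in% names(out)))
  expect_equal(out$roc_auc, roc_auc(ds$label, predict_pr(fit, ds)))
})
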