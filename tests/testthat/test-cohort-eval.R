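test_that("odds ratios are exact cross-product ratios with Woolf intervals", {
  sym <- gene_odds_ratio(tibble(gene = "G", a = 10, b = 10, c = 10, d = 10))
  expect_equal(sym$or, 1)
  expect_lt(sym$ci_low, 1); expect_gt(sym$ci_high, 1)
  expect_false(sym$corrected)

  worked <- gene_odds_ratio(tibble(gene = "G", a = 20, b = 980, c = 10, d = 9990))
  expect_equal(worked$or, (20 * 9990) / (980 * 10))
  expect_equal(worked$or, 20.3877551, tolerance = 1e-7)
  se <- sqrt(1 / 20 + 1 / 980 + 1 / 10 + 1 / 9990)
  expect_equal(worked$ci_low, exp(log(worked$or) - qnorm(0.975) * se))

  zero <- gene_odds_ratio(tibble(gene = "G", a = 0, b = 100, c = 5, d = 995))
  expect_true(zero$corrected)
  expect_true(is.finite(zero$or) && zero$or > 0)
  expect_equal(zero$or, (0.5 * 995.5) / (100.5 * 5.5))

  # exact-arithmetic property on random positive tables
  set.seed(11)
  for (i in 1:20) {
    cells <- sample(1:500, 4)
    res <- gene_odds_ratio(tibble(a = cells[1], b = cells[2], c = cells[3], d = cells[4]))
    expect_equal(res$or, cells[1] * cells[4] / (cells[2] * cells[3]))
    expect_true(res$ci_low <= res$or && res$or <= res$ci_high)
  }

  expect_error(gene_odds_ratio(tibble(a = -1, b = 1, c = 1, d = 1)),
               class = "pb_domain_error")
})

test_that("stratified comparison tests log-OR differences against the baseline", {
  tabs <- tibble(
    gene = "MYH7",
    stratum = c("all-rare", "predicted-disease-causing", "predicted-benign"),
    a = c(60, 45, 5), b = c(940, 955, 995),
    c = c(30, 10, 20), d = c(9970, 9990, 9980)
  )
  res <- stratified_or_comparison(tabs)
  ors <- setNames(res$or, res$stratum)
  expect_gt(ors["predicted-disease-causing"], ors["all-rare"])
  expect_gt(ors["all-rare"], ors["predicted-benign"])
  expect_true(is.na(res$p_vs_baseline[res$stratum == "all-rare"]))
  expect_true(all(res$p_vs_baseline[res$stratum != "all-rare"] < 1))

  # stratum identical to baseline: zero difference, p = 1
  same <- tibble(gene = "G", stratum = c("all-rare", "predicted-benign"),
                 a = 20, b = 980, c = 10, d = 9990)
  res_same <- stratified_or_comparison(same)
  expect_equal(res_same$log_or_diff[2], 0)
  expect_equal(res_same$p_vs_baseline[2], 1)

  # zero-cell stratum is corrected and flagged, still comparable
  zc <- tibble(gene = "G", stratum = c("all-rare", "predicted-benign"),
               a = c(20, 0), b = c(980, 1000), c = 10, d = 9990)
  res_zc <- stratified_or_comparison(zc)
  expect_true(res_zc$corrected[2])
  expect_true(is.finite(res_zc$p_vs_baseline[2]))

  expect_error(
    stratified_or_comparison(tibble(gene = "G", stratum = "predicted-benign",
                                    a = 1, b = 9, c = 1, d = 9)),
    class = "pb_usage_error"
  )
})

test_that("Kaplan-Meier estimates match the product-limit computed by hand", {
  km <- km_estimate(tibble(age = 1:4, event = c(1, 0, 1, 0)))
  expect_equal(km$surv[km$age == 1], 3 / 4)
  expect_equal(km$surv[km$age == 3], 3 / 8)   # 3/4 * 1/2
  expect_equal(km$cuminc, 1 - km$surv)
  expect_equal(risk_at_age(km, 2.5), 1 / 4)
  expect_equal(risk_at_age(km, 0.5), 0)

  none <- km_estimate(tibble(age = c(2, 5, 9), event = 0))
  expect_true(all(none$surv == 1))

  # all events, distinct ages: empirical survival 1 - k/n
  emp <- km_estimate(tibble(age = c(3, 1, 4, 2), event = 1))
  expect_equal(emp$surv, 1 - (1:4) / 4)

  expect_error(km_estimate(tibble(age = c(1, -2), event = 1)),
               class = "pb_domain_error")
})

test_that("log-rank agrees with the hypergeometric hand computation", {
  ident <- tibble(age = rep(c(1, 3, 5), 2), event = rep(c(1, 0, 1), 2),
                  group = rep(c("A", "B"), each = 3))
  res <- logrank_test(ident)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1)

  worked <- tibble(
    age = c(2, 4, 6, 1, 3, 5),
    event = c(1, 1, 0, 1, 0, 1),
    group = rep(c("A", "B"), each = 3)
  )
  res_w <- logrank_test(worked)
  expect_equal(res_w$statistic, brute_logrank(worked$age, worked$event, worked$group),
               tolerance = 1e-10)
  expect_equal(res_w$df, 1)

  swapped <- worked |> dplyr::mutate(group = ifelse(group == "A", "B", "A"))
  expect_equal(logrank_test(swapped)$statistic, res_w$statistic)

  expect_warning(nores <- logrank_test(tibble(age = c(1, 2), event = 0,
                                              group = c("A", "B"))))
  expect_true(is.na(nores$p.value))
  expect_error(logrank_test(tibble(age = 1, event = 1, group = "A")),
               class = "pb_usage_error")
})

test_that("Cox hazard ratios recover truth and flag monotone likelihoods", {
  base <- tibble(age = c(2, 3, 5, 7, 8, 11), event = c(1, 1, 0, 1, 0, 1))
  twin <- dplyr::bind_rows(
    dplyr::mutate(base, group = "A"),
    dplyr::mutate(base, group = "B")
  )
  same <- cox_hr(twin, reference = "A")
  expect_equal(same$hr, 1, tolerance = 1e-6)
  expect_gt(same$p.value, 0.99)
  expect_false(same$flagged)

  # mean log-HR over 20 seeded two-group simulations within 5% of log(1.9)
  groups <- tibble(group = c("ref", "carrier"), n = 2000L, hr = c(1, 1.9))
  log_hrs <- vapply(1:20, function(s) {
    sv <- gen_survival_cohort(survival_gen_spec(groups = groups, seed = 100 + s))
    log(cox_hr(sv, reference = "ref")$hr)
  }, numeric(1))
  expect_lt(abs(mean(log_hrs) - log(1.9)) / log(1.9), 0.05)

  # Wald and log-rank p agree in order of magnitude at a moderate effect
  sv1 <- gen_survival_cohort(survival_gen_spec(
    groups = tibble(group = c("ref", "carrier"), n = 300L, hr = c(1, 1.3)),
    seed = 101
  ))
  p_cox <- cox_hr(sv1, reference = "ref")$p.value
  p_lr <- logrank_test(sv1)$p.value
  expect_lt(abs(log10(p_cox) - log10(p_lr)), 1)

  noev <- tibble(age = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                 group = rep(c("A", "B"), each = 2))
  noev$event[noev$group == "B"] <- 0
  flagged <- suppressWarnings(cox_hr(noev, reference = "A"))
  expect_true(flagged$flagged)
})

test_that("risk difference at an age reduces to ECDFs without censoring", {
  ident <- tibble(age = rep(c(10, 20, 30, 40), 2), event = 1,
                  group = rep(c("A", "B"), each = 4))
  same <- outcome_risk_by_age(ident, 25, n_boot = 200, seed = 3)
  expect_equal(same$risk_difference, 0)
  expect_lte(same$ci_low, 0); expect_gte(same$ci_high, 0)

  nc <- tibble(
    age = c(10, 20, 30, 40, 15, 35, 45, 55), event = 1,
    group = rep(c("A", "B"), each = 4)
  )
  res <- outcome_risk_by_age(nc, 32, n_boot = 100, seed = 1)
  ecdf_a <- mean(nc$age[nc$group == "A"] <= 32)
  ecdf_b <- mean(nc$age[nc$group == "B"] <= 32)
  expect_equal(res$risk_difference, ecdf_a - ecdf_b)

  res2 <- outcome_risk_by_age(nc, 32, n_boot = 100, seed = 1)
  expect_identical(res, res2)   # seeded bootstrap is deterministic

  expect_warning(oob <- outcome_risk_by_age(nc, 99, n_boot = 10, seed = 1))
  expect_true(is.na(oob$risk_difference))
})
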