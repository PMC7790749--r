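test_that("a single stump separates gap-separated classes with zero error", {
  ds <- separable_1d(10)
  fit <- fit_adaboost(ds, n_rounds = 1, tree_depth = 1, seed = 1)
  expect_length(fit$trees, 1)
  expect_equal(fit$round_errors, 0)
  expect_equal(fit$metadata$stopping, "zero_training_error")
  expect_equal(fit$alphas, log(1e6))             # capped weight for a perfect round
  stump <- fit$trees[[1]]
  expect_false(stump$leaf)
  expect_gt(stump$threshold, -0.5)               # threshold inside the gap
  expect_lt(stump$threshold, 0.5)
  pr <- predict_pr(fit, ds)
  expect_true(all((pr > 0.5) == (ds$label == "pathogenic")))
})

test_that("round weights follow the closed-form error update", {
  expect_equal(pathboost:::alpha_from_error(0.25), 0.5 * log(3))
  expect_equal(pathboost:::alpha_from_error(0.5), 0)
  # on a fitted noisy model every stored alpha matches its stored error
  ds <- tiny_dataset(40, 40, p = 4, sep = 1, seed = 3)
  fit <- fit_adaboost(ds, n_rounds = 15, tree_depth = 1, seed = 1)
  recomputed <- pmin(pathboost:::alpha_from_error(fit$round_errors),
                     fit$metadata$alpha_cap)
  expect_equal(fit$alphas, recomputed)
  expect_true(all(fit$alphas >= 0 & is.finite(fit$alphas)))
})

test_that("degenerate inputs are refused or flagged", {
  # contradictory duplicated points: no stump beats chance in round 1
  xor_ds <- separable_1d(2)
  xor_ds$x1 <- c(1, 1, 1, 1)
  xor_ds$label <- c("pathogenic", "benign", "pathogenic", "benign")
  expect_error(suppressWarnings(fit_adaboost(xor_ds, n_rounds = 3, tree_depth = 1)),
               "chance", class = "pb_usage_error")

  one_class <- separable_1d(5) |> dplyr::mutate(label = "benign")
  expect_error(fit_adaboost(one_class, 5, 1), class = "pb_usage_error")

  const <- separable_1d(5) |> dplyr::mutate(x1 = 1)
  saw_constant_warning <- FALSE
  cond <- tryCatch(
    withCallingHandlers(
      fit_adaboost(const, 5, 1),
      warning = function(w) {
        saw_constant_warning <<- grepl("constant", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) e
  )
  expect_true(saw_constant_warning)
  expect_s3_class(cond, "pb_usage_error")
})

test_that("probability transforms implement the weighted-vote arithmetic", {
  df <- tibble(x1 = 0)
  m <- manual_boost_model(alphas = c(1, 3), votes = c(0L, 1L))
  expect_equal(predict_pr(m, df, transform = "vote_share"), 0.75)
  expect_equal(predict_pr(m, df, transform = "logistic_margin"),
               stats::plogis(2 * (3 - 1)))

  unanimous <- manual_boost_model(alphas = c(0.5, 1.2, 2), votes = c(1L, 1L, 1L))
  expect_equal(predict_pr(unanimous, df, transform = "vote_share"), 1)
  expect_gt(predict_pr(unanimous, df), 0.999)

  # flipping any single vote benign -> pathogenic never decreases Pr
  set.seed(99)
  for (i in 1:15) {
    alphas <- runif(5, 0, 2)
    votes <- sample(0:1, 5, replace = TRUE)
    base <- manual_boost_model(alphas, as.integer(votes))
    for (j in which(votes == 0L)) {
      flipped_votes <- votes; flipped_votes[j] <- 1L
      flipped <- manual_boost_model(alphas, as.integer(flipped_votes))
      for (tr in c("vote_share", "logistic_margin")) {
        expect_gte(predict_pr(flipped, df, transform = tr),
                   predict_pr(base, df, transform = tr))
      }
    }
  }
})

test_that("ensemble training error is driven to zero on separable data", {
  ds <- tiny_dataset(50, 50, p = 4, sep = 6, seed = 21, missing_rate = 0)
  fit <- fit_adaboost(ds, n_rounds = 40, tree_depth = 1, seed = 1)
  X <- pathboost:::impute_matrix(
    pathboost:::feature_matrix(ds, fit$schema), fit$imputation
  )
  votes <- vapply(fit$trees, function(tr) pathboost:::predict_tree(tr, X),
                  integer(nrow(X)))
  y <- as.integer(ds$label == "pathogenic")
  staged_error <- vapply(seq_along(fit$alphas), function(m) {
    f <- votes[, seq_len(m), drop = FALSE] %*% fit$alphas[seq_len(m)] -
      sum(fit$alphas[seq_len(m)]) / 2
    mean((f > 0) != (y == 1))
  }, numeric(1))
  expect_lte(staged_error[length(staged_error)], staged_error[1])
  expect_equal(staged_error[length(staged_error)], 0)
})

test_that("prediction is a row-wise map and honours the stored imputation", {
  ds <- tiny_dataset(40, 40, p = 5, sep = 2, seed = 4, missing_rate = 0.15)
  fit <- fit_adaboost(ds, n_rounds = 10, tree_depth = 2, seed = 1)
  meds <- apply(pathboost:::feature_matrix(ds, fit$schema), 2, median, na.rm = TRUE)
  expect_equal(fit$imputation, meds)

  pr <- predict_pr(fit, ds)
  expect_true(all(pr >= 0 & pr <= 1))
  perm <- sample(nrow(ds))
  expect_equal(predict_pr(fit, ds[perm, ]), pr[perm])

  # schema mismatch names the first offending column
  expect_error(predict_pr(fit, ds[setdiff(names(ds), "score_01")]),
               "score_01", class = "pb_schema_error")

  preds <- predict(fit, ds)
  expect_named(preds, c("variant_id", "pr", "clinical_call"))
  expect_s3_class(preds, "tbl_df")
})

test_that("JSON model files round-trip to bitwise-identical predictions", {
  ds <- tiny_dataset(50, 50, p = 6, sep = 2, seed = 12, missing_rate = 0.1)
  fit <- fit_adaboost(ds, n_rounds = 12, tree_depth = 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  reloaded <- load_model(path)
  expect_identical(predict_pr(fit, ds), predict_pr(reloaded, ds))
  expect_identical(predict_pr(fit, ds, "vote_share"),
                   predict_pr(reloaded, ds, "vote_share"))
  expect_equal(glance(reloaded)$n_rounds, glance(fit)$n_rounds)

  # tampered schema: drop a feature the trees still reference
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  payload$schema$feature <- payload$schema$feature[1:3]
  payload$schema$kind <- payload$schema$kind[1:3]
  payload$schema$missing_allowed <- payload$schema$missing_allowed[1:3]
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(payload, bad, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(bad), class = "pb_validation_error")

  empty <- withr::local_tempfile(fileext = ".json")
  file.create(empty)
  expect_error(load_model(empty), class = "pb_validation_error")

  payload2 <- jsonlite::read_json(path, simplifyVector = FALSE)
  payload2$format <- "pathboost-model-99"
  wrong <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(payload2, wrong, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(wrong), "format", class = "pb_validation_error")
})

test_that("tidy and glance expose the boosting trajectory", {
  ds <- tiny_dataset(30, 30, p = 4, sep = 2, seed = 6)
  fit <- fit_adaboost(ds, n_rounds = 8, tree_depth = 2, seed = 3)
  td <- tidy(fit)
  expect_equal(names(td), c("round", "alpha", "weighted_error"))
  expect_equal(nrow(td), length(fit$alphas))
  gl <- glance(fit)
  expect_equal(gl$tree_depth, 2)
  expect_equal(gl$n_train, 60)
})
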