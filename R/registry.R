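# The default candidate registry: nine algorithms spanning the major
# families (boosted trees, gradient boosting, random forest, regularised
# logistic regression, kernel SVM, nearest neighbour, naive Bayes, a single
# tree, and a small feed-forward net), plus a majority-class baseline for
# testing. Only the boosted-tree candidate's behaviour is specified in
# detail; the rest wrap established implementations and are tuning-grid
# stand-ins. A candidate whose backing package is unavailable fails inside
# cross-validation and is scored -Inf rather than aborting the selection.

# Shared preparation: schema-ordered feature matrix with training-median
# imputation; the medians travel with the fitted model.
xy_prepare <- function(data, schema) {
  X <- feature_matrix(data, schema)
  imput <- apply(X, 2, function(v) {
    m <- median(v, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
  list(x = impute_matrix(X, imput), y = factor(data$label, c("benign", "pathogenic")),
       imputation = imput)
}

x_apply <- function(model, data, schema) {
  impute_matrix(feature_matrix(data, schema), model$imputation)
}

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    pb_usage_error(paste0("Candidate requires the '", pkg, "' package."))
  }
}

#' Candidate constructors
#'
#' Each constructor returns a [candidate()] with a small default grid;
#' supply `grid` to override. `candidate_boost()` wraps [fit_adaboost()]
#' (the package's own model); `candidate_majority()` always predicts the
#' training prevalence and serves as a floor in comparisons.
#'
#' @param grid Named list of hyperparameter value vectors.
#' @return A `pb_candidate`.
#' @name candidates
NULL

#' @rdname candidates
#' @export
candidate_boost <- function(grid = list(n_rounds = 30, tree_depth = c(1, 3))) {
  candidate("adaboost", grid,
    fit = function(data, params, schema) {
      fit_adaboost(data, n_rounds = params$n_rounds, tree_depth = params$tree_depth,
                   seed = 1, schema = schema)
    },
    predict = function(model, data) predict_pr(model, data)
  )
}

#' @rdname candidates
#' @export
candidate_majority <- function(grid = list(intercept = TRUE)) {
  candidate("majority_class", grid,
    fit = function(data, params, schema) {
      list(prevalence = mean(data$label == "pathogenic"))
    },
    predict = function(model, data) rep(model$prevalence, nrow(data))
  )
}

#' @rdname candidates
#' @export
candidate_gradient_boost <- function(grid = list(nrounds = 50, max_depth = c(2, 3))) {
  candidate("gradient_boosting", grid,
    fit = function(data, params, schema) {
      need_pkg("xgboost")
      xy <- xy_prepare(data, schema)
      booster <- xgboost::xgboost(
        data = xy$x, label = as.integer(xy$y == "pathogenic"),
        nrounds = params$nrounds, max_depth = params$max_depth,
        objective = "binary:logistic", verbose = 0, nthread = 1
      )
      list(fit = booster, imputation = xy$imputation, schema = schema)
    },
    predict = function(model, data) {
      as.numeric(predict(model$fit, x_apply(model, data, model$schema)))
    }
  )
}

#' @rdname candidates
#' @export
candidate_random_forest <- function(grid = list(num_trees = 200, mtry_frac = c(0.2))) {
  candidate("random_forest", grid,
    fit = function(data, params, schema) {
      need_pkg("ranger")
      xy <- xy_prepare(data, schema)
      df <- data.frame(xy$x, .label = xy$y, check.names = FALSE)
      rf <- ranger::ranger(
        dependent.variable.name = ".label", data = df,
        num.trees = params$num_trees,
        mtry = max(1L, floor(params$mtry_frac * ncol(xy$x))),
        probability = TRUE, seed = 1, num.threads = 1
      )
      list(fit = rf, imputation = xy$imputation, schema = schema)
    },
    predict = function(model, data) {
      x <- as.data.frame(x_apply(model, data, model$schema))
      predict(model$fit, data = x, num.threads = 1)$predictions[, "pathogenic"]
    }
  )
}

#' @rdname candidates
#' @export
candidate_logistic <- function(grid = list(lambda = c(0.01, 0.001))) {
  candidate("logistic_lasso", grid,
    fit = function(data, params, schema) {
      need_pkg("glmnet")
      xy <- xy_prepare(data, schema)
      fit <- glmnet::glmnet(xy$x, xy$y, family = "binomial",
                            lambda = params$lambda)
      list(fit = fit, imputation = xy$imputation, schema = schema, lambda = params$lambda)
    },
    predict = function(model, data) {
      as.numeric(predict(model$fit, x_apply(model, data, model$schema),
                         s = model$lambda, type = "response"))
    }
  )
}

#' @rdname candidates
#' @export
candidate_svm <- function(grid = list(cost = c(1, 10))) {
  candidate("svm_rbf", grid,
    fit = function(data, params, schema) {
      need_pkg("e1071")
      xy <- xy_prepare(data, schema)
      fit <- e1071::svm(xy$x, xy$y, cost = params$cost, probability = TRUE)
      list(fit = fit, imputation = xy$imputation, schema = schema)
    },
    predict = function(model, data) {
      p <- predict(model$fit, x_apply(model, data, model$schema), probability = TRUE)
      attr(p, "probabilities")[, "pathogenic"]
    }
  )
}

#' @rdname candidates
#' @export
candidate_knn <- function(grid = list(k = c(5, 15))) {
  candidate("nearest_neighbour", grid,
    fit = function(data, params, schema) {
      need_pkg("class")
      xy <- xy_prepare(data, schema)
      list(x = xy$x, y = xy$y, k = params$k, imputation = xy$imputation, schema = schema)
    },
    predict = function(model, data) {
      x <- x_apply(model, data, model$schema)
      p <- class::knn(model$x, x, model$y, k = model$k, prob = TRUE)
      prob <- attr(p, "prob")
      ifelse(p == "pathogenic", prob, 1 - prob)
    }
  )
}

#' @rdname candidates
#' @export
candidate_naive_bayes <- function(grid = list(laplace = 0)) {
  candidate("naive_bayes", grid,
    fit = function(data, params, schema) {
      need_pkg("e1071")
      xy <- xy_prepare(data, schema)
      fit <- e1071::naiveBayes(as.data.frame(xy$x), xy$y, laplace = params$laplace)
      list(fit = fit, imputation = xy$imputation, schema = schema)
    },
    predict = function(model, data) {
      x <- as.data.frame(x_apply(model, data, model$schema))
      predict(model$fit, x, type = "raw")[, "pathogenic"]
    }
  )
}

#' @rdname candidates
#' @export
candidate_tree <- function(grid = list(maxdepth = c(3, 6))) {
  candidate("decision_tree", grid,
    fit = function(data, params, schema) {
      need_pkg("rpart")
      xy <- xy_prepare(data, schema)
      df <- data.frame(xy$x, .label = xy$y, check.names = FALSE)
      fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                          control = rpart::rpart.control(maxdepth = params$maxdepth,
                                                         cp = 0, xval = 0))
      list(fit = fit, imputation = xy$imputation, schema = schema)
    },
    predict = function(model, data) {
      x <- as.data.frame(x_apply(model, data, model$schema))
      predict(model$fit, x, type = "prob")[, "pathogenic"]
    }
  )
}

#' @rdname candidates
#' @export
candidate_neural_net <- function(grid = list(size = c(4), decay = c(0.01))) {
  candidate("feedforward_net", grid,
    fit = function(data, params, schema) {
      need_pkg("nnet")
      xy <- xy_prepare(data, schema)
      fit <- pb_with_seed(1, nnet::nnet(
        xy$x, as.integer(xy$y == "pathogenic"), size = params$size,
        decay = params$decay, maxit = 200, trace = FALSE
      ))
      list(fit = fit, imputation = xy$imputation, schema = schema)
    },
    predict = function(model, data) {
      as.numeric(predict(model$fit, x_apply(model, data, model$schema)))
    }
  )
}

#' Default candidate registry
#'
#' The nine-algorithm registry used by [nested_select()] when none is given.
#'
#' @return A list of `pb_candidate` objects, boosted trees first.
#' @export
default_registry <- function() {
  list(
    candidate_boost(),
    candidate_gradient_boost(),
    candidate_random_forest(),
    candidate_logistic(),
    candidate_svm(),
    candidate_knn(),
    candidate_naive_bayes(),
    candidate_tree(),
    candidate_neural_net()
  )
}
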