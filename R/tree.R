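# Depth-limited weighted decision trees: the weak learner inside the
# boosting ensemble. Numeric features only (the feature matrix is imputed
# before fitting); splits minimise weighted Gini impurity; leaves vote by
# weighted majority. Trees are plain nested lists so they serialize to JSON
# exactly and predictions round-trip bit-for-bit.

tree_leaf <- function(vote) list(leaf = TRUE, vote = as.integer(vote))

# Best single split of rows flagged in `member`, by weighted Gini.
# `ord` holds the per-feature presorted row orders of the full matrix (they
# never change across boosting rounds, so they are computed once per fit).
# Returns NULL when no split separates distinct feature values or none
# reduces impurity.
best_split <- function(X, y, w, member, ord) {
  W <- sum(w[member])
  P <- sum(w[member] * y[member])
  # parent weighted Gini: 2 p (1-p) W
  parent <- 2 * P * (W - P) / W
  best <- NULL
  best_cost <- parent - 1e-12
  for (j in seq_len(ncol(X))) {
    oj <- ord[[j]]
    o <- oj[member[oj]]  # node rows in presorted feature order
    xs <- X[o, j]
    n <- length(xs)
    if (xs[1] == xs[n]) next
    ws <- w[o]
    cw <- cumsum(ws)
    cw1 <- cumsum(ws * y[o])
    pos <- which(xs[-n] < xs[-1])
    wl <- cw[pos]
    pl <- cw1[pos]
    wr <- W - wl
    pr <- P - pl
    cost <- 2 * (ifelse(wl > 0, pl * (wl - pl) / wl, 0) +
                 ifelse(wr > 0, pr * (wr - pr) / wr, 0))
    k <- which.min(cost)
    if (length(k) && cost[k] < best_cost) {
      best_cost <- cost[k]
      i <- pos[k]
      best <- list(feature = j, threshold = (xs[i] + xs[i + 1]) / 2)
    }
  }
  best
}

presort_features <- function(X) {
  lapply(seq_len(ncol(X)), function(j) order(X[, j], method = "radix"))
}

fit_tree <- function(X, y, w, max_depth, ord = presort_features(X)) {
  member <- logical(nrow(X))
  build <- function(idx, depth) {
    wn <- w[idx]
    p1 <- sum(wn * y[idx]) / sum(wn)
    vote <- as.integer(p1 >= 0.5)
    if (depth >= max_depth || p1 <= 0 || p1 >= 1 || length(idx) < 2L) {
      return(tree_leaf(vote))
    }
    member[idx] <<- TRUE
    sp <- best_split(X, y, w, member, ord)
    member[idx] <<- FALSE
    if (is.null(sp)) return(tree_leaf(vote))
    go_left <- X[idx, sp$feature] <= sp$threshold
    list(
      leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
      left = build(idx[go_left], depth + 1L),
      right = build(idx[!go_left], depth + 1L)
    )
  }
  build(seq_len(nrow(X)), 0L)
}

# Vectorised 0/1 votes of one tree over a feature matrix.
predict_tree <- function(node, X) {
  out <- integer(nrow(X))
  walk <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (isTRUE(node$leaf)) {
      out[idx] <<- node$vote
      return(invisible())
    }
    go_left <- X[idx, node$feature] <= node$threshold
    walk(node$left, idx[go_left])
    walk(node$right, idx[!go_left])
    invisible()
  }
  walk(node, seq_len(nrow(X)))
  out
}

# Validate a deserialized tree against the schema width; errors on any
# malformed node so edited model files fail loudly at load time.
check_tree <- function(node, p) {
  if (!is.list(node) || is.null(node$leaf)) {
    pb_validation_error("Malformed tree node in model file.")
  }
  if (isTRUE(node$leaf)) {
    if (!node$vote %in% c(0L, 1L)) pb_validation_error("Tree leaf vote must be 0 or 1.")
    return(invisible())
  }
  if (is.null(node$feature) || node$feature < 1 || node$feature > p ||
      is.null(node$threshold) || !is.finite(node$threshold)) {
    pb_validation_error("Tree split references a feature outside the model schema.")
  }
  check_tree(node$left, p)
  check_tree(node$right, p)
}

# Rebuild exact-typed tree nodes from parsed JSON (lists of length-1 vectors).
deserialize_tree <- function(node) {
  if (isTRUE(node$leaf)) return(tree_leaf(node$vote))
  list(
    leaf = FALSE,
    feature = as.integer(node$feature),
    threshold = as.numeric(node$threshold),
    left = deserialize_tree(node$left),
    right = deserialize_tree(node$right)
  )
}
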