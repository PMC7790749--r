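# broom-style accessors for fitted objects.

#' Tidy a boosted model: one row per boosting round
#'
#' @param x A `pb_boost` model.
#' @param ... Unused.
#' @return A tibble with `round`, `alpha` (round weight) and
#'   `weighted_error`.
#' @export
tidy.pb_boost <- function(x, ...) {
  tibble(
    round = seq_along(x$alphas),
    alpha = x$alphas,
    weighted_error = x$round_errors
  )
}

#' @rdname tidy.pb_boost
#' @return `glance()` returns a one-row model summary.
#' @export
glance.pb_boost <- function(x, ...) {
  md <- x$metadata
  tibble(
    n_rounds = length(x$alphas),
    n_rounds_requested = md$n_rounds_requested,
    tree_depth = md$tree_depth,
    stopping = md$stopping,
    n_train = md$n_train,
    n_pathogenic = md$n_pathogenic,
    n_benign = md$n_benign,
    seed = md$seed
  )
}

#' Tidy a selection report: one row per (algorithm, outer fold)
#'
#' @param x A `pb_selection_report`.
#' @param ... Unused.
#' @return A tibble with `algorithm`, `fold`, `score` and the chosen
#'   hyperparameters as a list column.
#' @export
tidy.pb_selection_report <- function(x, ...) x$scores

#' @rdname tidy.pb_selection_report
#' @return `glance()` returns a one-row summary with the winner.
#' @export
glance.pb_selection_report <- function(x, ...) {
  win <- x$summary[x$summary$algorithm == x$winner, ]
  tibble(
    winner = x$winner, metric = x$metric,
    mean_score = win$mean_score, sd_score = win$sd_score,
    outer_k = x$outer_k, inner_k = x$inner_k, seed = x$seed
  )
}
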