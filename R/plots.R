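# ggplot2 displays for the main result types.

#' Plot predicted score distributions with the clinical thresholds
#'
#' Histograms of the probability of pathogenicity by true label, with the
#' disease-causing / benign call thresholds overlaid; the region between
#' them is the clinically indeterminate band.
#'
#' @param data Tibble with label and probability columns.
#' @param truth,pr Unquoted column names (defaults `label`, `pr`).
#' @param thresholds A [threshold_pair()].
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(data, truth = label, pr = pr,
                                    thresholds = threshold_pair()) {
  ggplot2::ggplot(data, ggplot2::aes(x = {{ pr }}, fill = {{ truth }})) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.55,
                            bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(thresholds$lower, thresholds$upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Probability of pathogenicity", y = "Variants",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by group
#'
#' @param data Tibble with `age`, `event`, `group`.
#' @param cumulative Plot cumulative incidence (`1 - S`) instead of
#'   survival (default FALSE).
#' @return A ggplot object.
#' @export
plot_km <- function(data, cumulative = FALSE) {
  curves <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ km_estimate(.x)) |>
    dplyr::ungroup()
  start <- dplyr::distinct(curves, .data$group) |>
    dplyr::mutate(age = 0, surv = 1, cuminc = 0)
  curves <- dplyr::bind_rows(start, curves)
  y <- if (cumulative) "cuminc" else "surv"
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$age, y = .data[[y]],
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Age (years)",
                  y = if (cumulative) "Cumulative incidence" else "Event-free survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of per-gene odds ratios (log scale)
#'
#' @param or_table Output of [gene_odds_ratio()] or
#'   [stratified_or_comparison()] (columns `gene`, `or`, `ci_low`,
#'   `ci_high`, optionally `stratum`).
#' @return A ggplot object.
#' @export
plot_or_forest <- function(or_table) {
  aes <- if ("stratum" %in% names(or_table)) {
    ggplot2::aes(x = .data$or, y = .data$gene, colour = .data$stratum)
  } else {
    ggplot2::aes(x = .data$or, y = .data$gene)
  }
  ggplot2::ggplot(or_table, aes) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2, position = ggplot2::position_dodge(width = 0.6)
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pb_boost <- function(object, ...) {
  d <- tidy(object)
  tidyr::pivot_longer(d, c("alpha", "weighted_error")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$round, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Boosting round", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pb_selection_report <- function(object, ...) {
  scores <- object$scores
  scores$algorithm <- factor(scores$algorithm,
                             levels = object$summary$algorithm)
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$algorithm, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = paste0("Outer-fold ", object$metric)) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
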