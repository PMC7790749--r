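# Cohort-level validation: per-gene case/control odds-ratio enrichment
# stratified by predicted class, and survival stratification of patients by
# predicted genotype group. Carrier counts are per patient per gene (a
# carrier counts once regardless of variant multiplicity); training-set
# variants are assumed excluded upstream.

#' Per-gene carrier odds ratio with Woolf confidence interval
#'
#' For each row of a carrier-count table (`a` case carriers, `b` case
#' non-carriers, `c` reference carriers, `d` reference non-carriers) the
#' cross-product odds ratio `ad / bc` with the Woolf (log-normal) 95% CI
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero, the Haldane-Anscombe correction adds 0.5 to all four cells of that
#' row (flagged in `corrected`).
#'
#' @param data Tibble with non-negative integer columns `a`, `b`, `c`, `d`
#'   (and typically `gene`/`stratum`).
#' @param conf_level Confidence level (default 0.95).
#' @return `data` with columns `or`, `ci_low`, `ci_high`, `log_or`,
#'   `se_log_or`, `corrected` appended.
#' @export
#' @examples
#' gene_odds_ratio(tibble::tibble(gene = "MYH7", a = 20, b = 980, c = 10, d = 9990))
gene_odds_ratio <- function(data, conf_level = 0.95) {
  need <- c("a", "b", "c", "d")
  if (!all(need %in% names(data))) {
    pb_usage_error("`data` must have columns a, b, c, d.")
  }
  cells <- as.matrix(data[need])
  if (any(cells < 0)) pb_domain_error("Carrier counts must be non-negative.")
  if (any(data$a + data$b <= 0) || any(data$c + data$d <= 0)) {
    pb_domain_error("Cohort sizes (a+b and c+d) must be positive.")
  }
  corrected <- apply(cells == 0, 1, any)
  adj <- cells + 0.5 * corrected
  z <- qnorm(1 - (1 - conf_level) / 2)
  log_or <- unname(log(adj[, "a"]) + log(adj[, "d"]) - log(adj[, "b"]) - log(adj[, "c"]))
  se <- unname(sqrt(rowSums(1 / adj)))
  corrected <- unname(corrected)
  dplyr::mutate(as_tibble(data),
    or = exp(log_or), ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se),
    log_or = log_or, se_log_or = se, corrected = corrected
  )
}

#' Stratified odds-ratio comparison against the all-rare baseline
#'
#' For one or more genes with carrier counts per stratum (an `all-rare`
#' baseline plus predicted classes), computes each stratum's odds ratio and
#' a two-sided z-test on the difference of log odds ratios against the
#' gene's baseline, with variance equal to the sum of the two Woolf
#' variances. The independence approximation is conservative here because
#' strata share the same cohorts; `p_vs_baseline` is `NA` on the baseline
#' rows themselves.
#'
#' @param data Tibble with columns `gene`, `stratum`, `a`, `b`, `c`, `d`;
#'   every gene must include a `baseline` stratum row.
#' @param baseline Name of the baseline stratum (default `"all-rare"`).
#' @return Per-row odds-ratio results with `log_or_diff`, `statistic` and
#'   `p_vs_baseline` appended.
#' @export
stratified_or_comparison <- function(data, baseline = "all-rare") {
  if (!all(c("gene", "stratum") %in% names(data))) {
    pb_usage_error("`data` must have columns gene and stratum.")
  }
  res <- gene_odds_ratio(data)
  base <- res |>
    filter(.data$stratum == baseline) |>
    select("gene", base_log_or = "log_or", base_se = "se_log_or")
  missing_base <- setdiff(unique(res$gene), base$gene)
  if (length(missing_base)) {
    pb_usage_error(paste0(
      "No '", baseline, "' baseline stratum for gene(s): ",
      paste(missing_base, collapse = ", ")
    ))
  }
  res |>
    left_join(base, by = "gene") |>
    mutate(
      log_or_diff = .data$log_or - .data$base_log_or,
      statistic = .data$log_or_diff / sqrt(.data$se_log_or^2 + .data$base_se^2),
      p_vs_baseline = ifelse(.data$stratum == baseline, NA_real_,
                             2 * pnorm(-abs(.data$statistic)))
    ) |>
    select(-"base_log_or", -"base_se")
}

check_survival_cols <- function(data) {
  if (!all(c("age", "event") %in% names(data))) {
    pb_usage_error("Survival records need `age` and `event` columns.")
  }
  if (any(!is.finite(data$age)) || any(data$age <= 0)) {
    pb_domain_error("Ages must be finite and positive.")
  }
}

#' Kaplan-Meier survival curve and cumulative incidence
#'
#' Product-limit estimate of event-free survival over age, with the
#' cumulative incidence function `1 - S(age)`. Censored patients leave the
#' risk set after their censoring age.
#'
#' @param data Tibble with columns `age` (years at first composite event or
#'   censoring) and `event` (1 = event, 0 = censored).
#' @return A tibble with one row per distinct observed age: `age`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `cuminc`.
#' @export
#' @examples
#' km <- km_estimate(tibble::tibble(age = 1:4, event = c(1, 0, 1, 0)))
#' km$surv  # 3/4 after age 1, 3/8 after age 3
km_estimate <- function(data) {
  check_survival_cols(data)
  if (nrow(data) < 1L) pb_usage_error("Need at least one record.")
  fit <- survival::survfit(survival::Surv(age, event) ~ 1, data = data)
  tibble(
    age = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv, cuminc = 1 - fit$surv
  )
}

#' Cumulative incidence at a given age from a survival curve
#'
#' Steps the curve: returns `1 - S(age)` using the last estimate at or
#' before `age` (0 before the first event).
#'
#' @param curve A tibble from [km_estimate()].
#' @param age Age (years).
#' @return Cumulative incidence in \[0, 1\].
#' @export
risk_at_age <- function(curve, age) {
  i <- findInterval(age, curve$age)
  if (i == 0L) return(0)
  curve$cuminc[[i]]
}

#' Two-group log-rank test
#'
#' Standard log-rank test (hypergeometric expected events at each distinct
#' event age), 1 degree of freedom for two groups.
#'
#' @param data Tibble with columns `age`, `event`, `group` (two or more
#'   non-empty groups).
#' @return A one-row tibble: `statistic` (chi-square), `df`, `p.value`
#'   (`NA`-flagged when no events occur at all).
#' @export
logrank_test <- function(data) {
  check_survival_cols(data)
  if (!"group" %in% names(data) || length(unique(data$group)) < 2L) {
    pb_usage_error("`data` must contain >= 2 non-empty groups.")
  }
  if (sum(data$event) == 0L) {
    warn("Log-rank undefined: no events in either group.")
    return(tibble(statistic = NA_real_, df = NA_integer_, p.value = NA_real_))
  }
  sd <- survival::survdiff(survival::Surv(age, event) ~ group, data = data)
  df <- length(sd$n) - 1L
  tibble(statistic = sd$chisq, df = df,
         p.value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards ratios by genotype group
#'
#' Fits a Cox model with group indicators (Breslow tie handling) and
#' returns the hazard ratio, Wald confidence interval and p-value of each
#' group against the reference. Monotone-likelihood fits (e.g. a group with
#' no events) are flagged rather than raised.
#'
#' @param data Tibble with columns `age`, `event`, `group`.
#' @param reference Reference group (default: first unique value).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble, one row per non-reference group: `group`, `hr`,
#'   `ci_low`, `ci_high`, `p.value`, `flagged` (TRUE when the estimate did
#'   not converge to a finite hazard ratio).
#' @export
cox_hr <- function(data, reference = NULL, conf_level = 0.95) {
  check_survival_cols(data)
  groups <- unique(data$group)
  if (length(groups) < 2L) pb_usage_error("Need >= 2 groups for a Cox model.")
  if (sum(data$event) == 0L) {
    warn("Cox model undefined: no events.")
    return(tibble(group = setdiff(groups, reference %||% groups[[1]]),
                  hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  p.value = NA_real_, flagged = TRUE))
  }
  reference <- reference %||% groups[[1]]
  if (!reference %in% groups) pb_usage_error("`reference` is not a group in `data`.")
  dat <- dplyr::mutate(data, .group = stats::relevel(factor(group), ref = reference))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(age, event) ~ .group, data = dat,
                    ties = "breslow"),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  z <- qnorm(1 - (1 - conf_level) / 2)
  beta <- coef(fit)
  se <- unname(sqrt(diag(fit$var)))
  terms <- sub("^\\.group", "", names(beta))
  beta <- unname(beta)
  flagged <- warned | !is.finite(beta) | se > 100 | abs(beta) > 15
  tibble(
    group = terms,
    hr = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p.value = 2 * pnorm(-abs(beta / se)),
    flagged = unname(flagged)
  )
}

#' Risk difference at an age with a bootstrap confidence interval
#'
#' Difference in Kaplan-Meier cumulative incidence at `age` between exactly
#' two groups (first minus second in their order of appearance), with a
#' percentile bootstrap CI over patients resampled within group.
#'
#' @param data Tibble with columns `age`, `event`, `group` (two groups).
#' @param at_age Age (years) at which to compare cumulative incidence; must
#'   lie within the observed follow-up of both groups.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `at_age`, `group_a`, `group_b`, `risk_a`,
#'   `risk_b`, `risk_difference`, `ci_low`, `ci_high`, `n_boot`.
#' @export
outcome_risk_by_age <- function(data, at_age, n_boot = 2000, seed = 1,
                                conf_level = 0.95) {
  check_survival_cols(data)
  groups <- unique(data$group)
  if (length(groups) != 2L) pb_usage_error("Exactly two groups are required.")
  ga <- data[data$group == groups[[1]], ]
  gb <- data[data$group == groups[[2]], ]
  if (at_age > max(ga$age) || at_age > max(gb$age)) {
    warn("Requested age exceeds follow-up in a group; risk difference undefined.")
    return(tibble(at_age = at_age, group_a = groups[[1]], group_b = groups[[2]],
                  risk_a = NA_real_, risk_b = NA_real_,
                  risk_difference = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, n_boot = n_boot))
  }
  risk_of <- function(d) risk_at_age(km_estimate(d), at_age)
  ra <- risk_of(ga)
  rb <- risk_of(gb)
  boots <- pb_with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      risk_of(ga[sample(nrow(ga), replace = TRUE), ]) -
        risk_of(gb[sample(nrow(gb), replace = TRUE), ])
    }, numeric(1))
  })
  alpha <- 1 - conf_level
  ci <- quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  tibble(
    at_age = at_age, group_a = groups[[1]], group_b = groups[[2]],
    risk_a = ra, risk_b = rb, risk_difference = ra - rb,
    ci_low = ci[[1]], ci_high = ci[[2]], n_boot = n_boot
  )
}
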