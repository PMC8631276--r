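#' Univariate Cox proportional-hazards association
#'
#' Fits `Surv(time, event) ~ value` and reports the hazard ratio per unit
#' (or per standard deviation) with the Wald p-value.
#'
#' @param values Numeric covariate (methylation or expression), one per
#'   subject; must not be constant.
#' @param time,event Follow-up time and 0/1 event indicator.
#' @param per_sd Scale the covariate to unit standard deviation first.
#' @param min_events Minimum number of events required (default 10).
#' @return A one-row tibble: `hr`, `ci_lower`, `ci_upper`, `p`, `n`,
#'   `n_events`.
#' @export
cox_univariate <- function(values, time, event, per_sd = FALSE,
                           min_events = 10) {
  if (stats::sd(values) == 0) {
    stop_dmrlink("covariate is constant; Cox fit is degenerate",
                 "dmrlink_degenerate_fit_error")
  }
  if (sum(event) < min_events) {
    stop_dmrlink(paste0("need at least ", min_events, " events"),
                 "dmrlink_insufficient_data")
  }
  v <- if (per_sd) as.vector(scale(values)) else values
  fit <- survival::coxph(survival::Surv(time, event) ~ v)
  s <- summary(fit)
  tibble::tibble(
    hr = unname(s$coefficients[1, "exp(coef)"]),
    ci_lower = unname(s$conf.int[1, "lower .95"]),
    ci_upper = unname(s$conf.int[1, "upper .95"]),
    p = unname(s$coefficients[1, "Pr(>|z|)"]),
    n = length(values), n_events = sum(event)
  )
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square comparing the survival curves of two
#' groups.
#'
#' @param groups Two-level grouping vector.
#' @param time,event Follow-up time and 0/1 event indicator.
#' @return A list with `statistic` (chi-square, 1 df) and `p`.
#' @export
logrank_test <- function(groups, time, event) {
  g <- factor(groups)
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    stop_dmrlink("log-rank test needs exactly 2 non-empty groups",
                 "dmrlink_validation_error")
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ g)
  stat <- fit$chisq
  list(statistic = unname(stat),
       p = unname(stats::pchisq(stat, df = 1, lower.tail = FALSE)))
}

#' Optimal survival cutoff by log-rank minimisation
#'
#' Scans candidate cutoffs at the value quantiles (default 0.1 to 0.9 in
#' steps of 0.05), keeps those yielding two groups each holding at least
#' `min_frac` of subjects, and returns the cutoff minimising the
#' log-rank p-value. The reported `p_min` is not corrected for the
#' cutoff search and is optimistic under the null; treat it as a
#' descriptive quantity unless permutation-adjusted.
#'
#' @param values Numeric biomarker values.
#' @param time,event Survival data.
#' @param probs Quantile grid of candidate cutoffs.
#' @param min_frac Minimum fraction of subjects in each group.
#' @param min_n Minimum number of subjects (default 20).
#' @return A list: `cutoff`, `p_min`, `statistic`, and the scanned
#'   `grid` tibble.
#' @export
optimal_cutoff <- function(values, time, event,
                           probs = seq(0.1, 0.9, by = 0.05),
                           min_frac = 0.1, min_n = 20) {
  n <- length(values)
  if (n < min_n) {
    stop_dmrlink(paste0("need at least ", min_n, " subjects"),
                 "dmrlink_insufficient_data")
  }
  if (stats::sd(values) == 0) {
    stop_dmrlink("constant values admit no cutoff",
                 "dmrlink_degenerate_fit_error")
  }
  cuts <- unique(stats::quantile(values, probs, names = FALSE))
  rows <- purrr::map(cuts, function(cv) {
    hi <- values > cv
    if (min(sum(hi), sum(!hi)) < max(1, floor(min_frac * n))) return(NULL)
    lr <- logrank_test(hi, time, event)
    tibble::tibble(cutoff = cv, statistic = lr$statistic, p = lr$p)
  }) |> dplyr::bind_rows()
  if (nrow(rows) == 0) {
    stop_dmrlink("no cutoff satisfies the group-size constraint",
                 "dmrlink_validation_error")
  }
  best <- rows[which.min(rows$p), ]
  list(cutoff = best$cutoff, p_min = best$p, statistic = best$statistic,
       grid = rows)
}

#' Combined methylation + expression survival stratification
#'
#' Joint grid search over one methylation and one expression cutoff.
#' The high-risk group is defined by the tumor-like side of each
#' variable (taken from the discovery-phase signs rather than searched,
#' to limit optimism): subjects whose methylation lies on the
#' `meth_high_risk` side of the methylation cutoff AND whose expression
#' lies on the `expr_high_risk` side of the expression cutoff, versus
#' all others. Returns the pair of cutoffs minimising the log-rank p,
#' alongside the single-variable optimal cutoffs for comparison.
#'
#' @param meth,expr Per-subject methylation and expression values.
#' @param time,event Survival data.
#' @param meth_high_risk,expr_high_risk `"low"` or `"high"`: which tail
#'   of each variable marks the high-risk group.
#' @param probs,min_frac,min_n As in [optimal_cutoff()].
#' @return A list: `cutoff_meth`, `cutoff_expr`, `p`, `statistic`,
#'   `p_meth_only`, `p_expr_only`.
#' @export
combined_stratification <- function(meth, expr, time, event,
                                    meth_high_risk = c("low", "high"),
                                    expr_high_risk = c("high", "low"),
                                    probs = seq(0.1, 0.9, by = 0.05),
                                    min_frac = 0.1, min_n = 20) {
  meth_high_risk <- match.arg(meth_high_risk)
  expr_high_risk <- match.arg(expr_high_risk)
  n <- length(meth)
  single_m <- optimal_cutoff(meth, time, event, probs, min_frac, min_n)
  single_e <- optimal_cutoff(expr, time, event, probs, min_frac, min_n)
  cuts_m <- unique(stats::quantile(meth, probs, names = FALSE))
  cuts_e <- unique(stats::quantile(expr, probs, names = FALSE))
  side <- function(v, cut, which_side) {
    if (which_side == "high") v > cut else v <= cut
  }
  best <- NULL
  for (cm in cuts_m) {
    m_risk <- side(meth, cm, meth_high_risk)
    for (ce in cuts_e) {
      risk <- m_risk & side(expr, ce, expr_high_risk)
      if (min(sum(risk), sum(!risk)) < max(1, floor(min_frac * n))) next
      lr <- logrank_test(risk, time, event)
      if (is.null(best) || lr$p < best$p) {
        best <- list(cutoff_meth = cm, cutoff_expr = ce,
                     p = lr$p, statistic = lr$statistic)
      }
    }
  }
  if (is.null(best)) {
    stop_dmrlink("no cutoff pair satisfies the group-size constraint",
                 "dmrlink_validation_error")
  }
  c(best, list(p_meth_only = single_m$p_min, p_expr_only = single_e$p_min))
}

#' Tumor-stage association by one-way ANOVA
#'
#' Compares biomarker values across tumor stages; stages with fewer than
#' 2 samples are dropped with a warning.
#'
#' @param values Numeric biomarker values.
#' @param stages Stage labels (ordinal categories).
#' @return A list with `statistic` (F), `p`, `df_between`, `df_within`.
#' @export
stage_association <- function(values, stages) {
  tab <- table(stages)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    rlang::warn(paste0("dropping stage group(s) with < 2 samples: ",
                       paste(small, collapse = ", ")))
    keep <- !stages %in% small
    values <- values[keep]
    stages <- stages[keep]
  }
  if (length(unique(stages)) < 2) {
    stop_dmrlink("need at least 2 stage groups with >= 2 samples",
                 "dmrlink_validation_error")
  }
  fit <- stats::aov(values ~ factor(stages))
  s <- summary(fit)[[1]]
  f <- s[["F value"]][1]
  list(statistic = f, p = s[["Pr(>F)"]][1],
       df_between = s[["Df"]][1], df_within = s[["Df"]][2])
}
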