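# Survival evaluation of signatures and group labels, plus the cohort-level
# comparison statistics (cross-tab percentages, rank tests).

#' Split samples at the median score
#'
#' Scores strictly above the median are `high`; scores at or below the
#' median are `low` (recorded tie rule).
#'
#' @param scores named numeric vector (>= 2 samples, not all identical).
#' @return named character vector (`high` / `low`).
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples")
  if (diff(range(scores)) == 0) stop("all scores identical; no split possible")
  m <- median(scores)
  setNames(ifelse(scores > m, "high", "low"), names(scores))
}

# Administrative censoring at the horizon (years).
truncate_horizon <- function(time, event, horizon) {
  over <- time > horizon
  event[over] <- 0L
  time[over] <- horizon
  list(time = time, event = event)
}

#' Kaplan-Meier curves and log-rank test for grouped survival
#'
#' Product-limit estimates per group with administrative censoring at the
#' horizon, plus the log-rank chi-square across groups.
#'
#' @param time follow-up in years.
#' @param event event indicator (1 = death/relapse, 0 = censored).
#' @param group group label per sample (each group non-empty).
#' @param horizon_years censoring horizon.
#' @return list: `fit` (a [survival::survfit] object), `statistic`,
#'   `p_value`, `n_groups`.
#' @export
km_logrank <- function(time, event, group, horizon_years = 20) {
  group <- as.factor(droplevels(as.factor(group)))
  if (any(table(group) == 0) || nlevels(group) < 2)
    stop("need at least two non-empty groups")
  tr <- truncate_horizon(time, as.integer(event), horizon_years)
  if (sum(tr$event) == 0) stop("no events within the horizon; log-rank undefined")
  dat <- data.frame(time = tr$time, event = tr$event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  p <- pchisq(sd$chisq, df = nlevels(group) - 1, lower.tail = FALSE)
  list(fit = fit, statistic = unname(sd$chisq), p_value = p,
       n_groups = nlevels(group))
}

#' Cox proportional-hazards model for a signature score
#'
#' Fits the score as a continuous covariate (partial likelihood, Efron tie
#' handling) and, additionally, the median-split binary factor. Hazard
#' ratios are per unit score and high-versus-low respectively, with 95%
#' confidence intervals. Monotone likelihood (perfect separation) is
#' flagged and the affected confidence bound reported as infinite.
#'
#' @param time,event as in [km_logrank()].
#' @param score per-sample signature score (must vary).
#' @param horizon_years censoring horizon.
#' @return list with elements `continuous` and `median_split`, each
#'   `(hr, ci_lower, ci_upper, p_value)`, plus `n`, `n_events`, `flagged`.
#' @export
cox_hr <- function(time, event, score, horizon_years = 20) {
  if (diff(range(score)) == 0) stop("score is constant; Cox model undefined")
  tr <- truncate_horizon(time, as.integer(event), horizon_years)
  if (sum(tr$event) == 0) stop("no events within the horizon")
  fit_one <- function(x) {
    dat <- data.frame(time = tr$time, event = tr$event, x = x)
    flagged <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(time, event) ~ x, data = dat,
                      ties = "efron"),
      warning = function(w) {
        if (grepl("infinite|converge", conditionMessage(w))) flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    ci <- s$conf.int[1, c("lower .95", "upper .95")]
    if (flagged) ci <- c(0, Inf)
    list(hr = unname(exp(stats::coef(fit)[1])),
         ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
         p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
         flagged = flagged)
  }
  cont <- fit_one(score)
  split <- median_split(score)
  bin <- fit_one(as.numeric(split == "high"))
  list(continuous = cont, median_split = bin,
       n = length(score), n_events = sum(tr$event),
       flagged = cont$flagged || bin$flagged)
}

#' Percentages by category with a chi-square test
#'
#' For each category, the nearest-integer percentage `100 * num / den`, plus
#' Pearson's chi-square on the implied 2 x k table
#' `(num, den - num)` across categories (k >= 2).
#'
#' @param numerators,denominators equal-length (optionally named) counts
#'   with `num <= den` and `den > 0`.
#' @return list: `percent` (named integer vector), `statistic`, `p_value`
#'   (`NA` for a single category).
#' @export
crosstab_percent <- function(numerators, denominators) {
  if (length(numerators) != length(denominators))
    stop("numerators and denominators must have equal length")
  if (any(denominators <= 0)) stop("zero or negative denominator")
  if (any(numerators < 0 | numerators > denominators))
    stop("numerators must lie in [0, denominator]")
  pct <- round(100 * numerators / denominators)
  names(pct) <- names(numerators)
  if (length(numerators) >= 2) {
    tab <- rbind(numerators, denominators - numerators)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(percent = pct, statistic = unname(ct$statistic),
         p_value = unname(ct$p.value))
  } else {
    list(percent = pct, statistic = NA_real_, p_value = NA_real_)
  }
}

#' Rank-based group comparisons
#'
#' Wilcoxon rank-sum (exactly two groups) or Kruskal-Wallis (two or more),
#' with tie correction, wrapping the standard routines.
#'
#' @param values numeric vector.
#' @param labels group label per value.
#' @param kind `"wilcoxon"` or `"kruskal_wallis"`.
#' @return list: `statistic`, `p_value`.
#' @export
rank_tests <- function(values, labels, kind = c("wilcoxon", "kruskal_wallis")) {
  kind <- match.arg(kind)
  labels <- droplevels(as.factor(labels))
  if (any(table(labels) == 0)) stop("empty group")
  if (kind == "wilcoxon") {
    if (nlevels(labels) != 2) stop("wilcoxon requires exactly two groups")
    ht <- wilcox.test(values ~ labels, exact = FALSE, correct = FALSE)
  } else {
    if (nlevels(labels) < 2) stop("kruskal-wallis requires at least two groups")
    ht <- kruskal.test(values, labels)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
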