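#' Build a prediction-delta table
#'
#' @param sample_id Sample identifiers.
#' @param predicted_age,chronological_age Ages in years.
#' @param condition Categorical condition labels (two levels for the tests
#'   below).
#' @return Data frame with a `delta = predicted - chronological` column.
#' @export
make_delta_table <- function(sample_id, predicted_age, chronological_age,
                             condition) {
  data.frame(
    sample_id = sample_id,
    predicted_age = predicted_age,
    chronological_age = chronological_age,
    delta = predicted_age - chronological_age,
    condition = as.character(condition),
    stringsAsFactors = FALSE
  )
}

#' Two-sample t-test on prediction errors by condition
#'
#' Welch (unequal-variance) t-test of `delta` between the two condition
#' groups. Degenerate inputs where both groups are constant with equal means
#' return t = 0, p = 1.
#'
#' @param deltas A delta table from [make_delta_table()].
#' @return List with `t`, `p_value`, `group_means`, `groups`.
#' @export
group_ttest <- function(deltas) {
  lv <- sort(unique(deltas$condition))
  if (length(lv) != 2) stop("condition must have exactly two levels")
  g1 <- deltas$delta[deltas$condition == lv[1]]
  g2 <- deltas$delta[deltas$condition == lv[2]]
  if (length(g1) < 2 || length(g2) < 2) {
    stop("each condition group needs at least 2 samples")
  }
  means <- stats::setNames(c(mean(g1), mean(g2)), lv)
  if (stats::sd(g1) < 1e-12 && stats::sd(g2) < 1e-12) {
    if (abs(means[1] - means[2]) < 1e-12) {
      return(list(t = 0, p_value = 1, group_means = means, groups = lv))
    }
    return(list(t = Inf * sign(means[2] - means[1]), p_value = 0,
                group_means = means, groups = lv))
  }
  tt <- stats::t.test(g2, g1, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       group_means = means, groups = lv)
}

#' Age-adjusted condition effect on prediction error
#'
#' Fits `delta ~ 1 + chronological_age + condition` by OLS, accounting for
#' age-dependent clock bias (e.g. overestimation of young donors) before
#' estimating the condition effect in years. The reference level is the
#' lexicographically first condition label. Warns when the two groups' age
#' ranges do not overlap (effect confounded with age).
#'
#' @param deltas A delta table from [make_delta_table()].
#' @param conf_level Confidence level for the effect interval.
#' @return List with `effect_years`, `p_value`, `ci` (confidence interval),
#'   `reference`, `coefficients`.
#' @export
age_adjusted_effect <- function(deltas, conf_level = 0.95) {
  lv <- sort(unique(deltas$condition))
  if (length(lv) != 2) stop("condition must have exactly two levels")
  a1 <- range(deltas$chronological_age[deltas$condition == lv[1]])
  a2 <- range(deltas$chronological_age[deltas$condition == lv[2]])
  if (a1[2] < a2[1] || a2[2] < a1[1]) {
    warning("condition groups have non-overlapping age ranges; ",
            "the effect is confounded with age")
  }
  cond <- factor(deltas$condition, levels = lv)
  fit <- stats::lm(delta ~ chronological_age + condition,
                   data = data.frame(delta = deltas$delta,
                                     chronological_age =
                                       deltas$chronological_age,
                                     condition = cond))
  term <- paste0("condition", lv[2])
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, term, level = conf_level)
  list(effect_years = unname(stats::coef(fit)[term]),
       p_value = sm[term, "Pr(>|t|)"],
       ci = as.vector(ci),
       reference = lv[1],
       coefficients = stats::coef(fit))
}
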