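#' Decision curve: net benefit by probability threshold
#'
#' Net benefit of flagging visits with fitted probability at or above
#' each threshold t: `TP/n - FP/n * t/(1-t)`, compared against treating
#' all visits as users (`nb_all = prev - (1-prev) * t/(1-t)`) and
#' treating none (`nb_none = 0`).
#'
#' @param predictions Fitted utilization probabilities.
#' @param outcome Binary 0/1 outcome.
#' @param grid Threshold grid in (0, 1); default 0.001 steps over
#'   (0, 0.99].
#' @return Tibble of class `decision_curve` with columns `threshold`,
#'   `nb_model`, `nb_all`, `nb_none`; attributes `positive_range`
#'   (thresholds where the model's net benefit is positive) and
#'   `value_add_range` (where it beats both comparators), plus
#'   `prevalence`.
#' @export
net_benefit_curve <- function(predictions, outcome,
                              grid = seq(0.001, 0.99, by = 0.001)) {
  outcome <- as.integer(outcome)
  if (any(grid <= 0 | grid >= 1)) abort("grid thresholds must be in (0, 1).")
  if (length(unique(outcome)) < 2) abort("both outcome classes must be present.")
  n <- length(outcome)
  prev <- mean(outcome)
  # counts of {p >= t} among events/non-events via sorted scores
  sp_event <- sort(predictions[outcome == 1])
  sp_non <- sort(predictions[outcome == 0])
  tp <- length(sp_event) - findInterval(grid, sp_event, left.open = TRUE)
  fp <- length(sp_non) - findInterval(grid, sp_non, left.open = TRUE)
  w <- grid / (1 - grid)
  curve <- tibble(
    threshold = grid,
    nb_model = tp / n - fp / n * w,
    nb_all = prev - (1 - prev) * w,
    nb_none = 0
  )
  pos <- curve$threshold[curve$nb_model > 0]
  add <- curve$threshold[curve$nb_model > pmax(curve$nb_all, curve$nb_none)]
  structure(
    curve,
    class = c("decision_curve", class(curve)),
    prevalence = prev,
    positive_range = if (length(pos)) range(pos) else c(NA_real_, NA_real_),
    value_add_range = if (length(add)) range(add) else c(NA_real_, NA_real_)
  )
}

#' Cost:benefit odds implied by a probability threshold
#'
#' A threshold t corresponds to odds t/(1-t): e.g. t = 0.20 encodes a
#' 1:4 cost-benefit tradeoff.
#'
#' @param t Threshold strictly inside (0, 1).
#' @return The odds t/(1-t).
#' @export
threshold_odds <- function(t) {
  if (any(t <= 0 | t >= 1)) abort("threshold must lie strictly in (0, 1).")
  t / (1 - t)
}

#' Calibrate the decision threshold to industry utilization intensity
#'
#' Among grid thresholds where the model adds value over treat-all and
#' treat-none, picks the one whose flagged rate (share of visits with
#' fitted probability at or above t) is closest to the observed
#' utilization rate, so classification neither inflates nor deflates
#' utilization relative to industry standards. Ties break to the
#' smaller threshold.
#'
#' @param predictions Fitted probabilities.
#' @param outcome Binary 0/1 outcome (its mean is the calibration
#'   target unless `target_rate` is given).
#' @param curve A [net_benefit_curve()]; computed if omitted.
#' @param target_rate Optional explicit utilization intensity to match,
#'   e.g. from a reference set of industry-leading facilities.
#' @return List of class `threshold_calibration`: `threshold`,
#'   `flagged_rate`, `target_rate`, `odds` (t/(1-t)).
#' @export
calibrate_threshold <- function(predictions, outcome, curve = NULL,
                                target_rate = NULL) {
  curve <- curve %||% net_benefit_curve(predictions, outcome)
  rng <- attr(curve, "value_add_range")
  if (any(is.na(rng))) {
    abort("the model adds no value over treat-all/treat-none on this grid; set a threshold manually.")
  }
  cand <- curve$threshold[curve$nb_model > pmax(curve$nb_all, curve$nb_none)]
  target <- target_rate %||% mean(as.integer(outcome))
  sp <- sort(predictions)
  flagged <- (length(sp) - findInterval(cand, sp, left.open = TRUE)) / length(sp)
  gap <- abs(flagged - target)
  best <- which(gap == min(gap))[1]  # candidates ascend, so first = smallest t
  structure(
    list(threshold = cand[best], flagged_rate = flagged[best],
         target_rate = target, odds = threshold_odds(cand[best])),
    class = "threshold_calibration"
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "threshold %.3f (cost:benefit odds %.3f); flagged rate %.4f vs target %.4f\n",
    x$threshold, x$odds, x$flagged_rate, x$target_rate))
  invisible(x)
}

#' Classify visits as concordant / over- / under-utilized
#'
#' A visit is over-utilized when the resource was used but its fitted
#' probability falls below the threshold, under-utilized when unused
#' with probability at or above the threshold (probabilities exactly at
#' the threshold count as expected use), and concordant otherwise.
#'
#' @param predictions Fitted probabilities.
#' @param outcome Binary 0/1 outcome.
#' @param threshold Decision threshold in (0, 1), typically from
#'   [calibrate_threshold()].
#' @return Tibble with `.fitted`, `outcome_used`, `expected_use`, and
#'   `label` (factor: concordant_used, concordant_unused, over, under);
#'   the threshold is attached as an attribute.
#' @export
classify_visits <- function(predictions, outcome, threshold) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1).")
  outcome <- as.integer(outcome)
  expected <- predictions >= threshold
  label <- dplyr::case_when(
    outcome == 1 & !expected ~ "over",
    outcome == 0 & expected ~ "under",
    outcome == 1 ~ "concordant_used",
    TRUE ~ "concordant_unused"
  )
  out <- tibble(
    .fitted = predictions,
    outcome_used = outcome,
    expected_use = expected,
    label = factor(label, levels = c("concordant_used", "concordant_unused",
                                     "over", "under"))
  )
  attr(out, "threshold") <- threshold
  out
}

#' Summarise misutilization of classified visits
#'
#' @param classified Output of [classify_visits()].
#' @return One-row tibble: `n`, `mis_rate`, `over_rate`, `under_rate`
#'   (proportions of all visits), `over_share`, `under_share`
#'   (proportions of misutilized visits), `flagged_rate` (share with
#'   fitted probability at or above the threshold), `threshold`.
#' @export
misutilization_summary <- function(classified) {
  n <- nrow(classified)
  over <- sum(classified$label == "over")
  under <- sum(classified$label == "under")
  mis <- over + under
  tibble(
    n = n,
    mis_rate = mis / n,
    over_rate = over / n,
    under_rate = under / n,
    over_share = if (mis > 0) over / mis else NA_real_,
    under_share = if (mis > 0) under / mis else NA_real_,
    flagged_rate = mean(classified$expected_use),
    threshold = attr(classified, "threshold")
  )
}
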