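# placement values underpinning DeLong's nonparametric AUC machinery:
# v10[i] = P-hat(score of event i exceeds a non-event score), ties 1/2
delong_placements <- function(predictions, outcome) {
  outcome <- as.integer(outcome)
  if (length(predictions) != length(outcome)) {
    abort("predictions and outcome must have equal length.")
  }
  x <- predictions[outcome == 1]
  y <- predictions[outcome == 0]
  m <- length(x)
  n <- length(y)
  if (m == 0 || n == 0) abort("both outcome classes must be present.")
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rx) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' AUC with DeLong variance and confidence interval
#'
#' The AUC is the Mann-Whitney two-sample statistic (ties counted one
#' half); its variance comes from the DeLong structural components
#' (placement values), and the 95% interval is normal-theory, truncated
#' to \[0, 1\].
#'
#' @param predictions Numeric risk scores.
#' @param outcome Binary 0/1 outcome.
#' @return List of class `auc_estimate` with `auc`, `variance`, `ci95`.
#' @export
auc_delong <- function(predictions, outcome) {
  pl <- delong_placements(predictions, outcome)
  s10 <- if (pl$m > 1) var(pl$v10) else 0
  s01 <- if (pl$n > 1) var(pl$v01) else 0
  v <- s10 / pl$m + s01 / pl$n
  half <- qnorm(0.975) * sqrt(v)
  structure(
    list(auc = pl$auc, variance = v,
         ci95 = c(max(0, pl$auc - half), min(1, pl$auc + half))),
    class = "auc_estimate"
  )
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.4f (95%% CI %.4f-%.4f)\n", x$auc, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Paired DeLong test for an AUC difference
#'
#' Compares two correlated AUCs computed on the same visits, using the
#' covariance of their DeLong structural components. Identical
#' prediction vectors give a difference of 0 with p = 1.
#'
#' @param predictions_a,predictions_b Risk scores from two models over
#'   the same visits.
#' @param outcome Binary 0/1 outcome.
#' @return Tibble with `auc_a`, `auc_b`, `auc_diff`, `conf.low`,
#'   `conf.high`, `p.value`.
#' @export
compare_auc_delong <- function(predictions_a, predictions_b, outcome) {
  if (length(predictions_a) != length(predictions_b)) {
    abort("the two prediction vectors must cover the same visits.")
  }
  pa <- delong_placements(predictions_a, outcome)
  pb <- delong_placements(predictions_b, outcome)
  d10 <- pa$v10 - pb$v10
  d01 <- pa$v01 - pb$v01
  v <- (if (pa$m > 1) var(d10) else 0) / pa$m +
    (if (pa$n > 1) var(d01) else 0) / pa$n
  diff <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    p <- if (abs(diff) < 1e-12) 1 else 0
    half <- 0
  } else {
    z <- diff / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    half <- qnorm(0.975) * sqrt(v)
  }
  tibble(
    auc_a = pa$auc, auc_b = pb$auc, auc_diff = diff,
    conf.low = diff - half, conf.high = diff + half, p.value = p
  )
}
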