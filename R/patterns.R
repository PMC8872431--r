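#' Competing-resource co-usage patterns
#'
#' Encodes each visit's seven competing-resource bits as a bitstring
#' over the fixed alphabetical resource ordering (see
#' [resource_columns()]), summarises outcome utilization per observed
#' pattern, and tests for outcome differences across observed patterns
#' with a Pearson chi-square (no continuity correction; degrees of
#' freedom from observed patterns only). Expected cell counts below 5
#' are recorded in the result, not fatal.
#'
#' @param cohort Cohort tibble with the seven resource bits and
#'   `outcome_used`.
#' @return List of class `pattern_analysis`: `patterns` (tibble with
#'   `pattern`, `count`, `outcome_rate`), `statistic`, `df`, `p.value`,
#'   `n_possible` (2^7 = 128), `n_observed`, `low_expected_cells`.
#' @export
pattern_analysis <- function(cohort) {
  bits <- as.matrix(cohort[, resource_columns()])
  pattern <- apply(bits, 1, paste0, collapse = "")
  patterns <- tibble(pattern = pattern,
                     outcome = as.integer(cohort$outcome_used)) %>%
    group_by(.data$pattern) %>%
    summarise(count = dplyr::n(), outcome_rate = mean(.data$outcome),
              .groups = "drop") %>%
    arrange(desc(.data$count))
  if (nrow(patterns) < 2) {
    abort("need at least two observed resource patterns.")
  }
  tab <- table(pattern, factor(cohort$outcome_used, levels = 0:1))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(
    list(
      patterns = patterns,
      statistic = unname(ct$statistic),
      df = nrow(patterns) - 1L,
      p.value = unname(pchisq(unname(ct$statistic), nrow(patterns) - 1L,
                              lower.tail = FALSE)),
      n_possible = as.integer(2^length(resource_columns())),
      n_observed = nrow(patterns),
      low_expected_cells = sum(ct$expected < 5)
    ),
    class = "pattern_analysis"
  )
}

#' @export
print.pattern_analysis <- function(x, ...) {
  cat(sprintf(
    "%d of %d possible resource patterns observed; chi-square %.1f on %d df (p %s)\n",
    x$n_observed, x$n_possible, x$statistic, x$df, format.pval(x$p.value)))
  invisible(x)
}

# log-likelihood of a 2x2 table under the bivariate-normal liability
# model with margins fixed at (h, k) and latent correlation rho
tetrachoric_loglik <- function(rho, counts, h, k) {
  p11 <- mvtnorm::pmvnorm(upper = c(h, k), corr = matrix(c(1, rho, rho, 1), 2))
  p11 <- min(max(as.numeric(p11), 1e-12), 1 - 1e-12)
  p1 <- pnorm(h)
  p2 <- pnorm(k)
  probs <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
  probs <- pmax(probs, 1e-12)
  sum(counts * log(probs))
}

#' Maximum-likelihood tetrachoric correlation of a 2x2 table
#'
#' Thresholds are fixed at the normal quantiles of the margins; the
#' latent correlation is found by one-dimensional likelihood
#' maximization over \[-0.999, 0.999\].
#'
#' @param table2x2 2x2 count matrix; rows = first indicator (1/0),
#'   columns = second indicator (1/0), with `[1, 1]` the joint-use
#'   cell.
#' @return List with `rho` (NA when a margin is empty, with
#'   `defined = FALSE`), `defined`, and the input table.
#' @export
tetrachoric_rho <- function(table2x2) {
  n <- sum(table2x2)
  m1 <- table2x2[1, 1] + table2x2[1, 2]
  m2 <- table2x2[1, 1] + table2x2[2, 1]
  if (m1 == 0 || m1 == n || m2 == 0 || m2 == n) {
    return(list(rho = NA_real_, defined = FALSE, table = table2x2))
  }
  h <- qnorm(m1 / n)
  k <- qnorm(m2 / n)
  cnt <- c(table2x2[1, 1], table2x2[1, 2], table2x2[2, 1], table2x2[2, 2])
  opt <- optimize(function(r) tetrachoric_loglik(r, cnt, h, k),
                  interval = c(-0.999, 0.999), maximum = TRUE,
                  tol = 1e-6)
  list(rho = opt$maximum, defined = TRUE, table = table2x2)
}

#' Tetrachoric correlations among resources and with the outcome
#'
#' Estimates the latent bivariate-normal correlation for all 21
#' competing-resource pairs plus the 7 resource-outcome pairs,
#' supporting network-style views of joint utilization.
#'
#' @param cohort Cohort tibble.
#' @return Tibble with `var1`, `var2`, `rho`, `defined`, and the four
#'   cell counts `n11`, `n10`, `n01`, `n00`.
#' @export
tetrachoric_correlations <- function(cohort) {
  vars <- c(resource_columns(), "outcome_used")
  res <- resource_columns()
  pairs <- rbind(
    t(utils::combn(res, 2)),
    cbind(res, "outcome_used")
  )
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- cohort[[pairs[i, 1]]]
    b <- cohort[[pairs[i, 2]]]
    tab <- matrix(c(sum(a == 1 & b == 1), sum(a == 1 & b == 0),
                    sum(a == 0 & b == 1), sum(a == 0 & b == 0)),
                  2, 2, byrow = TRUE)
    est <- tetrachoric_rho(tab)
    tibble(var1 = pairs[i, 1], var2 = pairs[i, 2], rho = est$rho,
           defined = est$defined, n11 = tab[1, 1], n10 = tab[1, 2],
           n01 = tab[2, 1], n00 = tab[2, 2])
  })
}
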