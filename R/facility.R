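#' Per-facility misutilization counts and rates
#'
#' Aggregates visit labels to facilities: volume, counts and rates of
#' mis-, over-, and under-utilized visits (mis = over + under).
#'
#' @param classified Output of [classify_visits()], row-aligned with
#'   `cohort`.
#' @param cohort Cohort tibble with `facility_id`.
#' @return Tibble with `facility_id`, `volume`, `n_over`, `n_under`,
#'   `n_mis`, `rate_over`, `rate_under`, `rate_mis`.
#' @export
facility_rates <- function(classified, cohort) {
  if (nrow(classified) != nrow(cohort)) {
    abort("classified labels and cohort must be row-aligned.")
  }
  tibble(facility_id = cohort$facility_id, label = classified$label) %>%
    group_by(.data$facility_id) %>%
    summarise(
      volume = dplyr::n(),
      n_over = sum(.data$label == "over"),
      n_under = sum(.data$label == "under"),
      .groups = "drop"
    ) %>%
    mutate(
      n_mis = .data$n_over + .data$n_under,
      rate_over = .data$n_over / .data$volume,
      rate_under = .data$n_under / .data$volume,
      rate_mis = .data$n_mis / .data$volume
    )
}

#' Pooled misutilization rate across facilities
#'
#' The Poisson maximum-likelihood estimate of a common per-visit event
#' rate with volume as exposure: total events over total visits.
#'
#' @param profiles Output of [facility_rates()] (or any tibble with
#'   `volume` and the requested count column).
#' @param kind `"mis"`, `"over"`, or `"under"`.
#' @return The pooled rate, a single number.
#' @export
pooled_rate <- function(profiles, kind = c("mis", "over", "under")) {
  kind <- match.arg(kind)
  v <- sum(profiles$volume)
  if (v <= 0) abort("total volume must be positive.")
  sum(profiles[[paste0("n_", kind)]]) / v
}

#' Exact Poisson upper-tail probability
#'
#' P(X >= c) for X ~ Poisson(mean), computed through the upper
#' regularized incomplete gamma function (numerically stable for large
#' means). `c = 0` gives 1.
#'
#' @param c Observed count(s), non-negative integers.
#' @param mean Poisson mean(s), positive.
#' @return Upper-tail probabilities in (0, 1].
#' @export
poisson_upper_p <- function(c, mean) {
  if (any(c < 0) || any(c != floor(c))) abort("counts must be non-negative integers.")
  if (any(mean <= 0)) abort("mean must be positive.")
  ppois(c - 1, lambda = mean, lower.tail = FALSE)
}

#' Flag facilities departing from the common rate
#'
#' Under the null that every facility shares the pooled per-visit rate,
#' each facility's count is Poisson with mean pooled-rate x volume;
#' facilities with one-sided upper-tail p strictly below `alpha` are
#' flagged. Ranking is deterministic: p ascending, then rate
#' descending, then facility id.
#'
#' @param profiles Output of [facility_rates()].
#' @param alpha Flagging level (default 0.01, strict inequality).
#' @param kinds Misutilization kinds to test.
#' @param leave_one_out Estimate the pooled rate excluding the facility
#'   under test.
#' @param adjust `"none"` (default, raw p-values) or `"BH"` for
#'   Benjamini-Hochberg.
#' @return Long tibble: `facility_id`, `kind`, `volume`, `count`,
#'   `rate`, `expected`, `p_upper`, `flagged`, ordered within kind by
#'   the ranking above. The pooled rates are attached as attribute
#'   `pooled_rates`.
#' @export
flag_facilities <- function(profiles, alpha = 0.01,
                            kinds = c("mis", "over", "under"),
                            leave_one_out = FALSE,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1).")
  pooled <- setNames(numeric(length(kinds)), kinds)
  out <- purrr::map_dfr(kinds, function(kind) {
    cnt <- profiles[[paste0("n_", kind)]]
    lam <- pooled_rate(profiles, kind)
    pooled[[kind]] <<- lam
    rate_hat <- if (leave_one_out) {
      (sum(cnt) - cnt) / (sum(profiles$volume) - profiles$volume)
    } else {
      lam
    }
    expected <- rate_hat * profiles$volume
    p <- poisson_upper_p(cnt, pmax(expected, .Machine$double.xmin))
    p_eff <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
    tibble(
      facility_id = profiles$facility_id,
      kind = kind,
      volume = profiles$volume,
      count = cnt,
      rate = cnt / profiles$volume,
      expected = expected,
      p_upper = p,
      flagged = p_eff < alpha
    ) %>%
      arrange(.data$p_upper, desc(.data$rate), .data$facility_id)
  })
  attr(out, "pooled_rates") <- pooled
  attr(out, "alpha") <- alpha
  out
}

#' Actual vs expected counts for flagged facilities
#'
#' Bubble-plot-ready table for one misutilization kind: flagged
#' facilities only, with actual count, expected count under the pooled
#' rate, and log volume.
#'
#' @param flags Output of [flag_facilities()].
#' @param kind One misutilization kind.
#' @return Tibble with `facility_id`, `actual`, `expected`,
#'   `log_volume`.
#' @export
bubble_data <- function(flags, kind = c("mis", "over", "under")) {
  kind <- match.arg(kind)
  flags %>%
    filter(.data$kind == !!kind, .data$flagged) %>%
    transmute(.data$facility_id, actual = .data$count, .data$expected,
              log_volume = log(.data$volume))
}

#' Regress facility misutilization rate on log volume
#'
#' Unweighted ordinary least squares of the facility rate (in percent)
#' on the natural log of facility volume.
#'
#' @param profiles Output of [facility_rates()], at least 3 facilities.
#' @param kind Misutilization kind.
#' @return One-row tibble: `outcome_kind`, `slope` (percentage points
#'   per unit log volume), `intercept`, `p.value`, `n_facilities`.
#' @export
volume_regression <- function(profiles, kind = c("mis", "over", "under")) {
  kind <- match.arg(kind)
  if (nrow(profiles) < 3) abort("need at least 3 facilities.")
  lv <- log(profiles$volume)
  if (sd(lv) == 0) abort("facility volumes are constant; log-volume slope undefined.")
  y <- 100 * profiles[[paste0("rate_", kind)]]
  fit <- lm(y ~ lv)
  sm <- summary(fit)
  tibble(
    outcome_kind = kind,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    p.value = sm$coefficients[2, 4],
    n_facilities = nrow(profiles)
  )
}

#' Top and bottom facilities by misutilization rate
#'
#' Among facilities with at least `min_volume` visits, the `k` highest
#' and lowest rates per kind; ties break by larger volume, then
#' facility id. Facilities with 0% rates are eligible for the bottom
#' table.
#'
#' @param profiles Output of [facility_rates()].
#' @param min_volume Minimum visits for eligibility (default 30).
#' @param k Rows per table (default 10).
#' @param kinds Misutilization kinds.
#' @return Tibble with `kind`, `end` (`"top"`/`"bottom"`),
#'   `facility_id`, `volume`, `count`, `rate`.
#' @export
extreme_tables <- function(profiles, min_volume = 30, k = 10,
                           kinds = c("mis", "over", "under")) {
  eligible <- profiles %>% filter(.data$volume >= min_volume)
  purrr::map_dfr(kinds, function(kind) {
    tab <- eligible %>%
      transmute(kind = kind, .data$facility_id, .data$volume,
                count = .data[[paste0("n_", kind)]],
                rate = .data[[paste0("rate_", kind)]])
    top <- tab %>%
      arrange(desc(.data$rate), desc(.data$volume), .data$facility_id) %>%
      head(k) %>% mutate(end = "top", .after = "kind")
    bottom <- tab %>%
      arrange(.data$rate, desc(.data$volume), .data$facility_id) %>%
      head(k) %>% mutate(end = "bottom", .after = "kind")
    dplyr::bind_rows(top, bottom)
  })
}
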