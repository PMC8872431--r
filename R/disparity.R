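#' Odds ratios of misutilization by a patient characteristic
#'
#' For each misutilization kind (`under`, `over`), fits a logistic
#' regression of the 0/1 label indicator (among all visits) on the
#' characteristic's dummy levels, and reports per-level odds ratios
#' with Wald 95% confidence intervals and two-sided p-values. By
#' default the model is unadjusted (the characteristic alone);
#' `adjusted = TRUE` conditions on all other categorical
#' characteristics in the cohort.
#'
#' @param classified Output of [classify_visits()], row-aligned with
#'   `cohort`.
#' @param cohort Cohort tibble.
#' @param characteristic Column name, e.g. `"race"`.
#' @param reference_level Reference category; defaults to white for
#'   race, traditional Medicare for payor, otherwise the modal level.
#' @param kinds Which misutilization kinds to model.
#' @param adjusted Adjust for the other categorical characteristics.
#' @return Tibble of class `odds_ratio_table`: `characteristic`,
#'   `level`, `reference`, `outcome_kind`, `or`, `conf.low`,
#'   `conf.high`, `p.value`, `n_events`. Levels with zero events are
#'   flagged with `NA` intervals rather than raising an error.
#' @export
#' @examples
#' cfg <- synthetic_config(n_facilities = 30, total_visits_target = 4000,
#'                         seed = 11)
#' cohort <- collapse_categories(simulate_cohort(cfg))
#' fit <- fit_utilization_model(cohort, "a")
#' cls <- classify_visits(fit$fitted_probabilities, cohort$outcome_used, 0.2)
#' misuse_odds_ratios(cls, cohort, "race")
misuse_odds_ratios <- function(classified, cohort, characteristic,
                               reference_level = NULL,
                               kinds = c("under", "over"),
                               adjusted = FALSE) {
  if (!characteristic %in% names(cohort)) {
    abort(paste0("characteristic '", characteristic, "' not in cohort."))
  }
  if (nrow(classified) != nrow(cohort)) {
    abort("classified labels and cohort must be row-aligned.")
  }
  ref <- reference_level %||% switch(
    characteristic,
    race = "white",
    payor = "medicare_traditional",
    names(sort(table(cohort[[characteristic]]), decreasing = TRUE))[1]
  )
  x <- cohort[[characteristic]]
  if (!ref %in% x) abort(paste0("reference level '", ref, "' not observed."))
  levels_other <- setdiff(sort(unique(x)), ref)
  n <- nrow(cohort)

  dm <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  dm <- cbind(dm, vapply(levels_other, function(l) as.double(x == l),
                         numeric(n)))
  colnames(dm) <- c("(Intercept)", levels_other)
  if (adjusted) {
    for (v in setdiff(categorical_columns(cohort), characteristic)) {
      lv <- sort(unique(cohort[[v]]))
      modal <- names(sort(table(cohort[[v]]), decreasing = TRUE))[1]
      for (l in setdiff(lv, modal)) {
        dm <- cbind(dm, as.double(cohort[[v]] == l))
        colnames(dm)[ncol(dm)] <- paste0(v, "=", l)
      }
    }
  }

  purrr::map_dfr(kinds, function(kind) {
    y <- as.integer(classified$label == kind)
    events_by_level <- tapply(y, x, sum)
    dead <- names(events_by_level)[events_by_level == 0]
    keep <- setdiff(levels_other, dead)
    cols <- c("(Intercept)", keep,
              if (adjusted) setdiff(colnames(dm),
                                    c("(Intercept)", levels_other)))
    est <- se <- setNames(rep(NA_real_, length(levels_other)), levels_other)
    if (sum(y) > 0) {
      fit <- suppressWarnings(
        glm.fit(dm[, cols, drop = FALSE], y, family = binomial(),
                control = list(maxit = 100))
      )
      w <- fit$weights
      xw <- dm[, cols, drop = FALSE] * sqrt(w)
      covb <- chol2inv(qr.R(qr(xw)))
      ses <- sqrt(diag(covb))
      names(ses) <- cols
      est[keep] <- fit$coefficients[keep]
      se[keep] <- ses[keep]
    }
    est <- unname(est)
    se <- unname(se)
    z <- est / se
    tibble(
      characteristic = characteristic,
      level = levels_other,
      reference = ref,
      outcome_kind = kind,
      or = exp(est),
      conf.low = exp(est - qnorm(0.975) * se),
      conf.high = exp(est + qnorm(0.975) * se),
      p.value = 2 * pnorm(-abs(z)),
      n_events = as.integer(events_by_level[levels_other])
    )
  }) %>%
    structure(class = c("odds_ratio_table", class(tibble())))
}

#' Forest-plot coordinates for an odds-ratio table
#'
#' Log-scale coordinates for each level, with the reference category
#' pinned at 0 and no interval. Round-trips: `exp()` of the returned
#' coordinates recovers the odds ratios.
#'
#' @param rows An `odds_ratio_table` from [misuse_odds_ratios()].
#' @return Tibble with `outcome_kind`, `level`, `log_or`, `log_lo`,
#'   `log_hi`, `is_reference`.
#' @export
forest_data <- function(rows) {
  if (!nrow(rows)) abort("need at least one odds-ratio row.")
  refs <- rows %>%
    distinct(.data$outcome_kind, .data$reference) %>%
    transmute(.data$outcome_kind, level = .data$reference, log_or = 0,
              log_lo = NA_real_, log_hi = NA_real_, is_reference = TRUE)
  est <- rows %>%
    transmute(.data$outcome_kind, .data$level, log_or = log(.data$or),
              log_lo = log(.data$conf.low), log_hi = log(.data$conf.high),
              is_reference = FALSE)
  dplyr::bind_rows(refs, est) %>% arrange(.data$outcome_kind, .data$level)
}

#' Forest plot of misutilization odds ratios
#'
#' @param rows An `odds_ratio_table`.
#' @return A ggplot: per-level log odds ratios with 95% intervals,
#'   faceted by misutilization kind, reference at 0.
#' @export
plot_forest <- function(rows) {
  fd <- forest_data(rows)
  ggplot(fd, aes(x = .data$log_or, y = .data$level)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$log_lo, xmax = .data$log_hi),
                   height = 0.2, na.rm = TRUE) +
    geom_point(aes(shape = .data$is_reference), na.rm = TRUE) +
    scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 5), guide = "none") +
    facet_wrap(~outcome_kind) +
    labs(x = "log odds ratio (vs reference)", y = NULL) +
    theme_minimal()
}
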