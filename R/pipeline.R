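#' Run the full misutilization pipeline
#'
#' Orchestrates every stage end to end: cohort input (a CSV path, an
#' in-memory cohort, or a synthetic configuration), first-visit
#' deduplication, category collapsing, descriptive statistics, the
#' three logistic utilization models with AUC comparison, resource
#' co-usage patterns and tetrachoric correlations, the decision curve
#' and threshold (calibrated or fixed), visit classification, race
#' odds ratios, and facility profiling with Poisson flagging and
#' log-volume regressions. When `outdir` is given, tabular artifacts
#' (CSV/JSON) and a manifest with the configuration hash are written;
#' figures are optional and never required for the tabular outputs.
#'
#' @param input A cohort tibble, a CSV path readable by
#'   [read_cohort()], or `NULL` to simulate from `synthetic_config`.
#' @param synthetic_config A [synthetic_config()] used when `input` is
#'   `NULL`.
#' @param covariate_sets Model sets to fit (default all of a, b, c).
#' @param threshold `"auto"` to calibrate against observed utilization
#'   intensity, or a fixed value in (0, 1).
#' @param alpha Facility flagging level.
#' @param or_characteristics Characteristics for the disparity odds
#'   ratios.
#' @param outdir Output directory for artifacts, or `NULL` for none.
#' @param figures Also write figure files (PNG) under `outdir`.
#' @param seed Seed recorded in the manifest; defaults to the synthetic
#'   config's seed when simulating.
#' @return A report bundle (list) with elements `descriptives`,
#'   `models`, `auc_comparison`, `patterns`, `tetrachoric`, `decision`,
#'   `summary`, `odds_ratios`, `facility`, `manifest`.
#' @export
run_pipeline <- function(input = NULL, synthetic_config = NULL,
                         covariate_sets = c("a", "b", "c"),
                         threshold = "auto", alpha = 0.01,
                         or_characteristics = "race",
                         outdir = NULL, figures = FALSE, seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e),
                   " (check the stage's inputs and configuration)"))
    })
  }
  if (!identical(threshold, "auto") &&
      (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)) {
    abort("threshold must be 'auto' or a number in (0, 1).")
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1).")

  cohort <- stage("ingest", {
    if (is.null(input)) {
      if (is.null(synthetic_config)) {
        abort("provide either an input cohort or a synthetic_config.")
      }
      simulate_cohort(synthetic_config)
    } else if (is.character(input)) {
      read_cohort(input)
    } else {
      as_tibble(input)
    }
  })
  seed <- seed %||% synthetic_config$seed %||% NA_integer_

  cohort <- stage("deduplicate", deduplicate_first_visit(cohort))
  cohort <- stage("collapse", collapse_categories(cohort))
  descriptives <- stage("descriptives", descriptive_stats(cohort))

  models <- stage("fit", {
    fits <- lapply(covariate_sets, function(s) fit_utilization_model(cohort, s))
    names(fits) <- covariate_sets
    fits
  })
  auc_comparison <- stage("auc", {
    aucs <- purrr::map_dfr(names(models), function(s) {
      est <- auc_delong(models[[s]]$fitted_probabilities, cohort$outcome_used)
      tibble(covariate_set = s, auc = est$auc,
             conf.low = est$ci95[1], conf.high = est$ci95[2])
    })
    delong <- if (all(c("a", "b") %in% names(models))) {
      compare_auc_delong(models[["a"]]$fitted_probabilities,
                         models[["b"]]$fitted_probabilities,
                         cohort$outcome_used)
    }
    list(aucs = aucs, delong_a_vs_b = delong)
  })
  patterns <- stage("patterns", pattern_analysis(cohort))
  tetra <- stage("tetrachoric", tetrachoric_correlations(cohort))

  main_fit <- models[[covariate_sets[1]]]
  p_hat <- main_fit$fitted_probabilities
  decision <- stage("decide", {
    curve <- net_benefit_curve(p_hat, cohort$outcome_used)
    cal <- if (identical(threshold, "auto")) {
      calibrate_threshold(p_hat, cohort$outcome_used, curve)
    } else {
      list(threshold = threshold, flagged_rate = mean(p_hat >= threshold),
           target_rate = mean(cohort$outcome_used),
           odds = threshold_odds(threshold))
    }
    list(curve = curve, calibration = cal)
  })
  classified <- stage("classify", {
    classify_visits(p_hat, cohort$outcome_used, decision$calibration$threshold)
  })
  summary_tbl <- misutilization_summary(classified)

  odds_ratios <- stage("disparity", {
    dplyr::bind_rows(lapply(or_characteristics, function(ch) {
      misuse_odds_ratios(classified, cohort, ch)
    }))
  })

  facility <- stage("profile", {
    profiles <- facility_rates(classified, cohort)
    flags <- flag_facilities(profiles, alpha = alpha)
    regressions <- dplyr::bind_rows(lapply(c("mis", "over", "under"),
                                           function(k) volume_regression(profiles, k)))
    list(profiles = profiles, flags = flags, regressions = regressions,
         extremes = extreme_tables(profiles))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("misutilizr")),
    r_version = R.version.string,
    seed = seed,
    n_visits = nrow(cohort),
    n_facilities = dplyr::n_distinct(cohort$facility_id),
    threshold_mode = if (identical(threshold, "auto")) "auto" else "fixed",
    threshold = decision$calibration$threshold,
    alpha = alpha,
    covariate_sets = covariate_sets,
    config_hash = rlang::hash(list(
      threshold, alpha, covariate_sets, or_characteristics, seed,
      if (is.null(input)) synthetic_config else "external-input"
    ))
  )

  bundle <- list(
    descriptives = descriptives, models = models,
    auc_comparison = auc_comparison, patterns = patterns,
    tetrachoric = tetra, decision = decision, summary = summary_tbl,
    odds_ratios = odds_ratios, facility = facility, manifest = manifest
  )
  if (!is.null(outdir)) write_report_bundle(bundle, classified, outdir, figures)
  invisible(bundle)
}

write_report_bundle <- function(bundle, classified, outdir, figures = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_csv(x, file.path(outdir, f))
  w(bundle$descriptives, "descriptive_stats.csv")
  for (s in names(bundle$models)) {
    jsonlite::write_json(
      list(covariate_set = s,
           coefficients = as.list(bundle$models[[s]]$coefficients),
           standard_errors = as.list(bundle$models[[s]]$standard_errors),
           reference_levels = bundle$models[[s]]$reference_levels,
           log_likelihood = bundle$models[[s]]$log_likelihood),
      file.path(outdir, paste0("model_", s, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  w(bundle$auc_comparison$aucs, "auc.csv")
  if (!is.null(bundle$auc_comparison$delong_a_vs_b)) {
    w(bundle$auc_comparison$delong_a_vs_b, "auc_delong_a_vs_b.csv")
  }
  w(bundle$patterns$patterns, "resource_patterns.csv")
  w(bundle$tetrachoric, "tetrachoric.csv")
  w(as_tibble(bundle$decision$curve), "decision_curve.csv")
  w(as_tibble(classified), "visit_labels.csv")
  jsonlite::write_json(as.list(bundle$summary),
                       file.path(outdir, "misutilization_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  w(bundle$odds_ratios, "odds_ratios.csv")
  w(bundle$facility$profiles, "facility_profiles.csv")
  w(bundle$facility$flags, "facility_flags.csv")
  w(bundle$facility$regressions, "volume_regressions.csv")
  w(bundle$facility$extremes, "facility_extremes.csv")
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (figures) {
    gg <- function(p, f) ggplot2::ggsave(file.path(outdir, f), p,
                                         width = 7, height = 5, dpi = 150)
    gg(autoplot(bundle$decision$curve), "decision_curve.png")
    gg(plot_facility_rates(bundle$facility$profiles), "facility_rates.png")
    gg(plot_forest(bundle$odds_ratios), "forest.png")
    gg(plot_flagged_bubbles(bundle$facility$flags, "mis"), "flagged_bubbles.png")
    gg(plot_volume_flag_comparison(bundle$facility$profiles,
                                   bundle$facility$flags, "mis"),
       "volume_flag_comparison.png")
    gg(plot_under_over(bundle$facility$profiles), "under_over.png")
  }
  invisible(outdir)
}
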