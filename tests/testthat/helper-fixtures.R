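# Fixtures are generated in code; the heavier cohorts are memoized so
# several test files can share one generation.

.fixture_cache <- new.env(parent = emptyenv())

`%||%` <- function(x, y) if (is.null(x)) y else x

# build a classified-labels object directly from a vector of labels,
# for stages that only consume labels (disparity, facility profiling)
labels_as_classified <- function(labels, threshold = 0.2) {
  tib <- tibble::tibble(
    .fitted = ifelse(labels == "under", 0.5,
                     ifelse(labels == "over", 0.05, 0.5)),
    outcome_used = as.integer(labels %in% c("over", "concordant_used")),
    expected_use = labels %in% c("under", "concordant_used"),
    label = factor(labels, levels = c("concordant_used", "concordant_unused",
                                      "over", "under"))
  )
  attr(tib, "threshold") <- threshold
  tib
}

# moderate-size, outlier-free, well-specified cohort + its config
cached_cohort <- function(n = 50000, seed = 2024) {
  key <- paste0("cohort_", n, "_", seed)
  if (!exists(key, envir = .fixture_cache)) {
    cfg <- synthetic_config(n_facilities = 200, total_visits_target = n,
                            outlier_plan = list(), seed = seed)
    cohort <- collapse_categories(simulate_cohort(cfg))
    assign(key, list(config = cfg, cohort = cohort), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_config <- function(seed = 1, n_facilities = 30, n = 3000, ...) {
  synthetic_config(n_facilities = n_facilities, total_visits_target = n,
                   outlier_plan = list(), seed = seed, ...)
}

# a config whose generative model is flat: all coefficients zero, so
# the outcome rate equals plogis(intercept) everywhere
flat_config <- function(rate, seed, n_facilities = 10, n = 10000, ...) {
  tc <- default_true_coefficients()
  tc$factors <- lapply(tc$factors, function(x) {x[] <- 0; x})
  tc$terms[] <- 0
  synthetic_config(n_facilities = n_facilities, total_visits_target = n,
                   true_intercept = qlogis(rate), true_coefficients = tc,
                   outlier_plan = list(), seed = seed, ...)
}

# ground-truth log-odds for each design column, relative to the design's
# reference levels (generator baselines need not coincide with them)
truth_for_design <- function(design, config) {
  tc <- config$true_coefficients
  vapply(colnames(design$matrix), function(cn) {
    if (cn == "(Intercept)") {
      ref_shift <- sum(vapply(names(design$reference_levels), function(v) {
        cf <- tc$factors[[v]]
        ref <- design$reference_levels[[v]]
        if (!is.null(cf) && ref %in% names(cf)) cf[[ref]] else 0
      }, numeric(1)))
      return(config$true_intercept + ref_shift)
    }
    if (grepl("=", cn, fixed = TRUE)) {
      var <- sub("=.*$", "", cn)
      lev <- sub("^[^=]*=", "", cn)
      cf <- tc$factors[[var]]
      # collapsed charity/indigent payors share one (equal) true coefficient
      if (var == "payor" && !is.null(cf) && "charity" %in% names(cf)) {
        cf <- c(cf, charity_indigent = unname(cf[["charity"]]))
      }
      ref <- design$reference_levels[[var]]
      lev_coef <- if (!is.null(cf) && lev %in% names(cf)) cf[[lev]] else 0
      ref_coef <- if (!is.null(cf) && ref %in% names(cf)) cf[[ref]] else 0
      return(lev_coef - ref_coef)
    }
    if (cn %in% names(tc$terms)) return(tc$terms[[cn]])
    0
  }, numeric(1))
}

# O(n^2) pair-counting AUC oracle (ties count one half)
auc_bruteforce <- function(pred, outcome) {
  x <- pred[outcome == 1]
  y <- pred[outcome == 0]
  total <- 0
  for (xi in x) total <- total + sum(xi > y) + 0.5 * sum(xi == y)
  total / (length(x) * length(y))
}

# tiny hand-checkable classified table
hand_classified <- function() {
  p <- c(0.10, 0.30, 0.30, 0.05, 0.25, 0.20, 0.50, 0.01, 0.90, 0.15)
  y <- c(1, 0, 1, 0, 0, 0, 1, 1, 1, 0)
  classify_visits(p, y, 0.2)
}
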