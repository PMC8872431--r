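#' Default categorical marginals for the synthetic cohort
#'
#' Marginal level probabilities for the patient-characteristic variables,
#' taken from the descriptive distribution of a large US all-payor
#' in-patient prostate-cancer cohort (n = 51,111). Payor keeps `charity`
#' and `indigent` as separate low-count levels so that downstream
#' category collapsing has real work to do.
#'
#' @return Named list; each element is a probability vector over the
#'   variable's levels, summing to 1.
#' @export
default_covariate_marginals <- function() {
  n <- 51111
  lapply(list(
    age_group = c(
      "<=45" = 170, "46-50" = 597, "51-55" = 1977, "56-60" = 4408,
      "61-65" = 6977, "66-70" = 8234, "71-75" = 8168, "76-80" = 7305,
      "81-85" = 6155, ">85" = 7120),
    race = c(
      american_indian = 206, asian = 929, black = 8572,
      pacific_islander = 200, unknown = 1037, white = 36848, other = 3319),
    payor = c(
      charity = 65, indigent = 6, commercial_indemnity = 2706,
      direct_employer_contract = 96, managed_care_capitated = 168,
      managed_care_non_capitated = 8223,
      medicaid_managed_care_capitated = 264,
      medicaid_managed_care_non_capitated = 1209,
      medicaid_traditional = 716, medicare_managed_care_capitated = 3373,
      medicare_managed_care_non_capitated = 9615,
      medicare_traditional = 22077, other_government = 1245,
      self_pay = 439, workers_compensation = 63, other = 846),
    point_of_origin = c(
      clinic = 7255, court_law_enforcement = 38,
      info_not_available = 431, physician_referral = 39417,
      transfer_hospital = 2607, transfer_snf_icf = 675,
      transfer_asc = 51, transfer_other_hcf = 427,
      transfer_hospice = 15, transfer_same_facility = 195),
    discharge_status = c(
      court_law_enforcement = 65, expired = 1673, home_health = 7732,
      home_self_care = 29527, hospice_home = 1414, hospice_medical = 1100,
      left_ama = 241, ltc_hospital = 235, rehab_facility = 1273,
      icf = 185, other_facility = 712, snf = 6478, swing_bed = 124,
      other = 352)
  ), function(x) x / n)
}

# prevalences of the seven competing resources (alphabetical order)
# and of the binary patient flags, from the same cohort
default_resource_prevalences <- function() {
  c(ct_other = 18630, miscellaneous = 841, mri_mra = 5158,
    nuclear_medicine = 2826, special_imaging = 3384,
    ultrasound = 6493, xray = 28969) / 51111
}

default_flag_prevalences <- function() {
  c(icd_principal = 14817, malignancy_history = 2775,
    cm_hypertension_unc = 21819, cm_fluid_electrolyte = 17098,
    cm_metastatic_cancer = 15257, cm_cardiac_arrhythmia = 14830,
    cm_hypertension_comp = 14584) / 51111
}

#' Default ground-truth log-odds coefficients
#'
#' The generative logistic model for the outcome resource: moderate
#' case-mix effects for patient characteristics and stronger positive
#' effects for competing-resource usage (visits consuming other imaging
#' tend to also use the outcome CT). Reference levels are white race,
#' traditional Medicare, modal age (66-70), physician referral, and
#' home/self-care discharge, matching the design-matrix coding used by
#' [build_design()].
#'
#' @return List with elements `factors` (named list of named coefficient
#'   vectors over non-reference levels) and `terms` (named vector for
#'   binary/continuous columns).
#' @export
default_true_coefficients <- function() {
  list(
    factors = list(
      age_group = c(
        "<=45" = -0.30, "46-50" = -0.25, "51-55" = -0.20, "56-60" = -0.10,
        "61-65" = -0.05, "71-75" = 0.05, "76-80" = 0.10, "81-85" = 0.15,
        ">85" = 0.20),
      race = c(
        american_indian = 0.05, asian = -0.10, black = 0.15,
        pacific_islander = 0.05, unknown = -0.05, other = -0.05),
      payor = c(
        charity = 0.10, indigent = 0.10, commercial_indemnity = -0.15,
        direct_employer_contract = -0.10, managed_care_capitated = -0.10,
        managed_care_non_capitated = -0.10,
        medicaid_managed_care_capitated = 0.05,
        medicaid_managed_care_non_capitated = 0.05,
        medicaid_traditional = 0.10, medicare_managed_care_capitated = -0.05,
        medicare_managed_care_non_capitated = -0.05,
        other_government = 0.05, self_pay = 0.20,
        workers_compensation = -0.10, other = 0.00),
      point_of_origin = c(
        clinic = -0.10, court_law_enforcement = 0.10,
        info_not_available = 0.00, transfer_hospital = 0.20,
        transfer_snf_icf = 0.15, transfer_asc = 0.00,
        transfer_other_hcf = 0.10, transfer_hospice = 0.00,
        transfer_same_facility = 0.10),
      discharge_status = c(
        court_law_enforcement = 0.00, expired = 0.30, home_health = 0.10,
        hospice_home = 0.20, hospice_medical = 0.20, left_ama = -0.10,
        ltc_hospital = 0.20, rehab_facility = 0.15, icf = 0.10,
        other_facility = 0.10, snf = 0.15, swing_bed = 0.10, other = 0.00)
    ),
    terms = c(
      ct_other = 0.90, miscellaneous = 0.20, mri_mra = 0.30,
      nuclear_medicine = 0.40, special_imaging = 0.30, ultrasound = 0.20,
      xray = 0.50, icd_principal = -0.50, malignancy_history = 0.20,
      los_days = 0.03, cm_hypertension_unc = -0.10,
      cm_fluid_electrolyte = 0.30, cm_metastatic_cancer = 0.60,
      cm_cardiac_arrhythmia = 0.10, cm_hypertension_comp = 0.10)
  )
}

# calibrated once by large-n Monte Carlo so that, under the default
# marginals and coefficients, the marginal outcome rate is ~0.1172
DEFAULT_TRUE_INTERCEPT <- -3.3403

#' Configuration for the synthetic administrative cohort
#'
#' Bundles everything the generator needs: facility volume law, cohort
#' size, the ground-truth logistic model for the outcome resource, the
#' latent correlation structure of the competing resources, categorical
#' marginals, and the planted-outlier plan.
#'
#' @param n_facilities Number of facilities.
#' @param total_visits_target Total visits across all facilities; the
#'   default matches the motivating cohort (51,111 visits, 1056
#'   facilities).
#' @param volume_law List `(meanlog, sdlog)` of the log-normal law for
#'   facility volumes (right-skewed; `sdlog = 0` degenerates to equal
#'   volumes).
#' @param true_intercept Log-odds intercept of the generative outcome
#'   model.
#' @param true_coefficients See [default_true_coefficients()].
#' @param resource_dependence 7x7 latent (tetrachoric) correlation matrix
#'   for the competing resources, or a single exchangeable correlation.
#' @param resource_prevalences Named vector of 7 marginal prevalences.
#' @param flag_prevalences Named vector of binary patient-flag
#'   prevalences.
#' @param covariate_marginals Named list of categorical level
#'   probabilities; see [default_covariate_marginals()].
#' @param los Mean and SD of the gamma length-of-stay distribution, days.
#' @param outlier_plan Tibble/data frame with columns `facility_id`,
#'   `mode` (`"over"`/`"under"`) and `odds_multiplier` (> 1), or `NULL`
#'   to resolve a default plan against the generated volumes (12 over-
#'   and 8 under-utilizers at multiplier 3 among facilities with >= 100
#'   visits), or an empty `list()` for no outliers.
#' @param seed Mandatory integer seed; every random draw in the
#'   generator flows from it.
#' @return A validated list of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_facilities = 50, total_visits_target = 2000,
#'                         seed = 1)
#' head(generate_facility_volumes(cfg))
synthetic_config <- function(n_facilities = 1056,
                             total_visits_target = 51111,
                             volume_law = list(meanlog = 3.38, sdlog = 1),
                             true_intercept = DEFAULT_TRUE_INTERCEPT,
                             true_coefficients = default_true_coefficients(),
                             resource_dependence = 0.3,
                             resource_prevalences = default_resource_prevalences(),
                             flag_prevalences = default_flag_prevalences(),
                             covariate_marginals = default_covariate_marginals(),
                             los = list(mean = 4.57, sd = 5.44),
                             outlier_plan = NULL,
                             seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory in synthetic_config().")
  }
  if (is.numeric(resource_dependence) && length(resource_dependence) == 1) {
    rho <- resource_dependence
    resource_dependence <- matrix(rho, 7, 7)
    diag(resource_dependence) <- 1
  }
  cfg <- structure(
    list(
      n_facilities = as.integer(n_facilities),
      total_visits_target = as.integer(total_visits_target),
      volume_law = volume_law,
      true_intercept = true_intercept,
      true_coefficients = true_coefficients,
      resource_dependence = resource_dependence,
      resource_prevalences = resource_prevalences,
      flag_prevalences = flag_prevalences,
      covariate_marginals = covariate_marginals,
      los = los,
      outlier_plan = outlier_plan,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_facilities < 2) abort("n_facilities must be >= 2.")
  if (!is.numeric(cfg$volume_law$sdlog) || cfg$volume_law$sdlog < 0) {
    abort("volume_law sdlog must be a non-negative number.")
  }
  if (cfg$total_visits_target < cfg$n_facilities) {
    abort("total_visits_target must be at least n_facilities (each facility gets >= 1 visit).")
  }
  R <- cfg$resource_dependence
  if (!is.matrix(R) || nrow(R) != 7 || ncol(R) != 7) {
    abort("resource_dependence must be a 7x7 correlation matrix.")
  }
  if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8) {
    abort("resource_dependence must be symmetric with unit diagonal.")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("resource_dependence must be positive semidefinite.")
  }
  probs <- c(cfg$resource_prevalences, cfg$flag_prevalences)
  if (any(probs <= 0 | probs >= 1)) {
    abort("resource/flag prevalences must lie strictly in (0, 1).")
  }
  if (!identical(names(cfg$resource_prevalences), resource_columns())) {
    abort("resource_prevalences must be named by resource_columns(), in order.")
  }
  for (v in names(cfg$covariate_marginals)) {
    p <- cfg$covariate_marginals[[v]]
    if (any(p <= 0 | p >= 1)) abort(paste0("marginal probabilities for ", v, " must be in (0, 1)."))
    if (abs(sum(p) - 1) > 1e-9) abort(paste0("marginal for ", v, " must sum to 1."))
  }
  if (!is.null(cfg$outlier_plan) && length(cfg$outlier_plan)) {
    op <- as_tibble(cfg$outlier_plan)
    if (!all(c("facility_id", "mode", "odds_multiplier") %in% names(op))) {
      abort("outlier_plan needs columns facility_id, mode, odds_multiplier.")
    }
    if (!all(op$mode %in% c("over", "under"))) abort("outlier mode must be 'over' or 'under'.")
    if (any(op$odds_multiplier <= 1)) abort("odds_multiplier must exceed 1.")
  }
  invisible(cfg)
}

#' Read a synthetic-cohort configuration from YAML
#'
#' Any field of [synthetic_config()] may appear in the file; omitted
#' fields keep their defaults. `resource_dependence` may be a scalar
#' exchangeable correlation or a full 7x7 matrix (list of rows). The
#' seed must be present.
#'
#' @param path YAML file path.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) abort("YAML config must declare a seed.")
  args <- list()
  for (fld in c("n_facilities", "total_visits_target", "true_intercept", "seed")) {
    if (!is.null(raw[[fld]])) args[[fld]] <- raw[[fld]]
  }
  if (!is.null(raw$volume_law)) args$volume_law <- raw$volume_law
  if (!is.null(raw$los)) args$los <- raw$los
  if (!is.null(raw$resource_dependence)) {
    rd <- raw$resource_dependence
    if (is.list(rd)) rd <- do.call(rbind, rd)
    args$resource_dependence <- rd
  }
  if (!is.null(raw$resource_prevalences)) {
    args$resource_prevalences <- unlist(raw$resource_prevalences)
  }
  if (!is.null(raw$flag_prevalences)) {
    args$flag_prevalences <- unlist(raw$flag_prevalences)
  }
  if (!is.null(raw$covariate_marginals)) {
    args$covariate_marginals <- lapply(raw$covariate_marginals, unlist)
  }
  if (!is.null(raw$true_coefficients)) {
    args$true_coefficients <- list(
      factors = lapply(raw$true_coefficients$factors, unlist),
      terms = unlist(raw$true_coefficients$terms)
    )
  }
  if (!is.null(raw$outlier_plan)) {
    args$outlier_plan <- dplyr::bind_rows(lapply(raw$outlier_plan, as_tibble))
  }
  do.call(synthetic_config, args)
}

#' Generate right-skewed facility volumes
#'
#' Draws raw volumes from the configured log-normal law, then allocates
#' the visit total by a multinomial with probabilities proportional to
#' the raw draws, after guaranteeing one visit per facility. The
#' returned integer volumes therefore sum exactly to
#' `total_visits_target` and preserve the skewness of the law.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with columns `facility_id`, `volume`.
#' @export
generate_facility_volumes <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_facilities
  withr::with_seed(config$seed, {
    raw <- if (config$volume_law$sdlog == 0) {
      rep(exp(config$volume_law$meanlog), n)
    } else {
      rlnorm(n, config$volume_law$meanlog, config$volume_law$sdlog)
    }
    extra <- config$total_visits_target - n
    alloc <- as.integer(rmultinom(1, extra, prob = raw))
    tibble(facility_id = seq_len(n), volume = 1L + alloc)
  })
}

#' Resolve the planted-outlier plan against generated volumes
#'
#' With `outlier_plan = NULL` in the config, picks the default plan:
#' among facilities with at least `min_volume` visits (ordered by
#' facility id), the first `n_over` become over-utilizers and the next
#' `n_under` under-utilizers, each at the given odds multiplier. An
#' explicit plan in the config is returned unchanged; an empty `list()`
#' yields no outliers.
#'
#' @param config A `synthetic_config`.
#' @param volumes Output of [generate_facility_volumes()].
#' @param n_over,n_under Counts of planted over/under-utilizing
#'   facilities.
#' @param odds_multiplier Outcome-odds multiplier (> 1); over-utilizers
#'   have their odds multiplied, under-utilizers divided.
#' @param min_volume Minimum facility volume eligible for planting.
#' @return Tibble with columns `facility_id`, `mode`, `odds_multiplier`
#'   (possibly zero rows).
#' @export
resolve_outlier_plan <- function(config, volumes, n_over = 12, n_under = 8,
                                 odds_multiplier = 3, min_volume = 100) {
  if (!is.null(config$outlier_plan)) {
    if (!length(config$outlier_plan)) {
      return(tibble(facility_id = integer(), mode = character(),
                    odds_multiplier = numeric()))
    }
    return(as_tibble(config$outlier_plan))
  }
  eligible <- volumes$facility_id[volumes$volume >= min_volume]
  eligible <- sort(eligible)
  k <- min(length(eligible), n_over + n_under)
  picked <- eligible[seq_len(k)]
  tibble(
    facility_id = picked,
    mode = rep(c("over", "under"), c(n_over, n_under))[seq_len(k)],
    odds_multiplier = odds_multiplier
  )
}

# per-visit ground-truth log-odds excluding the outlier offset
true_linear_predictor <- function(cohort, config) {
  tc <- config$true_coefficients
  eta <- rep(config$true_intercept, nrow(cohort))
  for (v in names(tc$factors)) {
    if (!v %in% names(cohort)) next
    cf <- tc$factors[[v]]
    hit <- cf[match(cohort[[v]], names(cf))]
    hit[is.na(hit)] <- 0
    eta <- eta + unname(hit)
  }
  for (trm in names(tc$terms)) {
    if (!trm %in% names(cohort)) next
    eta <- eta + tc$terms[[trm]] * cohort[[trm]]
  }
  eta
}

#' Generate the visit-level synthetic cohort
#'
#' Covariate levels are drawn i.i.d. from the configured marginals;
#' competing-resource bits by thresholding a latent 7-variate Gaussian
#' with the configured correlation at quantiles matching the marginal
#' prevalences (a Gaussian copula, so the latent correlations are the
#' tetrachoric correlations of the bits); length of stay from a gamma
#' law; and the outcome from the ground-truth logistic model, with
#' planted facilities' odds multiplied (over) or divided (under).
#'
#' @param config A [synthetic_config()].
#' @param volumes Facility volumes; defaults to
#'   [generate_facility_volumes()] under the same config.
#' @return Tibble with one row per visit. The resolved outlier plan is
#'   attached as attribute `outlier_plan`.
#' @export
generate_visits <- function(config, volumes = generate_facility_volumes(config)) {
  validate_synthetic_config(config)
  if (!all(c("facility_id", "volume") %in% names(volumes))) {
    abort("volumes must have columns facility_id and volume.")
  }
  if (nrow(volumes) != config$n_facilities) {
    abort("volumes has a different number of facilities than the config.")
  }
  plan <- resolve_outlier_plan(config, volumes)
  n <- sum(volumes$volume)
  cohort <- withr::with_seed(config$seed + 1L, {
    facility <- rep(volumes$facility_id, volumes$volume)
    out <- tibble(
      visit_id = seq_len(n),
      patient_id = seq_len(n),
      facility_id = facility,
      discharge_date = as.Date("2019-01-01") +
        sample.int(365L, n, replace = TRUE) - 1L
    )
    # latent Gaussian copula for the seven competing resources
    z <- matrix(rnorm(n * 7L), n, 7L) %*% chol(config$resource_dependence)
    thresholds <- qnorm(config$resource_prevalences)
    for (j in seq_along(resource_columns())) {
      out[[resource_columns()[j]]] <- as.integer(z[, j] < thresholds[j])
    }
    shape <- (config$los$mean / config$los$sd)^2
    out$los_days <- rgamma(n, shape = shape, rate = shape / config$los$mean)
    for (fl in names(config$flag_prevalences)) {
      out[[fl]] <- rbinom(n, 1L, config$flag_prevalences[[fl]])
    }
    for (v in names(config$covariate_marginals)) {
      p <- config$covariate_marginals[[v]]
      out[[v]] <- sample(names(p), n, replace = TRUE, prob = p)
    }
    eta <- true_linear_predictor(out, config)
    if (nrow(plan)) {
      offset <- log(plan$odds_multiplier) * ifelse(plan$mode == "over", 1, -1)
      shift <- offset[match(out$facility_id, plan$facility_id)]
      shift[is.na(shift)] <- 0
      eta <- eta + shift
    }
    out$outcome_used <- rbinom(n, 1L, plogis(eta))
    out
  })
  attr(cohort, "outlier_plan") <- plan
  cohort
}

#' Generate volumes and visits in one call
#'
#' @inheritParams generate_visits
#' @return The visit-level cohort tibble (see [generate_visits()]),
#'   with `volumes` attached as an attribute.
#' @export
simulate_cohort <- function(config) {
  volumes <- generate_facility_volumes(config)
  cohort <- generate_visits(config, volumes)
  attr(cohort, "volumes") <- volumes
  cohort
}

#' Ground-truth expected-use labels
#'
#' Evaluates the generative logistic model (without any planted-outlier
#' odds multiplier, i.e. industry-standard behaviour) on a cohort and
#' flags visits whose true utilization probability meets the threshold.
#' Serves as the oracle for classification-recovery checks.
#'
#' @param cohort A cohort tibble.
#' @param config The `synthetic_config` that generated it.
#' @param threshold Probability threshold in (0, 1); boundary values 0
#'   and 1 are allowed and give all/none flagged.
#' @return Tibble with `visit_id`, `true_prob`, `expected_use`.
#' @export
ground_truth_labels <- function(cohort, config, threshold) {
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0, 1].")
  p0 <- plogis(true_linear_predictor(cohort, config))
  tibble(
    visit_id = cohort$visit_id,
    true_prob = p0,
    expected_use = p0 >= threshold
  )
}

#' Write a cohort to CSV with a JSON truth sidecar
#'
#' The sidecar (same path with extension `.truth.json`) echoes the
#' configuration (intercept, coefficients, prevalences, marginals, law,
#' seed) and the per-facility planted odds multipliers, so any
#' downstream result can be checked against the generator's truth.
#'
#' @param cohort Cohort tibble from [generate_visits()].
#' @param path Output CSV path.
#' @param config The generating `synthetic_config` (optional; sidecar
#'   written only when supplied).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config = NULL) {
  readr::write_csv(as_tibble(cohort), path)
  if (!is.null(config)) {
    plan <- attr(cohort, "outlier_plan") %||%
      tibble(facility_id = integer(), mode = character(),
             odds_multiplier = numeric())
    truth <- list(
      seed = config$seed,
      n_facilities = config$n_facilities,
      total_visits_target = config$total_visits_target,
      volume_law = config$volume_law,
      true_intercept = config$true_intercept,
      true_coefficients = config$true_coefficients,
      resource_prevalences = as.list(config$resource_prevalences),
      flag_prevalences = as.list(config$flag_prevalences),
      covariate_marginals = lapply(config$covariate_marginals, as.list),
      resource_dependence = config$resource_dependence,
      outlier_plan = plan
    )
    sidecar <- paste0(sub("\\.csv$", "", path), ".truth.json")
    jsonlite::write_json(truth, sidecar, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }
  invisible(path)
}
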