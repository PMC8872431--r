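#' Fixed ordering of the competing imaging resources
#'
#' Seven alternative imaging modalities recorded per visit alongside the
#' outcome resource. The ordering is alphabetical and fixed so that
#' seven-digit co-usage bitstrings (see [pattern_analysis()]) are
#' reproducible across cohorts.
#'
#' @return Character vector of the seven competing-resource column names.
#' @export
#' @examples
#' resource_columns()
resource_columns <- function() {
  c("ct_other", "miscellaneous", "mri_mra", "nuclear_medicine",
    "special_imaging", "ultrasound", "xray")
}

# binary patient-level flags always present in a cohort
flag_columns <- function(cohort = NULL) {
  base <- c("icd_principal", "malignancy_history")
  if (is.null(cohort)) return(base)
  c(base[base %in% names(cohort)], grep("^cm_", names(cohort), value = TRUE))
}

# categorical patient-level variables present in a cohort
categorical_columns <- function(cohort) {
  known <- c("age_group", "race", "payor", "point_of_origin",
             "discharge_status", "ms_drg")
  known[known %in% names(cohort)]
}

#' Declared cohort schema
#'
#' Describes the visit-level table the pipeline consumes: identifier
#' columns, the binary outcome, the seven competing-resource bits,
#' binary patient flags, categorical characteristics, and continuous
#' terms. Used by [read_cohort()] for validation and typing.
#'
#' @param extra_flags Additional binary column names (e.g. comorbidity
#'   flags, conventionally prefixed `cm_`).
#' @param categoricals Categorical variable names expected in the table.
#' @return A list with class `cohort_schema`.
#' @export
cohort_schema <- function(extra_flags = character(),
                          categoricals = c("age_group", "race", "payor",
                                           "point_of_origin",
                                           "discharge_status")) {
  structure(
    list(
      id_cols = c("visit_id", "patient_id", "facility_id"),
      date_cols = "discharge_date",
      outcome = "outcome_used",
      resources = resource_columns(),
      flags = c("icd_principal", "malignancy_history", extra_flags),
      categoricals = categoricals,
      continuous = "los_days"
    ),
    class = "cohort_schema"
  )
}

bit_columns <- function(schema) {
  c(schema$outcome, schema$resources, schema$flags)
}
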