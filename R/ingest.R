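#' Read a visit-level cohort from CSV
#'
#' Validates the table against a declared schema: mandatory columns
#' must be present, binary columns must contain only 0/1, length of
#' stay must be non-negative. Unknown categorical values are preserved
#' as their own levels (they are collapsed later, not rejected).
#'
#' @param path CSV file with a header row.
#' @param schema A [cohort_schema()]; comorbidity columns (`cm_*`)
#'   found in the file are accepted as additional flags automatically.
#' @return A typed cohort tibble. The row count is reported via a
#'   message.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cm_extra <- setdiff(grep("^cm_", names(raw), value = TRUE), schema$flags)
  schema$flags <- c(schema$flags, cm_extra)
  mandatory <- c(schema$id_cols, schema$outcome, schema$resources,
                 schema$continuous)
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    abort(paste0("cohort file is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  present_bits <- intersect(bit_columns(schema), names(raw))
  for (col in present_bits) {
    bad <- which(!(raw[[col]] %in% c(0, 1)))
    if (length(bad)) {
      abort(paste0("column '", col, "' must be binary 0/1; offending row(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    raw[[col]] <- as.integer(raw[[col]])
  }
  if (any(raw$los_days < 0)) abort("los_days must be non-negative.")
  if ("discharge_date" %in% names(raw) && !inherits(raw$discharge_date, "Date")) {
    raw$discharge_date <- as.Date(raw$discharge_date)
  }
  for (col in intersect(schema$categoricals, names(raw))) {
    raw[[col]] <- as.character(raw[[col]])
  }
  inform(paste0("read_cohort: ", nrow(raw), " visits, ",
                dplyr::n_distinct(raw$facility_id), " facilities."))
  raw
}

#' Keep only each patient's first visit
#'
#' Retains, per patient, the record with the earliest discharge date;
#' ties are broken by the smallest visit id. Avoids over-weighting
#' patients with repeated admissions.
#'
#' @param cohort Cohort tibble with `patient_id`, `discharge_date`,
#'   `visit_id`.
#' @return Cohort with one row per patient, original row order within
#'   the survivors preserved.
#' @export
deduplicate_first_visit <- function(cohort) {
  cohort %>%
    group_by(.data$patient_id) %>%
    arrange(.data$discharge_date, .data$visit_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$visit_id)
}

#' Category-collapsing rules
#'
#' @param payor_merge Payor levels merged into one low-count category.
#' @param payor_merge_label Name of the merged payor level.
#' @param age_merge_max Upper age bound: age-group levels lying wholly
#'   at or below it are merged into a single youngest category.
#' @param discharge_min_share Discharge-status levels with share of
#'   total observations strictly below this are pooled into `other`.
#' @param flag_min_count Comorbidity flags and MS-DRG levels need at
#'   least this many visits to stay; rarer MS-DRGs pool into
#'   `drg_other_label`, rarer flags are dropped from the covariate set.
#' @param drg_other_label Pooled MS-DRG level name.
#' @return List of class `collapse_rules`.
#' @export
collapse_rules <- function(payor_merge = c("charity", "indigent"),
                           payor_merge_label = "charity_indigent",
                           age_merge_max = 45,
                           discharge_min_share = 0.001,
                           flag_min_count = 500,
                           drg_other_label = "other") {
  if (discharge_min_share <= 0 || discharge_min_share >= 1) {
    abort("discharge_min_share must be in (0, 1).")
  }
  if (flag_min_count < 1) abort("flag_min_count must be >= 1.")
  structure(
    list(payor_merge = payor_merge, payor_merge_label = payor_merge_label,
         age_merge_max = age_merge_max,
         discharge_min_share = discharge_min_share,
         flag_min_count = flag_min_count, drg_other_label = drg_other_label),
    class = "collapse_rules"
  )
}

# numeric upper bound of an age-group label like "<=45", "46-50", ">85"
age_upper_bound <- function(level) {
  vapply(level, function(x) {
    if (grepl("^>[0-9]+$", x)) return(Inf)
    nums <- as.numeric(regmatches(x, gregexpr("[0-9]+", x))[[1]])
    if (!length(nums)) return(NA_real_)
    max(nums)
  }, numeric(1))
}

#' Collapse sparse categories
#'
#' Applies the low-count pooling rules: charity/indigent payors merged;
#' age groups wholly at or below the bound merged into the youngest
#' category; discharge-status levels with share strictly below the
#' minimum pooled into `other`; comorbidity flags below the count
#' threshold dropped from the covariate set; MS-DRG levels below it
#' pooled into the catch-all label. The operation is idempotent.
#'
#' @param cohort Cohort tibble.
#' @param rules A [collapse_rules()].
#' @return The collapsed cohort, with a tibble of every merge/drop
#'   attached as attribute `collapse_report` (see [collapse_report()]).
#' @export
collapse_categories <- function(cohort, rules = collapse_rules()) {
  report <- list()
  note <- function(action, variable, detail) {
    report[[length(report) + 1]] <<- tibble(action = action,
                                            variable = variable,
                                            detail = detail)
  }
  n <- nrow(cohort)

  if ("payor" %in% names(cohort)) {
    hit <- cohort$payor %in% rules$payor_merge
    if (any(hit)) {
      note("merge", "payor",
           paste0(paste(sort(unique(cohort$payor[hit])), collapse = "+"),
                  " -> ", rules$payor_merge_label, " (", sum(hit), " visits)"))
      cohort$payor[hit] <- rules$payor_merge_label
    }
  }

  if ("age_group" %in% names(cohort)) {
    lv <- unique(cohort$age_group)
    young <- lv[age_upper_bound(lv) <= rules$age_merge_max]
    if (length(young) > 1) {
      label <- paste0("<=", rules$age_merge_max)
      note("merge", "age_group",
           paste0(paste(sort(young), collapse = "+"), " -> ", label))
      cohort$age_group[cohort$age_group %in% young] <- label
    }
  }

  if ("discharge_status" %in% names(cohort)) {
    share <- table(cohort$discharge_status) / n
    rare <- setdiff(names(share)[share < rules$discharge_min_share], "other")
    if (length(rare)) {
      note("merge", "discharge_status",
           paste0(paste(sort(rare), collapse = "+"), " -> other"))
      cohort$discharge_status[cohort$discharge_status %in% rare] <- "other"
    }
  }

  for (fl in grep("^cm_", names(cohort), value = TRUE)) {
    if (sum(cohort[[fl]]) < rules$flag_min_count) {
      note("drop", fl, paste0("count ", sum(cohort[[fl]]), " < ",
                              rules$flag_min_count))
      cohort[[fl]] <- NULL
    }
  }

  if ("ms_drg" %in% names(cohort)) {
    cnt <- table(cohort$ms_drg)
    rare <- setdiff(names(cnt)[cnt < rules$flag_min_count],
                    rules$drg_other_label)
    if (length(rare)) {
      note("merge", "ms_drg",
           paste0(length(rare), " level(s) with < ", rules$flag_min_count,
                  " visits -> ", rules$drg_other_label))
      cohort$ms_drg[cohort$ms_drg %in% rare] <- rules$drg_other_label
    }
  }

  attr(cohort, "collapse_report") <- if (length(report)) {
    dplyr::bind_rows(report)
  } else {
    tibble(action = character(), variable = character(), detail = character())
  }
  cohort
}

#' Report of applied collapsing rules
#'
#' @param cohort A cohort returned by [collapse_categories()].
#' @return Tibble with columns `action`, `variable`, `detail`.
#' @export
collapse_report <- function(cohort) {
  attr(cohort, "collapse_report") %||%
    abort("no collapse report attached; run collapse_categories() first.")
}

#' Build a design matrix for one covariate set
#'
#' Covariate sets follow the three-model comparison: `"a"` patient
#' characteristics plus the seven competing resources, `"b"` patient
#' characteristics only, `"c"` competing resources only. Categorical
#' variables are dummy-coded with declared reference levels (race:
#' white; payor: traditional Medicare; otherwise the modal level);
#' length of stay enters untransformed and continuous.
#'
#' @param cohort A collapsed cohort tibble.
#' @param covariate_set `"a"`, `"b"`, or `"c"`.
#' @param include_los Include `los_days` in the patient sets (default
#'   yes).
#' @return List of class `design_matrix` with elements `matrix`
#'   (numeric, intercept first), `reference_levels`, `covariate_set`,
#'   `outcome`.
#' @export
build_design <- function(cohort, covariate_set = c("a", "b", "c"),
                         include_los = TRUE) {
  covariate_set <- match.arg(covariate_set)
  n <- nrow(cohort)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  reference_levels <- list()

  add_cols <- function(X, cols) cbind(X, cols)

  if (covariate_set %in% c("a", "c")) {
    res <- as.matrix(cohort[, resource_columns()])
    storage.mode(res) <- "double"
    X <- add_cols(X, res)
  }
  if (covariate_set %in% c("a", "b")) {
    for (v in categorical_columns(cohort)) {
      lv <- sort(unique(cohort[[v]]))
      ref <- switch(v,
                    race = "white",
                    payor = "medicare_traditional",
                    names(sort(table(cohort[[v]]), decreasing = TRUE))[1])
      if (!ref %in% lv) ref <- names(sort(table(cohort[[v]]), decreasing = TRUE))[1]
      reference_levels[[v]] <- ref
      other <- setdiff(lv, ref)
      if (length(other)) {
        dm <- vapply(other, function(l) as.double(cohort[[v]] == l),
                     numeric(n))
        colnames(dm) <- paste0(v, "=", other)
        X <- add_cols(X, dm)
      }
    }
    fl <- flag_columns(cohort)
    if (length(fl)) {
      fm <- as.matrix(cohort[, fl])
      storage.mode(fm) <- "double"
      X <- add_cols(X, fm)
    }
    if (include_los && "los_days" %in% names(cohort)) {
      X <- add_cols(X, matrix(cohort$los_days, ncol = 1,
                              dimnames = list(NULL, "los_days")))
    }
  }

  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient after collapsing; aliased column(s): ",
                 paste(aliased, collapse = ", ")))
  }
  structure(
    list(matrix = X, reference_levels = reference_levels,
         covariate_set = covariate_set,
         outcome = as.integer(cohort$outcome_used)),
    class = "design_matrix"
  )
}

#' Descriptive statistics table
#'
#' One row per categorical level or binary flag with count and percent
#' (of all visits, to two decimals), plus mean/SD rows for continuous
#' variables.
#'
#' @param cohort Cohort tibble (non-empty).
#' @return Tibble with columns `variable`, `level`, `count`, `percent`,
#'   `mean`, `sd`.
#' @export
descriptive_stats <- function(cohort) {
  n <- nrow(cohort)
  if (!n) abort("cohort is empty.")
  rows <- list()
  for (v in categorical_columns(cohort)) {
    tab <- table(cohort[[v]])
    rows[[v]] <- tibble(
      variable = v, level = names(tab), count = as.integer(tab),
      percent = round(100 * as.integer(tab) / n, 2),
      mean = NA_real_, sd = NA_real_
    )
  }
  bits <- intersect(c("outcome_used", resource_columns(),
                      flag_columns(cohort)), names(cohort))
  for (b in bits) {
    cnt <- sum(cohort[[b]])
    rows[[b]] <- tibble(variable = b, level = "1", count = as.integer(cnt),
                        percent = round(100 * cnt / n, 2),
                        mean = NA_real_, sd = NA_real_)
  }
  if ("los_days" %in% names(cohort)) {
    rows[["los_days"]] <- tibble(
      variable = "los_days", level = NA_character_, count = NA_integer_,
      percent = NA_real_, mean = mean(cohort$los_days),
      sd = sd(cohort$los_days)
    )
  }
  dplyr::bind_rows(rows)
}
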