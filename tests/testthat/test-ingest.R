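make_fixture_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "cohort.csv")
  readr::write_csv(df, path)
  path
}

base_fixture <- function(n = 6) {
  tibble::tibble(
    visit_id = seq_len(n), patient_id = seq_len(n), facility_id = 1L,
    discharge_date = as.Date("2019-03-01") + seq_len(n),
    outcome_used = rep_len(c(0L, 1L), n),
    ct_other = rep_len(c(1L, 0L), n), miscellaneous = 0L, mri_mra = 0L,
    nuclear_medicine = 0L, special_imaging = 0L, ultrasound = 0L,
    xray = rep_len(c(0L, 1L), n),
    los_days = 2.5, icd_principal = 0L, malignancy_history = 0L,
    age_group = "66-70", race = rep_len(c("white", "black"), n),
    payor = "medicare_traditional", point_of_origin = "physician_referral",
    discharge_status = "home_self_care"
  )
}

test_that("read_cohort validates schema, types, and bad bits", {
  df <- base_fixture()
  path <- make_fixture_csv(df)
  back <- suppressMessages(read_cohort(path))
  expect_equal(nrow(back), 6)
  expect_type(back$outcome_used, "integer")

  empty <- make_fixture_csv(df[0, ])
  expect_equal(nrow(suppressMessages(read_cohort(empty))), 0)

  bad <- df[1:3, ]
  bad$xray[2] <- 7L
  expect_error(suppressMessages(read_cohort(make_fixture_csv(bad))),
               "xray.*row.*2")

  missing <- df[, setdiff(names(df), "los_days")]
  expect_error(suppressMessages(read_cohort(make_fixture_csv(missing))),
               "los_days")
})

test_that("first-visit deduplication keeps earliest discharge, ties to lowest visit id", {
  df <- base_fixture(4)
  df$patient_id <- c(1L, 1L, 2L, 2L)
  df$discharge_date <- as.Date(c("2019-06-01", "2019-03-01",
                                 "2019-05-05", "2019-05-05"))
  out <- deduplicate_first_visit(df)
  expect_equal(nrow(out), 2)
  expect_equal(out$visit_id, c(2L, 3L))  # Mar-01 beats Jun-01; tie -> id 3

  unique_df <- base_fixture(5)
  expect_equal(deduplicate_first_visit(unique_df), unique_df)

  ten <- base_fixture(10)
  ten$patient_id <- c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 5L, 6L, 7L)
  expect_equal(nrow(deduplicate_first_visit(ten)), 7)
})

test_that("category collapsing applies the low-count rules and reports them", {
  n <- 50000
  df <- base_fixture(n)
  df$visit_id <- df$patient_id <- seq_len(n)
  df$payor <- c(rep("charity", 65), rep("indigent", 6),
                rep("medicare_traditional", n - 71))
  # exactly 0.1% share (strictly-less rule -> kept), one level below it
  df$discharge_status <- c(rep("swing_bed", 50), rep("court", 49),
                           rep("home_self_care", n - 99))
  df$cm_rare <- c(rep(1L, 499), rep(0L, n - 499))
  df$cm_common <- c(rep(1L, 500), rep(0L, n - 500))
  out <- collapse_categories(df)
  expect_equal(sum(out$payor == "charity_indigent"), 71)
  expect_false(any(out$payor %in% c("charity", "indigent")))
  expect_true("swing_bed" %in% out$discharge_status)     # 0.1% exactly: kept
  expect_false("court" %in% out$discharge_status)        # < 0.1%: pooled
  expect_false("cm_rare" %in% names(out))                # 499 < 500: dropped
  expect_true("cm_common" %in% names(out))               # 500: kept
  rep_tbl <- collapse_report(out)
  expect_true(all(c("payor", "discharge_status", "cm_rare") %in%
                    rep_tbl$variable))
})

test_that("collapsing pools rare MS-DRGs and is idempotent", {
  n <- 2000
  df <- base_fixture(n)
  df$visit_id <- df$patient_id <- seq_len(n)
  df$ms_drg <- c(rep("major_male_pelvic", 1500), rep("rare_drg", 100),
                 rep("another_rare", 400))
  rules <- collapse_rules(flag_min_count = 300)
  once <- collapse_categories(df, rules)
  expect_false("rare_drg" %in% once$ms_drg)
  expect_true("another_rare" %in% once$ms_drg)
  twice <- collapse_categories(once, rules)
  expect_equal(as.data.frame(twice), as.data.frame(once), ignore_attr = TRUE)
})

test_that("age groups wholly at or below the bound merge into one level", {
  df <- base_fixture(100)
  df$age_group <- rep(c("<=40", "41-45", "46-50", "66-70"), 25)
  out <- collapse_categories(df)
  expect_setequal(unique(out$age_group), c("<=45", "46-50", "66-70"))
  expect_equal(sum(out$age_group == "<=45"), 50)
})

test_that("design matrices code references, sets, and rank as declared", {
  fix <- cached_cohort()
  cohort <- fix$cohort
  dc <- build_design(cohort, "c")
  expect_equal(ncol(dc$matrix), 8)  # intercept + 7 resource bits
  expect_equal(colnames(dc$matrix)[1], "(Intercept)")

  da <- build_design(cohort, "a")
  expect_equal(da$reference_levels$race, "white")
  expect_equal(da$reference_levels$payor, "medicare_traditional")
  race_cols <- grep("^race=", colnames(da$matrix))
  white_rows <- cohort$race == "white"
  expect_true(all(da$matrix[white_rows, race_cols] == 0))
  # no visit carries two dummies within one variable
  expect_true(all(rowSums(da$matrix[, race_cols, drop = FALSE]) <= 1))
  expect_equal(nrow(da$matrix), nrow(cohort))

  db <- build_design(cohort, "b")
  expect_false(any(resource_columns() %in% colnames(db$matrix)))
})

test_that("a six-visit design equals the hand-written matrix", {
  df <- base_fixture(6)
  df$race <- c("white", "black", "black", "white", "asian", "white")
  df$icd_principal <- c(0L, 1L, 0L, 1L, 0L, 1L)
  df$malignancy_history <- c(0L, 0L, 1L, 1L, 0L, 1L)
  dm <- build_design(df, "b", include_los = FALSE)$matrix
  expect_equal(unname(dm[, "icd_principal"]), c(0, 1, 0, 1, 0, 1))
  expect_equal(unname(dm[, "race=black"]), c(0, 1, 1, 0, 0, 0))
  expect_equal(unname(dm[, "race=asian"]), c(0, 0, 0, 0, 1, 0))
  expect_equal(unname(dm[, "(Intercept)"]), rep(1, 6))
  # single-level variables contribute no dummy columns
  expect_false(any(grepl("^payor=", colnames(dm))))
})

test_that("aliased columns raise a diagnostic rank error", {
  df <- base_fixture(50)
  df$cm_dup1 <- rep_len(c(1L, 0L), 50)
  df$cm_dup2 <- df$cm_dup1
  expect_error(build_design(df, "b"), "aliased.*cm_dup")
})

test_that("descriptive statistics reproduce printed-percentage arithmetic", {
  n <- 51111
  df <- tibble::tibble(
    visit_id = seq_len(n), patient_id = seq_len(n), facility_id = 1L,
    outcome_used = c(rep(1L, 5990), rep(0L, n - 5990)),
    ct_other = 0L, miscellaneous = 0L, mri_mra = 0L, nuclear_medicine = 0L,
    special_imaging = 0L, ultrasound = 0L,
    xray = c(rep(1L, 28969), rep(0L, n - 28969)),
    los_days = 4.57, icd_principal = 0L, malignancy_history = 0L,
    race = c(rep("white", 36848), rep("black", n - 36848))
  )
  st <- descriptive_stats(df)
  expect_equal(st$percent[st$variable == "outcome_used"], 11.72)
  expect_equal(st$percent[st$variable == "xray"], 56.68)
  expect_equal(st$percent[st$variable == "race" & st$level == "white"], 72.09)

  one <- descriptive_stats(df[1, ])
  expect_equal(one$percent[one$variable == "race"], 100.00)

  # percents within a categorical variable sum to 100 up to rounding
  fix <- cached_cohort()
  st2 <- descriptive_stats(fix$cohort)
  st2 <- st2[st2$variable %in% c("race", "payor", "age_group"), ]
  sums <- stats::aggregate(percent ~ variable, st2, sum)
  expect_true(all(abs(sums$percent - 100) <= 0.05))
})
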