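test_that("intercept-only and 2x2 logistic fits match closed forms", {
  y <- c(rep(1L, 30), rep(0L, 70))
  X <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_logistic(X, y)
  expect_equal(unname(fit$coefficients), qlogis(0.3), tolerance = 1e-8)

  # group a: 20/100 events, group b: 50/100 -> slope = log odds ratio
  y2 <- c(rep(1L, 20), rep(0L, 80), rep(1L, 50), rep(0L, 50))
  X2 <- cbind(`(Intercept)` = 1, b = rep(c(0, 1), each = 100))
  fit2 <- fit_logistic(X2, y2)
  expect_equal(unname(fit2$coefficients["b"]),
               log((50 * 80) / (50 * 20)), tolerance = 1e-8)
})

test_that("the fitted model satisfies its score equations", {
  fix <- cached_cohort()
  fit <- fit_utilization_model(fix$cohort, "a")
  X <- build_design(fix$cohort, "a")$matrix
  grad <- crossprod(X, fix$cohort$outcome_used - fit$fitted_probabilities)
  expect_lt(max(abs(grad)), 1e-6)
  expect_true(all(fit$fitted_probabilities > 0 & fit$fitted_probabilities < 1))
  expect_true(fit$converged)
})

test_that("separation is reported, degenerate outcomes are rejected", {
  y <- c(rep(0L, 20), rep(1L, 20))
  X <- cbind(`(Intercept)` = 1, x = c(rep(0, 20), rep(1, 20)))
  expect_warning(fit_logistic(X, y), "separation")
  expect_error(fit_logistic(X, rep(1L, 40)), "both outcome classes")
})

test_that("tidy and glance expose coefficients and model summaries", {
  fix <- cached_cohort()
  fit <- fit_utilization_model(fix$cohort, "c")
  td <- tidy(fit)
  expect_equal(nrow(td), 8)
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  or_td <- tidy(fit, exponentiate = TRUE)
  expect_equal(or_td$estimate, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$df, 8)
  expect_equal(gl$n, nrow(fix$cohort))
})

test_that("log-likelihoods nest: the full model dominates both submodels", {
  fix <- cached_cohort()
  ll <- vapply(c("a", "b", "c"),
               function(s) fit_utilization_model(fix$cohort, s)$log_likelihood,
               numeric(1))
  expect_gte(ll[["a"]], ll[["b"]])
  expect_gte(ll[["a"]], ll[["c"]])
})

test_that("AUC equals the O(n^2) pair-counting oracle, including ties", {
  withr::with_seed(101, {
    for (rep in 1:3) {
      n <- 200
      pred <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # forces ties
      y <- rbinom(n, 1, 0.4)
      expect_equal(auc_delong(pred, y)$auc, auc_bruteforce(pred, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC handles separations and the worked four-score example", {
  expect_equal(auc_delong(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1.0)
  # swap one event/non-event score: 3 of 4 pairs concordant
  expect_equal(auc_delong(c(0.9, 0.2, 0.1, 0.8), c(1, 1, 0, 0))$auc, 0.75)
  est <- auc_delong(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_true(est$ci95[1] <= est$auc && est$auc <= est$ci95[2])
  expect_error(auc_delong(c(0.5, 0.6), c(1, 1)), "both outcome classes")
})

test_that("DeLong variance and test agree with the independent pROC implementation", {
  withr::with_seed(202, {
    n <- 400
    y <- rbinom(n, 1, 0.3)
    pa <- plogis(y + rnorm(n))
    pb <- plogis(0.5 * y + rnorm(n))
    est <- auc_delong(pa, y)
    roc_a <- pROC::roc(y, pa, quiet = TRUE, direction = "<")
    expect_equal(est$auc, as.numeric(pROC::auc(roc_a)), tolerance = 1e-12)
    expect_equal(sqrt(est$variance), sqrt(pROC::var(roc_a)),
                 tolerance = 1e-10)
    cmp <- compare_auc_delong(pa, pb, y)
    roc_b <- pROC::roc(y, pb, quiet = TRUE, direction = "<")
    ref <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE)
    expect_equal(cmp$p.value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("paired AUC comparison: identity, antisymmetry, bootstrap variance", {
  withr::with_seed(303, {
    n <- 500
    y <- rbinom(n, 1, 0.3)
    pa <- plogis(1.5 * y + rnorm(n))
    pb <- plogis(0.5 * y + rnorm(n))

    same <- compare_auc_delong(pa, pa, y)
    expect_equal(same$auc_diff, 0)
    expect_equal(same$p.value, 1)

    fwd <- compare_auc_delong(pa, pb, y)
    rev <- compare_auc_delong(pb, pa, y)
    expect_equal(fwd$auc_diff, -rev$auc_diff)
    expect_equal(fwd$p.value, rev$p.value)

    boot_diffs <- vapply(1:2000, function(i) {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(y[idx])) < 2) return(NA_real_)
      auc_delong(pa[idx], y[idx])$auc - auc_delong(pb[idx], y[idx])$auc
    }, numeric(1))
    boot_var <- var(boot_diffs, na.rm = TRUE)
    delong_var <- ((fwd$conf.high - fwd$auc_diff) / qnorm(0.975))^2
    expect_lt(abs(delong_var - boot_var) / boot_var, 0.15)

    expect_error(compare_auc_delong(pa[1:10], pb, y), "same visits")
  })
})

test_that("pattern analysis counts, chi-square, and label invariance", {
  fix <- cached_cohort()
  pa <- pattern_analysis(fix$cohort)
  expect_equal(pa$n_possible, 128)
  expect_equal(sum(pa$patterns$count), nrow(fix$cohort))
  expect_equal(pa$df, pa$n_observed - 1)

  # two patterns with identical outcome rates -> statistic 0
  df <- fix$cohort[1:40, ]
  for (rc in resource_columns()) df[[rc]] <- 0L
  df$ct_other <- rep(c(0L, 1L), each = 20)
  df$outcome_used <- rep(c(1L, 0L, 1L, 0L), each = 10)
  pa0 <- pattern_analysis(df)
  expect_equal(pa0$statistic, 0)

  # hand-computed 3-pattern fixture
  df3 <- df[1:60, ]
  for (rc in resource_columns()) df3[[rc]] <- 0L
  df3$ct_other <- rep(c(0L, 1L, 0L), each = 20)
  df3$xray <- rep(c(0L, 0L, 1L), each = 20)
  df3$outcome_used <- c(rep(1L, 4), rep(0L, 16),   # 4/20
                        rep(1L, 10), rep(0L, 10),  # 10/20
                        rep(1L, 7), rep(0L, 13))   # 7/20
  obs <- matrix(c(4, 16, 10, 10, 7, 13), 3, byrow = TRUE)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  hand_stat <- sum((obs - expected)^2 / expected)
  pa3 <- pattern_analysis(df3)
  expect_equal(pa3$statistic, hand_stat, tolerance = 1e-10)
  expect_equal(pa3$df, 2)

  # permuting which resources carry the pattern leaves the statistic unchanged
  df3_swap <- df3
  df3_swap$ct_other <- df3$xray
  df3_swap$xray <- df3$ct_other
  expect_equal(pattern_analysis(df3_swap)$statistic, pa3$statistic)
})

test_that("tetrachoric estimates: independence, concordance, copula recovery", {
  ind <- tetrachoric_rho(matrix(c(25, 25, 25, 25), 2))
  expect_true(ind$defined)
  expect_lt(abs(ind$rho), 1e-4)

  conc <- tetrachoric_rho(matrix(c(50, 0, 0, 50), 2))
  expect_gte(conc$rho, 0.99)

  degen <- tetrachoric_rho(matrix(c(0, 0, 50, 50), 2))
  expect_false(degen$defined)
  expect_true(is.na(degen$rho))

  cfg <- synthetic_config(n_facilities = 10, total_visits_target = 100000,
                          resource_dependence = 0.5, outlier_plan = list(),
                          seed = 404)
  cohort <- generate_visits(cfg)
  tet <- tetrachoric_correlations(cohort)
  res_pairs <- tet[tet$var2 != "outcome_used", ]
  expect_equal(nrow(res_pairs), 21)
  expect_equal(nrow(tet), 28)
  expect_true(all(abs(res_pairs$rho - 0.5) <= 0.03))
})
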