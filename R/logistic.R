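#' Fit a logistic utilization model
#'
#' Maximum-likelihood logistic regression via iteratively reweighted
#' least squares, with Wald standard errors from the observed Fisher
#' information. Separation is reported (any |coefficient| > 15 after
#' convergence triggers a warning and clears the `converged` bit).
#'
#' @param design A [build_design()] object, or a bare numeric matrix
#'   including an intercept column.
#' @param outcome Binary 0/1 outcome vector; defaults to the outcome
#'   stored in the design.
#' @return Object of class `utilization_fit`: coefficients, standard
#'   errors, fitted probabilities, log-likelihood, convergence bit,
#'   covariate set and reference levels.
#' @export
#' @examples
#' cfg <- synthetic_config(n_facilities = 20, total_visits_target = 3000,
#'                         seed = 7)
#' cohort <- collapse_categories(simulate_cohort(cfg))
#' fit <- fit_logistic(build_design(cohort, "c"))
#' glance(fit)
fit_logistic <- function(design, outcome = NULL) {
  if (inherits(design, "design_matrix")) {
    X <- design$matrix
    y <- outcome %||% design$outcome
    covariate_set <- design$covariate_set
    reference_levels <- design$reference_levels
  } else {
    X <- design
    y <- outcome
    covariate_set <- NA_character_
    reference_levels <- list()
  }
  if (is.null(y)) abort("an outcome vector is required.")
  y <- as.numeric(y)
  if (length(unique(y)) < 2) abort("both outcome classes must be present.")
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = list(maxit = 100, epsilon = 1e-10))
  )
  if (!fit$converged) {
    abort("logistic fit did not converge within the iteration limit.")
  }
  beta <- fit$coefficients
  if (any(abs(beta) > 15)) {
    warn(paste0("possible separation: |coefficient| > 15 for ",
                paste(names(beta)[abs(beta) > 15], collapse = ", ")))
  }
  w <- fit$weights
  # Wald SEs from (X' W X)^{-1}
  xw <- X * sqrt(w)
  R <- qr.R(qr(xw))
  cov_beta <- chol2inv(R)
  se <- sqrt(diag(cov_beta))
  names(se) <- colnames(X)
  p <- fit$fitted.values
  structure(
    list(
      coefficients = beta,
      standard_errors = se,
      vcov = cov_beta,
      fitted_probabilities = p,
      log_likelihood = sum(y * log(p) + (1 - y) * log1p(-p)),
      converged = fit$converged && all(abs(beta) <= 15),
      covariate_set = covariate_set,
      reference_levels = reference_levels,
      n = length(y),
      outcome = as.integer(y)
    ),
    class = "utilization_fit"
  )
}

#' Fit one of the three utilization models on a cohort
#'
#' Convenience wrapper: builds the design for the requested covariate
#' set and fits the logistic model. Set `"a"` uses patient plus
#' competing-resource covariates, `"b"` patient only, `"c"` resources
#' only.
#'
#' @inheritParams build_design
#' @return A `utilization_fit`.
#' @export
fit_utilization_model <- function(cohort, covariate_set = c("a", "b", "c"),
                                  include_los = TRUE) {
  covariate_set <- match.arg(covariate_set)
  fit_logistic(build_design(cohort, covariate_set, include_los = include_los))
}

#' @export
print.utilization_fit <- function(x, ...) {
  cat("<utilization_fit> covariate set:", x$covariate_set,
      "| n =", x$n,
      "| terms =", length(x$coefficients),
      "| logLik =", format(x$log_likelihood, digits = 8), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted utilization model
#'
#' @param x A `utilization_fit`.
#' @param exponentiate Report odds ratios instead of log-odds.
#' @param ... Unused.
#' @return Tibble with term, estimate, std.error, statistic, p.value,
#'   conf.low, conf.high.
#' @export
tidy.utilization_fit <- function(x, exponentiate = FALSE, ...) {
  est <- unname(x$coefficients)
  se <- unname(x$standard_errors)
  z <- est / se
  out <- tibble(
    term = names(x$coefficients),
    estimate = est,
    std.error = se,
    statistic = z,
    p.value = 2 * pnorm(-abs(z)),
    conf.low = est - qnorm(0.975) * se,
    conf.high = est + qnorm(0.975) * se
  )
  if (exponentiate) {
    out <- out %>% mutate(estimate = exp(.data$estimate),
                          conf.low = exp(.data$conf.low),
                          conf.high = exp(.data$conf.high))
  }
  out
}

#' One-row model summary
#'
#' @param x A `utilization_fit`.
#' @param ... Unused.
#' @return Tibble with n, df, log-likelihood, AIC, AUC and convergence.
#' @export
glance.utilization_fit <- function(x, ...) {
  auc <- auc_delong(x$fitted_probabilities, x$outcome)
  tibble(
    n = x$n,
    df = length(x$coefficients),
    logLik = x$log_likelihood,
    AIC = -2 * x$log_likelihood + 2 * length(x$coefficients),
    auc = auc$auc,
    converged = x$converged,
    covariate_set = x$covariate_set
  )
}

#' Per-visit fitted values
#'
#' @param x A `utilization_fit`.
#' @param ... Unused.
#' @return Tibble with `.fitted` (probability) and `outcome_used`.
#' @export
augment.utilization_fit <- function(x, ...) {
  tibble(.fitted = x$fitted_probabilities, outcome_used = x$outcome)
}
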