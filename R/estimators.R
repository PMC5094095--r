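#' @rdname fit_method
#' @format NULL
#' @export
METHODS <- c("CSP_UN", "CSP_AD", "TDCM", "PLR_UN", "PLR_AD")

new_fit_result <- function(method, est, se, pval, converged, n_rows, n_events,
                           model = NULL) {
  z <- qnorm(0.975)
  structure(
    list(
      method = method,
      coef = est, se = se,
      ci_lower = est - z * se, ci_upper = est + z * se,
      pvalue = pval,
      converged = converged,
      n_rows = n_rows, n_events = n_events,
      model = model
    ),
    class = "survpool_fit"
  )
}

# term mapping from model column names to the package's canonical terms
canonical_terms <- c(
  y = "link", y_current = "link",
  age_at_exam = "age", baseline_age = "age",
  sex = "sex",
  interval_start_time = "time",
  "(Intercept)" = "intercept"
)

relabel_terms <- function(x) {
  nm <- canonical_terms[names(x)]
  nm[is.na(nm)] <- names(x)[is.na(nm)]
  names(x) <- nm
  x
}

extract_wald <- function(method, fit, n_rows, n_events, converged) {
  est <- relabel_terms(coef(fit))
  se <- sqrt(diag(vcov(fit)))
  names(se) <- names(est)
  if (any(is.na(est)) || any(!is.finite(se))) converged <- FALSE
  z <- est / se
  pval <- 2 * pnorm(-abs(z))
  new_fit_result(method, est, se, pval, converged, n_rows, n_events,
                 model = fit)
}

#' Fit a Cox proportional-hazards model (Breslow ties)
#'
#' Maximizes the Cox partial likelihood on either layout produced by the
#' pooling builders. For person-period input the event-time axis is the
#' within-interval time (`time_in_interval`), optionally stratified by exam
#' interval so each interval keeps its own baseline hazard; for
#' counting-process input it is cumulative time with `(start, stop]`
#' risk-set entry and exit. Ties are handled with the Breslow approximation
#' and inference is Wald (SEs from the inverse observed information) in all
#' cases, so that interval-stratified person-period fits and
#' counting-process fits of the same cohort are term-by-term identical.
#'
#' @param rows a data.frame from [build_person_period()] (columns
#'   `time_in_interval`, `event`, `y`, `age_at_exam`, `sex`,
#'   `interval_index`) or [build_counting_process()] (columns `start`,
#'   `stop`, `event`, `y_current`, `baseline_age`, `sex`).
#' @param covariates subset of `c("link", "age", "sex")` to include; `link`
#'   is the longitudinal covariate, `age` the layout's age column.
#' @param stratify_by_interval stratify the person-period fit by
#'   `interval_index` (interval-specific baseline hazards). Ignored with a
#'   warning for counting-process input.
#' @return an object of class `survpool_fit` with elements `method`, `coef`,
#'   `se`, `ci_lower`, `ci_upper`, `pvalue` (two-sided Wald), `converged`,
#'   `n_rows`, `n_events`.
#' @export
fit_cox <- function(rows, covariates = c("link", "age", "sex"),
                    stratify_by_interval = FALSE) {
  covariates <- match.arg(covariates, c("link", "age", "sex"),
                          several.ok = TRUE)
  counting <- "start" %in% names(rows)
  if (counting) {
    cols <- c(link = "y_current", age = "baseline_age", sex = "sex")
    lhs <- "Surv(start, stop, event)"
    if (stratify_by_interval) {
      warning("stratify_by_interval ignored for counting-process input")
      stratify_by_interval <- FALSE
    }
  } else {
    cols <- c(link = "y", age = "age_at_exam", sex = "sex")
    lhs <- "Surv(time_in_interval, event)"
  }
  n_events <- sum(rows$event)
  if (nrow(rows) == 0 || n_events < 1)
    abort_estimation("Cox fit requires at least one event")
  rhs <- cols[covariates]
  if (stratify_by_interval) rhs <- c(rhs, "strata(interval_index)")
  fml <- as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    coxph(fml, data = rows, ties = "breslow",
          control = coxph.control(eps = 1e-12, iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  )
  method <- if (counting) "TDCM"
            else if (stratify_by_interval) "CSP_AD" else "CSP_UN"
  extract_wald(method, fit, nrow(rows), n_events, converged)
}

#' Fit a pooled logistic regression (discrete-time hazard model)
#'
#' Maximum-likelihood logistic regression of the interval event indicator on
#' the person-period rows, treating within-subject rows as conditionally
#' independent contributions (each row conditions on survival to its
#' interval). With `include_time = TRUE` a single linear coefficient on the
#' interval-opening exam time (coded 0, 5, ..., in years) adjusts for the
#' interval in which the covariate was measured.
#'
#' @param rows a person-period data.frame from [build_person_period()].
#' @param covariates subset of `c("link", "age", "sex")`.
#' @param include_time add the linear exam-time term.
#' @return an object of class `survpool_fit`; terms include `intercept` and,
#'   when requested, `time`.
#' @export
fit_logistic <- function(rows, covariates = c("link", "age", "sex"),
                         include_time = FALSE) {
  covariates <- match.arg(covariates, c("link", "age", "sex"),
                          several.ok = TRUE)
  n_events <- sum(rows$event)
  if (nrow(rows) == 0 || n_events < 1 || n_events == nrow(rows))
    abort_estimation("logistic fit requires at least one event and one non-event")
  cols <- c(link = "y", age = "age_at_exam", sex = "sex")
  rhs <- cols[covariates]
  if (include_time) rhs <- c(rhs, "interval_start_time")
  fml <- as.formula(paste("event ~", paste(rhs, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = rows,
        control = list(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("converge|fitted probabilities", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) converged <- FALSE
  method <- if (include_time) "PLR_AD" else "PLR_UN"
  extract_wald(method, fit, nrow(rows), n_events, converged)
}

#' Fit one of the five estimation strategies to a cohort
#'
#' Dispatch table (covariate handling differs by design):
#' \describe{
#'   \item{CSP_UN}{Cox on person-period within-interval times, unstratified,
#'     age time-varying (age at each exam).}
#'   \item{CSP_AD}{As CSP_UN but stratified by exam interval (one baseline
#'     hazard per interval).}
#'   \item{TDCM}{Cox on counting-process `(start, stop]` records over
#'     cumulative time, baseline age fixed, longitudinal covariate updated
#'     at each exam.}
#'   \item{PLR_UN}{Pooled logistic regression on person-period rows, age
#'     time-varying, no time term.}
#'   \item{PLR_AD}{As PLR_UN plus a linear exam-time coefficient.}
#' }
#' With exams at common times across subjects, CSP_AD and TDCM maximize the
#' same partial likelihood term by term and return identical estimates and
#' standard errors.
#'
#' @param method one of `METHODS` (`"CSP_UN"`, `"CSP_AD"`, `"TDCM"`,
#'   `"PLR_UN"`, `"PLR_AD"`).
#' @param cohort a `cohort` object.
#' @return a `survpool_fit`.
#' @examples
#' cfg <- sim_config(n_subjects = 200, gamma = 0.5, weibull_scale = 0.02,
#'                   master_seed = 7)
#' coh <- simulate_cohort(cfg)
#' fit_method("TDCM", coh)
#' @export
fit_method <- function(method, cohort) {
  if (length(method) != 1 || !method %in% METHODS)
    abort_config(sprintf("unknown method '%s'; expected one of %s",
                         paste(method, collapse = ","),
                         paste(METHODS, collapse = ", ")))
  switch(method,
    CSP_UN = fit_cox(build_person_period(cohort)),
    CSP_AD = fit_cox(build_person_period(cohort), stratify_by_interval = TRUE),
    TDCM = fit_cox(build_counting_process(cohort)),
    PLR_UN = fit_logistic(build_person_period(cohort)),
    PLR_AD = fit_logistic(build_person_period(cohort), include_time = TRUE)
  )
}

#' Fit several methods at once
#'
#' @param cohort a `cohort` object.
#' @param methods character vector of method labels (default all five).
#' @return named list of `survpool_fit` objects.
#' @export
fit_all_methods <- function(cohort, methods = METHODS) {
  fits <- lapply(methods, fit_method, cohort = cohort)
  names(fits) <- methods
  fits
}

#' Flatten fit results to a data.frame
#'
#' One row per (method, term) with estimate, SE, 95% Wald interval and
#' two-sided p-value — the serializable record form of a fit.
#'
#' @param fits a `survpool_fit` or list of them.
#' @return data.frame with columns `method`, `term`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p`, `converged`.
#' @export
tidy_fits <- function(fits) {
  if (inherits(fits, "survpool_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    data.frame(
      method = f$method,
      term = names(f$coef),
      estimate = unname(f$coef),
      se = unname(f$se),
      ci_low = unname(f$ci_lower),
      ci_high = unname(f$ci_upper),
      p = unname(f$pvalue),
      converged = f$converged,
      row.names = NULL
    )
  }))
}

#' @export
print.survpool_fit <- function(x, ...) {
  cat(sprintf("<survpool_fit> %s (%d rows, %d events%s)\n", x$method,
              x$n_rows, x$n_events,
              if (x$converged) "" else ", NOT CONVERGED"))
  tab <- data.frame(
    estimate = x$coef, se = x$se,
    ci_low = x$ci_lower, ci_high = x$ci_upper, p = x$pvalue
  )
  print(round(tab, 4))
  invisible(x)
}
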