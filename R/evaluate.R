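#' Specify one simulation scenario
#'
#' A scenario is a cell of the study grid: a target cumulative event rate,
#' a true link coefficient gamma, a cohort size and a replicate count, fit
#' with a subset of the five methods.
#'
#' @param event_rate target cumulative event rate (paper grid: 0.10, 0.50,
#'   0.90).
#' @param gamma true link coefficient (grid: 0, 0.5, 1).
#' @param n_subjects subjects per replicate (grid: 100 or 1000).
#' @param n_replicates Monte-Carlo replicates.
#' @param methods methods to fit, a subset of `METHODS`.
#' @param master_seed master seed for the scenario; replicate r uses
#'   `child_seed(master_seed, r)`.
#' @param config a base [sim_config()] supplying every other parameter
#'   (tau, shape, covariate coefficients, ...).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(event_rate, gamma, n_subjects = 1000,
                          n_replicates = 1000, methods = METHODS,
                          master_seed = 20160101,
                          config = sim_config()) {
  if (n_replicates < 1) abort_config("n_replicates must be >= 1")
  bad <- setdiff(methods, METHODS)
  if (length(bad) > 0)
    abort_config(paste("unknown method(s):", paste(bad, collapse = ", ")))
  config$n_subjects <- n_subjects
  config$gamma <- gamma
  config$target_event_rate <- event_rate
  config$weibull_scale <- NULL
  config$master_seed <- master_seed
  validate_config(config)
  structure(
    list(event_rate = event_rate, gamma = gamma, n_subjects = n_subjects,
         n_replicates = n_replicates, methods = methods,
         master_seed = master_seed, config = config),
    class = "scenario_spec"
  )
}

#' Replicate-level performance metrics
#'
#' Summaries of a vector of replicate estimates against the known truth:
#' mean estimate, mean model-based SE, empirical SD, bias (mean estimate
#' minus truth), MSE (mean squared deviation from truth), and coverage of
#' the 95% Wald interval `estimate +/- 1.96 * se`.
#'
#' @param estimates numeric vector of replicate point estimates.
#' @param ses matching vector of model-based standard errors.
#' @param truth the true parameter value.
#' @return list with `n`, `mean_estimate`, `mean_se`, `empirical_sd`,
#'   `bias`, `mse`, `coverage`.
#' @export
compute_metrics <- function(estimates, ses, truth) {
  if (length(estimates) < 1) abort_estimation("no converged replicates")
  stopifnot(length(estimates) == length(ses))
  z <- qnorm(0.975)
  lo <- estimates - z * ses
  hi <- estimates + z * ses
  list(
    n = length(estimates),
    mean_estimate = mean(estimates),
    mean_se = mean(ses),
    empirical_sd = if (length(estimates) > 1) sd(estimates) else NA_real_,
    bias = mean(estimates) - truth,
    mse = mean((estimates - truth)^2),
    coverage = mean(lo <= truth & truth <= hi)
  )
}

#' Type I error rate
#'
#' Proportion of two-sided Wald p-values below `alpha`; meaningful for the
#' link coefficient when data are generated under gamma = 0.
#'
#' @param pvalues numeric vector of p-values.
#' @param alpha nominal level (default 0.05).
#' @return a proportion in `[0, 1]`.
#' @export
type_i_error <- function(pvalues, alpha = 0.05) {
  mean(pvalues < alpha)
}

#' Run one scenario over replicates
#'
#' Calibrates the baseline hazard once (reserved calibration seed), then for
#' each replicate simulates a cohort, fits the requested methods and records
#' estimate, SE and p-value for every coefficient. Summaries are computed
#' over converged replicates only, with the converged count reported. The
#' whole run is deterministic given `master_seed` and the aggregation is
#' order-independent.
#'
#' @param spec a [scenario_spec()].
#' @param n_calib calibration sample size.
#' @param progress print a progress line every `progress` replicates
#'   (0 = quiet).
#' @return an object of class `scenario_result`: list with `spec`,
#'   `weibull_scale`, `replicates` (long data.frame: replicate, method, term,
#'   estimate, se, p, converged) and `summary` (per method x term: truth,
#'   n_converged, mean_estimate, mean_se, empirical_sd, bias, mse, coverage,
#'   type1 — the latter only for the link term in null scenarios).
#' @export
run_scenario <- function(spec, n_calib = 1e5, progress = 0) {
  stopifnot(inherits(spec, "scenario_spec"))
  cfg <- resolve_scale(spec$config, n_calib = n_calib)
  reps <- vector("list", spec$n_replicates)
  for (r in seq_len(spec$n_replicates)) {
    cohort <- simulate_cohort(cfg, replicate_id = r)
    fits <- lapply(spec$methods, function(m) {
      tryCatch(fit_method(m, cohort), survpool_estimation_error = function(e) NULL)
    })
    keep <- !vapply(fits, is.null, logical(1))
    tf <- tidy_fits(fits[keep])
    if (!is.null(tf) && nrow(tf) > 0) tf$replicate <- r
    reps[[r]] <- tf
    if (progress > 0 && r %% progress == 0)
      message(sprintf("  replicate %d / %d", r, spec$n_replicates))
  }
  replicates <- do.call(rbind, reps)
  if (is.null(replicates) || nrow(replicates) == 0)
    abort_estimation("no replicate produced a fit")
  summary <- summarize_replicates(replicates, spec)
  structure(
    list(spec = spec, weibull_scale = cfg$weibull_scale,
         replicates = replicates, summary = summary),
    class = "scenario_result"
  )
}

truth_for_term <- function(term, spec) {
  switch(term,
         link = spec$gamma,
         age = spec$config$alpha_age,
         sex = spec$config$alpha_sex,
         NA_real_)
}

summarize_replicates <- function(replicates, spec) {
  out <- list()
  for (m in unique(replicates$method)) {
    dm <- replicates[replicates$method == m & replicates$converged, ]
    if (nrow(dm) == 0) next
    for (term in intersect(c("link", "age", "sex"), unique(dm$term))) {
      dt <- dm[dm$term == term, ]
      truth <- truth_for_term(term, spec)
      met <- compute_metrics(dt$estimate, dt$se, truth)
      type1 <- if (term == "link" && spec$gamma == 0)
        type_i_error(dt$p) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        event_rate = spec$event_rate, gamma = spec$gamma,
        n_subjects = spec$n_subjects, method = m, term = term,
        truth = truth, n_converged = met$n,
        mean_estimate = met$mean_estimate, mean_se = met$mean_se,
        empirical_sd = met$empirical_sd, bias = met$bias, mse = met$mse,
        coverage = met$coverage, type1 = type1
      )
    }
  }
  do.call(rbind, out)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> rate %g, gamma %g, n = %d, %d replicates (scale %.5g)\n",
              x$spec$event_rate, x$spec$gamma, x$spec$n_subjects,
              x$spec$n_replicates, x$weibull_scale))
  s <- x$summary[x$summary$term == "link", ]
  print(s[, c("method", "mean_estimate", "mean_se", "coverage", "bias", "mse")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run a grid of scenarios
#'
#' Crosses event rates and gamma values, running [run_scenario()] on each
#' cell; scenario master seeds are derived from `master_seed` by cell index
#' so the grid is reproducible and cells are independent.
#'
#' @param event_rates,gammas grid axes.
#' @param n_subjects,n_replicates,methods,config per-scenario settings (see
#'   [scenario_spec()]).
#' @param master_seed grid master seed.
#' @param progress passed to [run_scenario()].
#' @return list of `scenario_result`, one per cell (rate varying fastest).
#' @export
run_grid <- function(event_rates = c(0.90, 0.50, 0.10),
                     gammas = c(0, 0.5, 1), n_subjects = 1000,
                     n_replicates = 1000, methods = METHODS,
                     master_seed = 20160101, config = sim_config(),
                     progress = 0) {
  cells <- expand.grid(event_rate = event_rates, gamma = gammas,
                       KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(cells)), function(i) {
    spec <- scenario_spec(cells$event_rate[i], cells$gamma[i],
                          n_subjects = n_subjects,
                          n_replicates = n_replicates, methods = methods,
                          master_seed = child_seed(master_seed, i),
                          config = config)
    run_scenario(spec, progress = progress)
  })
}

#' Arrange scenario results as report tables
#'
#' Produces the two standard summary tables: a Type-I-error table (rows =
#' event rates, one column per method, from null-gamma scenarios) and a
#' long estimates table (per event rate, gamma and method: mean link
#' estimate, mean SE, coverage, bias, MSE).
#'
#' @param results list of `scenario_result` (e.g. from [run_grid()]).
#' @return list with data.frames `type1` and `estimates`.
#' @export
render_tables <- function(results) {
  if (inherits(results, "scenario_result")) results <- list(results)
  summaries <- do.call(rbind, lapply(results, `[[`, "summary"))
  est_cols <- c("event_rate", "gamma", "method", "mean_estimate", "mean_se",
                "coverage", "bias", "mse", "n_converged")
  if (is.null(summaries) || nrow(summaries) == 0) {
    return(list(
      type1 = data.frame(event_rate = numeric(0)),
      estimates = stats::setNames(
        data.frame(matrix(numeric(0), 0, length(est_cols))), est_cols)
    ))
  }
  link <- summaries[summaries$term == "link", ]
  estimates <- link[order(-link$event_rate, link$gamma, link$method),
                    est_cols]
  rownames(estimates) <- NULL
  null_rows <- link[link$gamma == 0 & !is.na(link$type1), ]
  if (nrow(null_rows) > 0) {
    type1 <- stats::reshape(
      null_rows[, c("event_rate", "method", "type1")],
      idvar = "event_rate", timevar = "method", direction = "wide")
    names(type1) <- sub("^type1\\.", "", names(type1))
    type1 <- type1[order(-type1$event_rate), , drop = FALSE]
    rownames(type1) <- NULL
  } else {
    type1 <- data.frame(event_rate = numeric(0))
  }
  list(type1 = type1, estimates = estimates)
}

#' Write report tables and per-replicate records to CSV
#'
#' @param results list of `scenario_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_tables <- function(results, dir) {
  if (inherits(results, "scenario_result")) results <- list(results)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- render_tables(results)
  paths <- c(
    type1 = file.path(dir, "type1_error.csv"),
    estimates = file.path(dir, "estimates.csv"),
    replicates = file.path(dir, "replicates.csv")
  )
  write.csv(tabs$type1, paths["type1"], row.names = FALSE)
  write.csv(tabs$estimates, paths["estimates"], row.names = FALSE)
  reps <- do.call(rbind, lapply(results, function(r) {
    d <- r$replicates
    d$event_rate <- r$spec$event_rate
    d$gamma <- r$spec$gamma
    d
  }))
  write.csv(reps, paths["replicates"], row.names = FALSE)
  invisible(paths)
}
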