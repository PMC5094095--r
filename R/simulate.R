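#' Draw baseline covariates
#'
#' Baseline age is Normal(`age_mean`, `age_sd`^2) — draws are not truncated,
#' negative ages having negligible probability at the default (35, 5) — and
#' sex is Bernoulli(`female_prob`) with 1 = female.
#'
#' @param config a [sim_config()].
#' @param n number of subjects (defaults to `config$n_subjects`).
#' @return data.frame with columns `baseline_age`, `sex`.
#' @export
draw_baseline <- function(config, n = config$n_subjects) {
  validate_config(config)
  data.frame(
    baseline_age = rnorm(n, config$age_mean, config$age_sd),
    sex = rbinom(n, 1, config$female_prob)
  )
}

#' Generate longitudinal exam values
#'
#' Each subject's exam vector follows the random intercept/slope model
#' `Y_j = U1 + U2 * t_j + tau * Age + e_j` with `(U1, U2)` bivariate normal
#' (mean `re_mean`, covariance `G`) and iid residuals `e_j ~ N(0, sigma^2)`.
#' Marginally over subjects the exam vector is multivariate normal with mean
#' `re_mean[1] + re_mean[2] * t + tau * Age` and covariance
#' `Z G Z' + sigma^2 I`, `Z = [1, t_j]`.
#'
#' @param config a [sim_config()].
#' @param baseline data.frame from [draw_baseline()].
#' @return list with `y` (n x n_exams matrix), `u1`, `u2` (realized random
#'   effects).
#' @export
generate_longitudinal <- function(config, baseline) {
  validate_config(config)
  n <- nrow(baseline)
  tt <- exam_times(config)
  m <- config$n_exams
  if (n == 0) {
    return(list(y = matrix(numeric(0), 0, m), u1 = numeric(0),
                u2 = numeric(0)))
  }
  U <- MASS::mvrnorm(n, mu = config$re_mean, Sigma = config$G)
  U <- matrix(U, ncol = 2)  # mvrnorm drops to a vector when n = 1
  eps <- matrix(rnorm(n * m, 0, sqrt(config$resid_var)), n, m)
  y <- U[, 1] + outer(U[, 2], tt) +
    config$tau * baseline$baseline_age + eps
  list(y = y, u1 = U[, 1], u2 = U[, 2])
}

#' Generate interval-wise survival outcomes
#'
#' For each interval j = 1..n_exams in order, a candidate time is drawn from
#' the Weibull proportional-hazards model with hazard
#' `h(t) = k * lambda^k * t^(k-1) * exp(eta_j)` and linear predictor
#' `eta_j = alpha_age * (baseline_age + L*(j-1)) + alpha_sex * sex +
#' gamma * Y_j` — covariates frozen at the interval-opening exam, with the
#' baseline-hazard clock restarted at each interval start. Inverse-CDF draw:
#' `T_j = ((-log U) / (lambda^k * exp(eta_j)))^(1/k)`, `U ~ Uniform(0,1)`.
#' The first interval with `T_j <= L` yields the event; otherwise the subject
#' is administratively censored at `n_exams * L`.
#'
#' @param config a [sim_config()] with `weibull_scale` set (see
#'   [resolve_scale()]).
#' @param baseline data.frame from [draw_baseline()].
#' @param y exam-value matrix from [generate_longitudinal()].
#' @return data.frame with `event_interval` (NA when censored),
#'   `event_time_in_interval` (NA when censored), `total_time`, `delta`.
#' @export
generate_survival <- function(config, baseline, y) {
  validate_config(config)
  if (is.null(config$weibull_scale))
    abort_config("weibull_scale is unresolved; call resolve_scale() first")
  n <- nrow(baseline)
  m <- config$n_exams
  L <- config$interval_length
  k <- config$weibull_shape
  lam <- config$weibull_scale
  if (n == 0) {
    return(data.frame(event_interval = integer(0),
                      event_time_in_interval = numeric(0),
                      total_time = numeric(0), delta = integer(0)))
  }
  age_mat <- outer(baseline$baseline_age, rep(1, m)) +
    matrix(exam_times(config), n, m, byrow = TRUE)
  eta <- config$alpha_age * age_mat + config$alpha_sex * baseline$sex +
    config$gamma * y
  u <- matrix(runif(n * m), n, m)
  tcand <- ((-log(u)) / (lam^k * exp(eta)))^(1 / k)
  hit <- tcand <= L
  any_event <- rowSums(hit) > 0
  first <- max.col(hit, ties.method = "first")  # first TRUE when any
  event_interval <- ifelse(any_event, first, NA_integer_)
  event_time <- ifelse(any_event, tcand[cbind(seq_len(n), first)], NA_real_)
  total_time <- ifelse(any_event, L * (first - 1) + event_time, L * m)
  data.frame(
    event_interval = as.integer(event_interval),
    event_time_in_interval = event_time,
    total_time = total_time,
    delta = as.integer(any_event)
  )
}

#' Calibrate the Weibull scale to a target cumulative event rate
#'
#' Given the shape and the covariate model, finds the scale lambda at which
#' the cumulative event proportion over all intervals equals
#' `target_event_rate`. A calibration sample of covariates (baseline and
#' exam values) is drawn once under the reserved calibration seed
#' (`child_seed(master_seed, 0)`); conditional on covariates the per-subject
#' event probability is available in closed form,
#' `P(event) = 1 - exp(-(lambda * L)^k * sum_j exp(eta_j))`, so the expected
#' rate is a smooth monotone function of lambda and the root is found with
#' [uniroot()]. Deterministic given `master_seed`.
#'
#' @param config a [sim_config()].
#' @param target_event_rate target cumulative event proportion in (0, 1);
#'   defaults to `config$target_event_rate`.
#' @param n_calib calibration sample size (default 1e5).
#' @param tol convergence tolerance on the achieved expected rate.
#' @return the calibrated scale (single positive number).
#' @export
calibrate_baseline_hazard <- function(config,
                                      target_event_rate = config$target_event_rate,
                                      n_calib = 1e5, tol = 1e-10) {
  validate_config(config)
  if (is.null(target_event_rate) || !is.numeric(target_event_rate) ||
      length(target_event_rate) != 1 || is.na(target_event_rate) ||
      target_event_rate <= 0 || target_event_rate >= 1)
    abort_config("target_event_rate must be a single number in (0, 1)")
  k <- config$weibull_shape
  L <- config$interval_length
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(config$master_seed, 0))
  baseline <- draw_baseline(config, n_calib)
  y <- generate_longitudinal(config, baseline)$y
  m <- config$n_exams
  age_mat <- outer(baseline$baseline_age, rep(1, m)) +
    matrix(exam_times(config), n_calib, m, byrow = TRUE)
  eta <- config$alpha_age * age_mat + config$alpha_sex * baseline$sex +
    config$gamma * y
  s <- rowSums(exp(eta))  # per-subject sum over intervals of exp(eta_j)
  expected_rate <- function(log_lam) {
    mean(1 - exp(-(exp(log_lam) * L)^k * s))
  }
  f <- function(log_lam) expected_rate(log_lam) - target_event_rate
  lo <- -40; hi <- 20
  if (f(lo) > 0 || f(hi) < 0)
    abort_config("failed to bracket the calibration target")
  root <- uniroot(f, c(lo, hi), tol = tol)$root
  exp(root)
}

#' Resolve the Weibull scale of a configuration
#'
#' Returns `config` with `weibull_scale` filled in: unchanged when already
#' set, otherwise calibrated to `target_event_rate` via
#' [calibrate_baseline_hazard()].
#'
#' @param config a [sim_config()].
#' @param n_calib calibration sample size passed through.
#' @return a `sim_config` with a numeric `weibull_scale`.
#' @export
resolve_scale <- function(config, n_calib = 1e5) {
  if (!is.null(config$weibull_scale)) return(config)
  if (is.null(config$target_event_rate))
    abort_config("either weibull_scale or target_event_rate must be set")
  config$weibull_scale <- calibrate_baseline_hazard(config, n_calib = n_calib)
  config
}

#' Simulate one replicated cohort
#'
#' Draws baseline covariates, longitudinal exam values and interval-wise
#' survival for `config$n_subjects` subjects under the child seed
#' `child_seed(master_seed, replicate_id)`; identical arguments give a
#' bitwise-identical cohort.
#'
#' @param config a [sim_config()]; the scale is resolved automatically when
#'   only `target_event_rate` is set.
#' @param replicate_id positive integer replicate index (0 is reserved for
#'   calibration).
#' @return an object of class `cohort`: list with `subjects` (one row per
#'   subject: `subject_id`, `baseline_age`, `sex`, `u1`, `u2`,
#'   `event_interval`, `event_time_in_interval`, `total_time`, `delta`),
#'   `y` (n x n_exams exam-value matrix), `config`, `replicate_id`.
#' @examples
#' cfg <- sim_config(n_subjects = 50, gamma = 0.5, weibull_scale = 0.02)
#' coh <- simulate_cohort(cfg, replicate_id = 1)
#' table(coh$subjects$delta)
#' @export
simulate_cohort <- function(config, replicate_id = 1) {
  validate_config(config)
  if (replicate_id < 1 || replicate_id != floor(replicate_id))
    abort_config("replicate_id must be a positive integer")
  config <- resolve_scale(config)
  set.seed(child_seed(config$master_seed, replicate_id))
  baseline <- draw_baseline(config)
  long <- generate_longitudinal(config, baseline)
  surv <- generate_survival(config, baseline, long$y)
  subjects <- data.frame(
    subject_id = seq_len(config$n_subjects),
    baseline_age = baseline$baseline_age,
    sex = baseline$sex,
    u1 = long$u1, u2 = long$u2,
    event_interval = surv$event_interval,
    event_time_in_interval = surv$event_time_in_interval,
    total_time = surv$total_time,
    delta = surv$delta
  )
  structure(
    list(subjects = subjects, y = long$y, config = config,
         replicate_id = replicate_id),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x$subjects)
  cat(sprintf("<cohort> replicate %d: %d subjects, %d exams, %d events (%.1f%%)\n",
              x$replicate_id, n, x$config$n_exams, sum(x$subjects$delta),
              if (n > 0) 100 * mean(x$subjects$delta) else NA_real_))
  invisible(x)
}
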