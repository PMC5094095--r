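#' Simulation configuration
#'
#' Bundles every parameter of the cohort generator: the baseline covariate
#' distributions, the random intercept/slope longitudinal model, the
#' proportional-hazards Weibull survival model, and the seeding protocol.
#' Defaults reproduce the Framingham-style study conditions: 6 exams at
#' 5-year spacing, baseline Age ~ Normal(35, 5^2), Sex ~ Bernoulli(0.54)
#' (1 = female), random effects (U1, U2) with mean (4.250, 0.250) and
#' covariance `G`, residual variance 0.116, survival log-hazard
#' `alpha_age * Age_j + alpha_sex * Sex + gamma * Y_j` on top of a Weibull
#' baseline hazard `h0(t) = shape * scale^shape * t^(shape - 1)`.
#'
#' Exactly one of `weibull_scale` and `target_event_rate` should normally be
#' supplied; when `target_event_rate` is given the scale is resolved by
#' [calibrate_baseline_hazard()] (see [resolve_scale()]).
#'
#' @param n_subjects number of subjects per cohort.
#' @param n_exams number of exams (intervals); exam j opens interval j.
#' @param interval_length years between consecutive exams.
#' @param age_mean,age_sd baseline age distribution (years).
#' @param female_prob probability that sex = 1 (female).
#' @param re_mean length-2 mean of the random intercept and slope.
#' @param G 2x2 covariance matrix of the random intercept and slope.
#' @param resid_var residual variance sigma^2 of the exam-level measurement.
#' @param tau coefficient of baseline age in the longitudinal mean. The
#'   defining study did not publish this coefficient; 0.05 is this package's
#'   documented default.
#' @param alpha_age,alpha_sex survival log-hazard coefficients for age at the
#'   interval-opening exam and for sex.
#' @param gamma link coefficient: log hazard ratio per unit of the
#'   longitudinal covariate (the simulation's primary estimand).
#' @param weibull_shape Weibull shape k (> 0); 1 gives an exponential
#'   baseline hazard.
#' @param weibull_scale Weibull scale lambda (> 0), or `NULL` to calibrate.
#' @param target_event_rate cumulative event proportion over all intervals to
#'   which the scale is calibrated (in (0, 1)), or `NULL`.
#' @param master_seed integer master seed; replicate r uses
#'   `child_seed(master_seed, r)` and calibration reserves replicate 0.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_subjects = 100, gamma = 0.5, target_event_rate = 0.5)
#' cfg$gamma
#' @export
sim_config <- function(n_subjects = 1000,
                       n_exams = 6,
                       interval_length = 5,
                       age_mean = 35,
                       age_sd = 5,
                       female_prob = 0.54,
                       re_mean = c(4.250, 0.250),
                       G = matrix(c(0.29, -0.00465, -0.00465, 0.000320), 2, 2),
                       resid_var = 0.116,
                       tau = 0.05,
                       alpha_age = 0.050,
                       alpha_sex = -0.500,
                       gamma = 0.000,
                       weibull_shape = 1,
                       weibull_scale = NULL,
                       target_event_rate = NULL,
                       master_seed = 20160101) {
  cfg <- structure(
    list(
      n_subjects = n_subjects, n_exams = n_exams,
      interval_length = interval_length,
      age_mean = age_mean, age_sd = age_sd, female_prob = female_prob,
      re_mean = re_mean, G = G, resid_var = resid_var, tau = tau,
      alpha_age = alpha_age, alpha_sex = alpha_sex, gamma = gamma,
      weibull_shape = weibull_shape, weibull_scale = weibull_scale,
      target_event_rate = target_event_rate, master_seed = master_seed
    ),
    class = "sim_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) abort_config(msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(cfg$n_subjects) && cfg$n_subjects >= 0 &&
        cfg$n_subjects == floor(cfg$n_subjects),
      "n_subjects must be a non-negative integer")
  chk(num1(cfg$n_exams) && cfg$n_exams >= 1 &&
        cfg$n_exams == floor(cfg$n_exams), "n_exams must be >= 1")
  chk(num1(cfg$interval_length) && cfg$interval_length > 0,
      "interval_length must be > 0")
  chk(num1(cfg$age_sd) && cfg$age_sd >= 0, "age_sd must be >= 0")
  chk(num1(cfg$female_prob) && cfg$female_prob >= 0 && cfg$female_prob <= 1,
      "female_prob must be in [0, 1]")
  chk(is.numeric(cfg$re_mean) && length(cfg$re_mean) == 2,
      "re_mean must have length 2")
  G <- cfg$G
  chk(is.matrix(G) && all(dim(G) == c(2, 2)), "G must be a 2x2 matrix")
  chk(max(abs(G - t(G))) < 1e-12, "G must be symmetric")
  chk(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) >= -1e-12,
      "G must be positive semidefinite")
  chk(num1(cfg$resid_var) && cfg$resid_var >= 0, "resid_var must be >= 0")
  chk(num1(cfg$weibull_shape) && cfg$weibull_shape > 0,
      "weibull_shape must be > 0")
  if (!is.null(cfg$weibull_scale))
    chk(num1(cfg$weibull_scale) && cfg$weibull_scale > 0,
        "weibull_scale must be > 0")
  if (!is.null(cfg$target_event_rate))
    chk(num1(cfg$target_event_rate) && cfg$target_event_rate > 0 &&
          cfg$target_event_rate < 1, "target_event_rate must be in (0, 1)")
  chk(num1(cfg$master_seed), "master_seed must be a single number")
  invisible(cfg)
}

#' Exam times of a configuration
#'
#' Interval-opening exam times `interval_length * (0:(n_exams - 1))`; with
#' the defaults these are coded 0, 5, 10, 15, 20, 25.
#'
#' @param config a [sim_config()].
#' @return numeric vector of length `n_exams`.
#' @export
exam_times <- function(config) {
  config$interval_length * (seq_len(config$n_exams) - 1)
}

# Deterministic seed splitting: replicate r of a run with master seed m gets
# (m mod 46300) * 46300 + (r mod 46300), which stays below 2^31 - 1.
# Replicate 0 is reserved for hazard calibration.
child_seed <- function(master_seed, replicate_id) {
  a <- as.numeric(master_seed) %% 46300
  b <- as.numeric(replicate_id) %% 46300
  as.integer(a * 46300 + b)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort: %d subjects, %d exams every %g years\n",
              x$n_subjects, x$n_exams, x$interval_length))
  cat(sprintf("  longitudinal: re_mean = (%g, %g), sigma^2 = %g, tau = %g\n",
              x$re_mean[1], x$re_mean[2], x$resid_var, x$tau))
  cat(sprintf("  survival: alpha_age = %g, alpha_sex = %g, gamma = %g\n",
              x$alpha_age, x$alpha_sex, x$gamma))
  scale_txt <- if (is.null(x$weibull_scale)) "to be calibrated"
               else format(x$weibull_scale)
  cat(sprintf("  weibull: shape = %g, scale = %s", x$weibull_shape, scale_txt))
  if (!is.null(x$target_event_rate))
    cat(sprintf(" (target event rate %g)", x$target_event_rate))
  cat(sprintf("\n  master_seed: %s\n", format(x$master_seed)))
  invisible(x)
}
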