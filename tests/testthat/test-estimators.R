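test_that("Cox fit matches the brute-force partial-likelihood maximizer", {
  # fixed 5-subject fixture, binary covariate constant over exams
  coh <- make_cohort(
    baseline_age = rep(0, 5), sex = rep(0, 5),
    y = matrix(rep(c(1, 0, 1, 0, 1), 6), nrow = 5),
    event_interval = c(1L, 1L, 2L, 3L, NA),
    event_time = c(2.0, 3.5, 1.2, 4.0, NA)
  )
  cp <- build_counting_process(coh)
  fit <- fit_cox(cp, covariates = "link")
  oracle <- oracle_maximize(function(b) breslow_loglik_cp(b, cp))
  expect_equal(unname(fit$coef["link"]), oracle, tolerance = 1e-4)

  # random tiny cohorts, counting-process and person-period axes
  for (coh in tiny_cohorts(5)) {
    cp <- build_counting_process(coh)
    fit <- fit_cox(cp, covariates = "link")
    oracle <- oracle_maximize(function(b) breslow_loglik_cp(b, cp))
    expect_equal(unname(fit$coef["link"]), oracle, tolerance = 1e-4)

    pp <- build_person_period(coh)
    fit_pp <- fit_cox(pp, covariates = "link")
    oracle_pp <- oracle_maximize(function(b) breslow_loglik_pp(b, pp))
    expect_equal(unname(fit_pp$coef["link"]), oracle_pp, tolerance = 1e-4)

    fit_st <- fit_cox(pp, covariates = "link", stratify_by_interval = TRUE)
    oracle_st <- oracle_maximize(
      function(b) breslow_loglik_pp(b, pp, stratified = TRUE))
    expect_equal(unname(fit_st$coef["link"]), oracle_st, tolerance = 1e-4)
  }
})

test_that("a sign-symmetric dataset gives a zero link estimate", {
  coh <- make_cohort(
    baseline_age = rep(0, 4), sex = rep(0, 4),
    y = matrix(rep(c(1, -1, 1, -1), 6), nrow = 4),
    event_interval = c(1L, 1L, 2L, 2L),
    event_time = c(1, 1, 2, 2)
  )
  fit <- fit_cox(build_counting_process(coh), covariates = "link")
  expect_equal(unname(fit$coef["link"]), 0, tolerance = 1e-8)
})

test_that("logistic fit equals the closed-form 2x2 log odds ratio", {
  rows <- data.frame(
    y = rep(c(1, 0), each = 50),
    event = c(rep(1, 10), rep(0, 40), rep(1, 5), rep(0, 45)),
    age_at_exam = 0, sex = 0, interval_start_time = 0
  )
  fit <- fit_logistic(rows, covariates = "link")
  expect_equal(unname(fit$coef["link"]), log((10 / 40) / (5 / 45)),
               tolerance = 1e-8)
  expect_equal(unname(fit$coef["intercept"]), log(5 / 45), tolerance = 1e-8)
  # and a second table
  rows2 <- data.frame(
    y = rep(c(1, 0), c(30, 60)),
    event = c(rep(1, 12), rep(0, 18), rep(1, 6), rep(0, 54)),
    age_at_exam = 0, sex = 0, interval_start_time = 0
  )
  fit2 <- fit_logistic(rows2, covariates = "link")
  expect_equal(unname(fit2$coef["link"]), log((12 / 18) / (6 / 54)),
               tolerance = 1e-8)
})

test_that("degenerate outcomes are estimation errors", {
  pp <- build_person_period(toy_cohort())
  pp$event <- 0L
  expect_error(fit_logistic(pp), class = "survpool_estimation_error")
  expect_error(fit_cox(pp), class = "survpool_estimation_error")
  pp$event <- 1L
  expect_error(fit_logistic(pp), class = "survpool_estimation_error")
})

test_that("method dispatch covers the five strategies with correct terms", {
  cfg <- sim_config(n_subjects = 250, gamma = 0.5, target_event_rate = 0.5,
                    master_seed = 12)
  coh <- simulate_cohort(resolve_scale(cfg, n_calib = 20000), 1)
  fits <- fit_all_methods(coh)
  expect_named(fits, c("CSP_UN", "CSP_AD", "TDCM", "PLR_UN", "PLR_AD"))
  for (m in names(fits)) {
    f <- fits[[m]]
    expect_true(f$converged)
    expect_true(all(c("link", "age", "sex") %in% names(f$coef)))
    expect_equal(f$ci_lower, f$coef - qnorm(0.975) * f$se)
    expect_equal(f$ci_upper, f$coef + qnorm(0.975) * f$se)
    has_int <- "intercept" %in% names(f$coef)
    expect_equal(has_int, m %in% c("PLR_UN", "PLR_AD"))
    expect_equal("time" %in% names(f$coef), m == "PLR_AD")
  }
  expect_error(fit_method("COX", coh), class = "survpool_config_error")
})

test_that("interval-stratified pooling equals the time-dependent Cox model", {
  cfg <- sim_config(n_subjects = 300, gamma = 1, target_event_rate = 0.9,
                    master_seed = 21)
  coh <- simulate_cohort(resolve_scale(cfg, n_calib = 20000), 1)
  a <- fit_method("CSP_AD", coh)
  b <- fit_method("TDCM", coh)
  expect_equal(unname(a$coef), unname(b$coef), tolerance = 1e-8)
  expect_equal(unname(a$se), unname(b$se), tolerance = 1e-8)
})

test_that("a common age shift leaves stratified estimates unchanged", {
  cfg <- sim_config(n_subjects = 200, gamma = 0.5, weibull_scale = 3e-5,
                    master_seed = 8)
  coh <- simulate_cohort(cfg, 1)
  shifted <- coh
  shifted$subjects$baseline_age <- shifted$subjects$baseline_age + 10
  for (m in c("CSP_AD", "TDCM")) {
    f0 <- fit_method(m, coh)
    f1 <- fit_method(m, shifted)
    expect_equal(f1$coef[c("link", "sex")], f0$coef[c("link", "sex")],
                 tolerance = 1e-6)
  }
})

test_that("tidy_fits flattens results to serializable records", {
  coh <- simulate_cohort(
    sim_config(n_subjects = 150, gamma = 0.5, weibull_scale = 3e-5,
               master_seed = 4), 1)
  rec <- tidy_fits(fit_all_methods(coh, c("TDCM", "PLR_AD")))
  expect_setequal(names(rec), c("method", "term", "estimate", "se", "ci_low",
                                "ci_high", "p", "converged"))
  expect_equal(sum(rec$method == "TDCM"), 3)   # link, age, sex
  expect_equal(sum(rec$method == "PLR_AD"), 5) # + intercept, time
  expect_true(all(rec$p >= 0 & rec$p <= 1))
})
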