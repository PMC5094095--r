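# Hand-built cohorts and independent brute-force oracles used across tests.

# Assemble a cohort object directly from subject-level fields.
make_cohort <- function(baseline_age, sex, y, event_interval, event_time,
                        interval_length = 5) {
  y <- as.matrix(y)
  n <- nrow(y)
  m <- ncol(y)
  delta <- as.integer(!is.na(event_interval))
  total_time <- ifelse(delta == 1,
                       interval_length * (event_interval - 1) + event_time,
                       interval_length * m)
  subjects <- data.frame(
    subject_id = seq_len(n),
    baseline_age = baseline_age,
    sex = sex,
    u1 = NA_real_, u2 = NA_real_,
    event_interval = as.integer(event_interval),
    event_time_in_interval = event_time,
    total_time = total_time,
    delta = delta
  )
  cfg <- sim_config(n_subjects = n, n_exams = m,
                    interval_length = interval_length, weibull_scale = 1)
  structure(list(subjects = subjects, y = y, config = cfg,
                 replicate_id = 1L),
            class = "cohort")
}

# The worked 3-subject example: event in interval 2 at 1.0 y; censored;
# event in interval 6 at 4.9 y.
toy_cohort <- function() {
  make_cohort(
    baseline_age = c(30, 35, 40),
    sex = c(0, 1, 0),
    y = matrix(seq_len(18) / 10, nrow = 3, byrow = TRUE),
    event_interval = c(2L, NA, 6L),
    event_time = c(1.0, NA, 4.9)
  )
}

# Breslow log partial likelihood for counting-process rows, one covariate.
breslow_loglik_cp <- function(beta, rows, xcol = "y_current") {
  x <- rows[[xcol]]
  ev <- rows$event == 1
  ll <- 0
  for (t in unique(rows$stop[ev])) {
    at_t <- ev & rows$stop == t
    risk <- rows$start < t & t <= rows$stop
    ll <- ll + beta * sum(x[at_t]) -
      sum(at_t) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# Breslow log partial likelihood for person-period rows on the
# within-interval time axis, optionally stratified by interval.
breslow_loglik_pp <- function(beta, rows, xcol = "y", stratified = FALSE) {
  x <- rows[[xcol]]
  ev <- rows$event == 1
  strat <- if (stratified) rows$interval_index else rep(1L, nrow(rows))
  ll <- 0
  for (i in which(ev)) {
    t <- rows$time_in_interval[i]
    risk <- rows$time_in_interval >= t & strat == strat[i]
    at_t <- ev & rows$time_in_interval == t & strat == strat[i]
    # each tied event contributes the full-risk-set denominator once; handle
    # per event row so ties are counted like Breslow
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_maximize <- function(loglik, lower = -5, upper = 5) {
  stats::optimize(function(b) -loglik(b), c(lower, upper), tol = 1e-10)$minimum
}

# Small seeded cohorts with at least `min_events` events and one censored
# subject, for oracle comparisons.
tiny_cohorts <- function(k = 5, n = 8, min_events = 2) {
  out <- list()
  for (seed in 1:200) {
    cfg <- sim_config(n_subjects = n, gamma = 0.4, weibull_scale = 5e-5,
                      tau = 0.03, master_seed = seed)
    coh <- simulate_cohort(cfg, 1)
    nev <- sum(coh$subjects$delta)
    if (nev >= min_events && nev < n) out[[length(out) + 1]] <- coh
    if (length(out) == k) return(out)
  }
  stop("could not assemble tiny fixtures")
}
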