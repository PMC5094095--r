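test_that("person-period layout of the 3-subject worked example", {
  pp <- build_person_period(toy_cohort())
  expect_equal(nrow(pp), 14)
  expect_equal(as.vector(table(pp$subject_id)), c(2, 6, 6))
  expect_equal(sum(pp$event), 2)
  s1 <- pp[pp$subject_id == 1, ]
  expect_equal(s1$time_in_interval, c(5, 1.0))
  expect_equal(s1$event, c(0L, 1L))
  expect_equal(s1$interval_start_time, c(0, 5))
  expect_equal(s1$age_at_exam, c(30, 35))
  # exam times carried on the common grid
  expect_equal(sort(unique(pp$interval_start_time)), c(0, 5, 10, 15, 20, 25))
})

test_that("counting-process layout of the worked example", {
  cp <- build_counting_process(toy_cohort())
  expect_equal(as.vector(table(cp$subject_id)), c(2, 6, 6))
  s1 <- cp[cp$subject_id == 1, ]
  expect_equal(s1$start, c(0, 5))
  expect_equal(s1$stop, c(5, 6))
  expect_equal(s1$event, c(0L, 1L))
  expect_equal(unique(s1$baseline_age), 30)  # age fixed on all rows
  s2 <- cp[cp$subject_id == 2, ]  # censored: last row (25, 30], no event
  expect_equal(s2$stop[6], 30)
  expect_equal(sum(s2$event), 0)
  s3 <- cp[cp$subject_id == 3, ]
  expect_equal(s3$stop[6], 29.9)
})

test_that("a first-interval event yields a single row in both layouts", {
  coh <- make_cohort(baseline_age = 40, sex = 1,
                     y = matrix(1:6, 1), event_interval = 1L,
                     event_time = 2.3)
  pp <- build_person_period(coh)
  cp <- build_counting_process(coh)
  expect_equal(nrow(pp), 1)
  expect_equal(pp$time_in_interval, 2.3)
  expect_equal(pp$event, 1L)
  expect_equal(pp$interval_start_time, 0)
  expect_equal(cp$start, 0)
  expect_equal(cp$stop, 2.3)
})

test_that("row-count and exposure identities hold on a simulated cohort", {
  cfg <- sim_config(n_subjects = 200, gamma = 0.5, weibull_scale = 1e-4,
                    master_seed = 31)
  coh <- simulate_cohort(cfg, 1)
  pp <- build_person_period(coh)
  cp <- build_counting_process(coh)
  expect_equal(nrow(pp), nrow(cp))
  expect_equal(sum(pp$event), sum(cp$event))
  expect_equal(sum(pp$event), sum(coh$subjects$delta))
  expect_equal(sum(pp$time_in_interval), sum(cp$stop - cp$start))
  expect_equal(sum(pp$time_in_interval), sum(coh$subjects$total_time))
  # y values pulled from the correct exam
  expect_equal(pp$y, coh$y[cbind(pp$subject_id, pp$interval_index)])
  # idempotence
  expect_identical(pp, build_person_period(coh))
  expect_identical(cp, build_counting_process(coh))
})

test_that("corrupt event times are rejected", {
  coh <- make_cohort(baseline_age = 40, sex = 1, y = matrix(1:6, 1),
                     event_interval = 2L, event_time = 6.5)  # > interval
  expect_error(build_person_period(coh), class = "survpool_data_error")
  coh$subjects$event_time_in_interval <- 0
  expect_error(build_counting_process(coh), class = "survpool_data_error")
})

test_that("long CSV round-trips to identical analysis datasets", {
  cfg <- sim_config(n_subjects = 60, gamma = 0.5, weibull_scale = 1e-4,
                    master_seed = 77)
  coh <- simulate_cohort(cfg, 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  coh2 <- read_long_csv(path)
  pp1 <- build_person_period(coh)
  pp2 <- build_person_period(coh2)
  pp2$subject_id <- as.integer(pp2$subject_id)
  expect_equal(pp2, pp1, tolerance = 1e-12)
  cp1 <- build_counting_process(coh)
  cp2 <- build_counting_process(coh2)
  cp2$subject_id <- as.integer(cp2$subject_id)
  expect_equal(cp2, cp1, tolerance = 1e-12)
})

test_that("the worked-example CSV reconstructs its 3 subjects", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(toy_cohort(), path)
  expect_equal(nrow(read.csv(path)), 14)
  coh <- read_long_csv(path)
  expect_equal(nrow(coh$subjects), 3)
  expect_equal(sum(coh$subjects$delta), 2)
  expect_equal(coh$subjects$total_time, c(6, 30, 29.9))
})

test_that("schema violations are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(toy_cohort(), path)
  base <- read.csv(path)

  # rows for a subject after its event row
  extra <- base[base$subject_id == 1 & base$exam_index == 2, ]
  extra$exam_index <- 3
  extra$exam_time <- 10
  extra$age_at_exam <- extra$age_at_exam + 5
  extra$event_in_interval <- 0
  extra$time_in_interval <- 5
  bad <- rbind(base, extra)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, p2, row.names = FALSE)
  expect_error(read_long_csv(p2), "event row",
               class = "survpool_data_error")

  # duplicate (subject, exam)
  bad <- rbind(base, base[1, ])
  write.csv(bad, p2, row.names = FALSE)
  expect_error(read_long_csv(p2), "duplicate",
               class = "survpool_data_error")

  # missing column
  write.csv(base[, setdiff(names(base), "y")], p2, row.names = FALSE)
  expect_error(read_long_csv(p2), "missing columns",
               class = "survpool_data_error")

  # exam times off the common grid
  bad <- base
  bad$exam_time[bad$subject_id == 2 & bad$exam_index == 3] <- 11
  write.csv(bad, p2, row.names = FALSE)
  expect_error(read_long_csv(p2), class = "survpool_data_error")
})
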