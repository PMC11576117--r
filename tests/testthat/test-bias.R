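fake_patients <- function(death_age, last_visit_age) {
  data.frame(patient_id = seq_along(last_visit_age),
             death_age = death_age, last_visit_age = last_visit_age)
}

test_that("implied mean death age follows the midpoint definition", {
  p <- fake_patients(c(60, 70), c(55, 65))
  expect_equal(implied_mean_death_age(p, 100), 65)   # all recorded: no U
  expect_equal(implied_mean_death_age(p, 40), 65)
  p2 <- fake_patients(c(NA, 64), c(50, 60))
  expect_equal(implied_mean_death_age(p2, 70), ((50 + 70) / 2 + 64) / 2)
  # last visit beyond U contributes its own age
  p3 <- fake_patients(NA, 90)
  expect_equal(implied_mean_death_age(p3, 70), 90)
  expect_error(implied_mean_death_age(fake_patients(numeric(0), numeric(0)),
                                      70), "empty")
})

test_that("implied mean is monotone non-decreasing in the bound", {
  set.seed(20)
  p <- fake_patients(ifelse(runif(300) < 0.05, 60 + rnorm(300, sd = 8), NA),
                     45 + runif(300, 0, 30))
  grid <- seq(0, 120, by = 2.5)
  v <- vapply(grid, function(U) implied_mean_death_age(p, U), numeric(1))
  expect_true(all(diff(v) >= -1e-12))
})

test_that("bisection calibration hits the target and matches a grid search", {
  co <- generate_cohort(cohort_params(800, seed = 22))
  cal <- calibrate_upper_bound(co)
  expect_lt(abs(cal$implied_mean - 63.9), 0.01 + 1e-9)
  grid <- seq(0, 120, by = 0.02)
  err <- abs(vapply(grid, function(U) implied_mean_death_age(co, U),
                    numeric(1)) - 63.9)
  expect_lt(abs(cal$upper_bound - grid[which.min(err)]), 0.05)
})

test_that("calibration fails informatively when the target is unreachable", {
  p <- fake_patients(c(50, 52), c(45, 47))     # nothing censored
  expect_error(calibrate_upper_bound(p, bias_calibration(63.9)),
               "no censored")
  p2 <- fake_patients(c(NA, NA), c(80, 85))    # floor above the target
  expect_error(calibrate_upper_bound(p2, bias_calibration(63.9)),
               "achievable")
})

test_that("censoring events are constructed per the augmentation rules", {
  co <- generate_cohort(cohort_params(100, true_model =
                                        default_emission_model(),
                                      seed = 23))
  ev <- recovery_events(co, upper_bound = 80)
  rec <- co$patients$patient_id[!is.na(co$patients$death_age)]
  cen <- setdiff(co$patients$patient_id, rec)
  expect_setequal(ev$patient_id[ev$kind == "death_exact"], rec)
  expect_setequal(ev$patient_id[ev$kind == "death_interval"], cen)
  expect_setequal(ev$patient_id[ev$kind == "birth"],
                  co$patients$patient_id)
  iv <- ev[ev$kind == "death_interval", ]
  lv <- co$patients$last_visit_age[match(iv$patient_id,
                                         co$patients$patient_id)]
  expect_equal(iv$lo, as.numeric(lv))
  expect_equal(iv$hi, pmax(80, as.numeric(lv) + 0.01))
  # without an upper bound, censored patients get no death event
  ev0 <- recovery_events(co, upper_bound = NULL)
  expect_false(any(ev0$kind == "death_interval"))
})

test_that("the correction shrinks the final-state sojourn toward truth", {
  co <- generate_cohort(cohort_params(500, true_model =
                                        default_emission_model(),
                                      seed = 24))
  cal <- calibrate_upper_bound(co)
  fc <- fit_cthmm(init_model_from_events(recovery_events(co,
                                                         cal$upper_bound),
                                         5),
                  recovery_events(co, cal$upper_bound))
  fu <- fit_cthmm(init_model_from_events(recovery_events(co, NULL), 5),
                  recovery_events(co, NULL))
  s4c <- mean_sojourn_times(fc$model)[4]
  s4u <- mean_sojourn_times(fu$model)[4]
  expect_lt(abs(s4c - 11.4), abs(s4u - 11.4))
})
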