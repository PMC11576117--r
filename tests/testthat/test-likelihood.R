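toy_model <- function() {
  progression_model(c(0.4, 0.25),
                    emission_means = cbind(PC1 = c(-1, 1.5)),
                    emission_sds = cbind(PC1 = c(0.8, 1.1)))
}

test_that("likelihood matches closed forms on pinned configurations", {
  m <- progression_model(0.5, emission_means = matrix(1, 1, 1),
                         emission_sds = matrix(2, 1, 1),
                         feature_names = "PC1")
  ev <- single_patient_events(0, matrix(0.3, 1, 1,
                                        dimnames = list(NULL, "PC1")))
  expect_equal(log_likelihood(m, ev), dnorm(0.3, 1, 2, log = TRUE),
               tolerance = 1e-12)
  ev2 <- single_patient_events(numeric(0),
                               matrix(numeric(0), 0, 1,
                                      dimnames = list(NULL, "PC1")),
                               death_age = 3)
  expect_equal(log_likelihood(m, ev2), log(exp(-0.5 * 3) * 0.5),
               tolerance = 1e-12)
  ev3 <- single_patient_events(numeric(0),
                               matrix(numeric(0), 0, 1,
                                      dimnames = list(NULL, "PC1")),
                               dlo = 2, dhi = 5)
  expect_equal(log_likelihood(m, ev3), log(exp(-1) - exp(-2.5)),
               tolerance = 1e-12)
})

test_that("likelihood matches a 2-D quadrature oracle on 3-state toys", {
  m <- toy_model()
  cases <- list(
    list(ages = c(1.5, 4), x = c(-0.8, 1.2), death = 7.25),
    list(ages = c(2, 5, 6.5), x = c(-1.2, 0.4, 2.1), dlo = 6.5, dhi = 20),
    list(ages = c(0.5, 3), x = c(-1, -0.6), death = NULL)
  )
  for (cs in cases) {
    X <- matrix(cs$x, ncol = 1, dimnames = list(NULL, "PC1"))
    ev <- single_patient_events(cs$ages, X, death_age = cs$death,
                                dlo = cs$dlo, dhi = cs$dhi)
    oracle <- loglik_quadrature_3state(
      0.4, 0.25, mu = c(-1, 1.5), sd1 = c(0.8, 1.1),
      visit_ages = cs$ages, x = cs$x, death_age = cs$death,
      dlo = cs$dlo, dhi = cs$dhi, grid_n = 2000L, horizon = 80)
    expect_equal(log_likelihood(m, ev), oracle, tolerance = 5e-3)
  }
})

test_that("compiled likelihood agrees with the expm-based reference", {
  co <- generate_cohort(cohort_params(60, true_model =
                                        default_emission_model(), seed = 4))
  ev <- recovery_events(co, upper_bound = 80)
  m <- default_emission_model()
  expect_equal(log_likelihood(m, ev), hdprog:::loglik_reference(m, ev),
               tolerance = 1e-8)
})

test_that("zero-probability configurations give -Inf, not an error", {
  m <- toy_model()
  # death interval before any possible transit through both states is
  # impossible only with zero-width interval at age 0; use an exact death
  # at age 0 instead: occupancy of state 2 at time 0 is 0
  ev <- single_patient_events(numeric(0),
                              matrix(numeric(0), 0, 1,
                                     dimnames = list(NULL, "PC1")),
                              death_age = 0)
  expect_identical(log_likelihood(m, ev), -Inf)
})

test_that("event validation catches malformed sequences", {
  blank <- matrix(NA_real_, 2, 1, dimnames = list(NULL, "PC1"))
  df <- data.frame(patient_id = "a", kind = c("death_exact", "death_exact"),
                   age = c(5, 6), lo = NA_real_, hi = NA_real_, blank)
  expect_error(as_hd_events(df, "PC1"), "more than one death")
  df2 <- data.frame(patient_id = "a", kind = c("visit", "death_exact"),
                    age = c(5, 4), lo = NA_real_, hi = NA_real_,
                    rbind(c(PC1 = 0.2), c(PC1 = NA)))
  expect_error(as_hd_events(df2, "PC1"), "death must not precede")
  df3 <- data.frame(patient_id = "a", kind = "visit", age = c(3, 3),
                    lo = NA_real_, hi = NA_real_,
                    matrix(0, 2, 1, dimnames = list(NULL, "PC1")))
  expect_error(as_hd_events(df3, "PC1"), "strictly increasing")
  expect_error(as_hd_events(df3[, -3], "PC1"), "missing column")
})

test_that("viterbi equals exhaustive path enumeration", {
  set.seed(31)
  for (rep in 1:6) {
    ns <- sample(3:4, 1)
    mu <- sort(rnorm(ns - 1, sd = 2))
    m <- progression_model(runif(ns - 1, 0.1, 0.8),
                           emission_means = cbind(PC1 = mu),
                           emission_sds = cbind(PC1 = runif(ns - 1, 0.5,
                                                            1.5)))
    nv <- sample(2:5, 1)
    ages <- sort(runif(nv, 0.5, 12))
    X <- matrix(rnorm(nv, sample(mu, nv, replace = TRUE), 0.7), ncol = 1,
                dimnames = list(NULL, "PC1"))
    death <- switch(sample(3, 1),
                    NULL,
                    list(kind = "exact", age = max(ages) + runif(1, 0.5, 3)),
                    list(kind = "interval", lo = max(ages),
                         hi = max(ages) + 15))
    ev <- single_patient_events(
      ages, X,
      death_age = if (!is.null(death) && death$kind == "exact") death$age,
      dlo = if (!is.null(death) && death$kind == "interval") death$lo,
      dhi = if (!is.null(death) && death$kind == "interval") death$hi)
    got <- viterbi(m, ev)
    expect_identical(got$state, viterbi_bruteforce(m, ages, X, death))
  }
})

test_that("viterbi respects structure on simple cases", {
  m1 <- progression_model(0.2, emission_means = matrix(0, 1, 1),
                          emission_sds = matrix(1, 1, 1),
                          feature_names = "PC1")
  X <- matrix(rnorm(4), ncol = 1, dimnames = list(NULL, "PC1"))
  ev <- single_patient_events(c(1, 2, 3, 4), X)
  expect_identical(viterbi(m1, ev)$state, rep(1L, 4))

  m <- default_emission_model()
  X2 <- matrix(c(-2, -0.3, 0, 1.1, 0, 2.6, 0, 0), ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("PC1", "PC2")))
  ev2 <- single_patient_events(c(20, 40, 55, 68), X2)
  st <- viterbi(m, ev2)$state
  expect_true(all(diff(st) >= 0))
  expect_lt(st[1], st[4])
})

test_that("fitting recovers a 2-state model and ascends from the truth", {
  truth <- progression_model(0.25,
                             emission_means = matrix(c(0.5), 1, 1),
                             emission_sds = matrix(1, 1, 1),
                             feature_names = "PC1")
  set.seed(8)
  rows <- lapply(1:400, function(i) {
    d <- rexp(1, 0.25)
    ages <- seq(0.5, by = 1, length.out = 3)
    ages <- ages[ages < d]
    X <- matrix(rnorm(length(ages), 0.5, 1), ncol = 1,
                dimnames = list(NULL, "PC1"))
    blank <- matrix(NA_real_, 1, 1, dimnames = list(NULL, "PC1"))
    out <- data.frame(patient_id = paste0("p", i), kind = "birth", age = 0,
                      lo = NA_real_, hi = NA_real_, blank)
    if (length(ages))
      out <- rbind(out, data.frame(patient_id = paste0("p", i),
                                   kind = "visit", age = ages,
                                   lo = NA_real_, hi = NA_real_, X))
    rbind(out, data.frame(patient_id = paste0("p", i), kind = "death_exact",
                          age = d + 1e-3, lo = NA_real_, hi = NA_real_,
                          blank))
  })
  ev <- as_hd_events(do.call(rbind, rows), "PC1")
  fit <- fit_cthmm(init_model_from_events(ev, 2), ev)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$rates[1] - 0.25) / 0.25, 0.1)
  # refitting from the truth never decreases the likelihood
  fit2 <- fit_cthmm(truth, ev)
  expect_gte(fit2$log_likelihood, log_likelihood(truth, ev) - 1e-6)
  # determinism
  fitb <- fit_cthmm(init_model_from_events(ev, 2), ev)
  expect_equal(fit$log_likelihood, fitb$log_likelihood, tolerance = 1e-12)
})
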