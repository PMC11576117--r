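test_that("Dirichlet decomposition sums exactly and matches moments", {
  set.seed(50)
  shares <- c(0.1, 0.2, 0.4, 0.3)
  for (i in 1:50) {
    d <- dirichlet_decompose(1234.5, shares, concentration = 10)
    expect_equal(sum(d), 1234.5, tolerance = 1e-9)
    expect_true(all(d >= 0))
  }
  expect_equal(dirichlet_decompose(0, shares), rep(0, 4))
  d0 <- replicate(2000, dirichlet_decompose(1, c(0.5, 0, 0.5), 10))
  expect_true(all(d0[2, ] == 0))          # zero share stays exactly zero
  # moments against the closed form
  P <- hdprog:::rdirichlet_mat(100000, 10 * shares)
  expect_equal(colMeans(P), shares, tolerance = 0.01)
  expect_equal(apply(P, 2, var), shares * (1 - shares) / 11,
               tolerance = 0.05)
  expect_error(dirichlet_decompose(1, c(0.5, 0.2)), "sum to 1")
  expect_error(dirichlet_decompose(1, shares, concentration = 0),
               "positive")
})

test_that("simulated progression matches the model law", {
  m <- default_progression_model()
  tr <- simulate_progression(m, 10000, seed = 51)
  expect_identical(tr, simulate_progression(m, 10000, seed = 51))
  d1 <- tr[, 2] - tr[, 1]
  expect_lt(abs(mean(d1) - 23.6), 3 * sd(d1) / sqrt(10000))
  death <- tr[, 5]
  expect_lt(abs(mean(death) - sum(true_sojourns())),
            3 * sd(death) / sqrt(10000))
})

test_that("patient costs are quantile-coupled across states", {
  cd <- cost_dist_from_table()
  u <- c(0.2, 0.5, 0.9)
  M <- sample_patient_costs(u, cd)
  expect_equal(dim(M), c(3L, 4L))
  # medians at u = 0.5
  expect_equal(M[2, ], vapply(1:4, function(s)
    state_cost_quantile(cd, s, 0.5), numeric(1)),
    ignore_attr = TRUE)
  # comonotone: ordering in u preserved in every state
  for (s in 1:4) expect_true(all(diff(M[, s]) > 0))
  # LLN: population mean per state near the distribution mean
  set.seed(52)
  MM <- sample_patient_costs(runif(10000), cd)
  for (s in 1:4)
    expect_lt(abs(mean(MM[, s]) - state_cost_mean(cd, s)) /
                state_cost_mean(cd, s), 0.05)
})

test_that("interventions shift later entries and extend the target state", {
  m <- default_progression_model()
  tr <- simulate_progression(m, 500, seed = 53)
  iv <- intervention(2, 10)
  tr2 <- apply_intervention(tr, iv)
  expect_equal(tr2[, 1:2], tr[, 1:2], ignore_attr = TRUE)
  expect_equal(tr2[, 3:5], tr[, 3:5] + 10, ignore_attr = TRUE)
  # time in state 2 grows by exactly the delay, later sojourns unchanged
  expect_equal((tr2[, 3] - tr2[, 2]) - (tr[, 3] - tr[, 2]), rep(10, 500))
  expect_equal(tr2[, 4] - tr2[, 3], tr[, 4] - tr[, 3])
  expect_equal(apply_intervention(tr, intervention(2, 0)), tr)
  # single-trajectory (data frame) form
  t1 <- sample_trajectory(m, seed = 54)
  t1b <- apply_intervention(t1, iv)
  expect_equal(t1b$entry_age[3:5], t1$entry_age[3:5] + 10)
  expect_error(intervention(2, -1), "delay")
})

test_that("lifetime cost integrates monthly costs with the GDP rules", {
  # one living state occupied 2 years at 100/month, all in one category
  lc <- lifetime_cost(c(0, 2, 2.0001), state_costs = c(100, 100),
                      category_props = rbind(c(0, 1, 0, 0), c(0, 1, 0, 0)),
                      salary = 0, pension_age = 66)
  expect_equal(lc$total, 100 * 12 * 2 + 100 * 12 * 1e-4, tolerance = 1e-6)
  expect_equal(unname(lc$by_category["benefits"]), 0)
  # zero costs cost nothing
  expect_equal(lifetime_cost(c(0, 30, 60), c(0, 0),
                             rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                             salary = 0)$total, 0)
  # death at 56 with pension age 66: exactly 10 years of post-death GDP loss
  lc2 <- lifetime_cost(c(0, 40, 56), c(0, 0),
                       rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                       salary = 24000, pension_age = 66)
  expect_equal(unname(lc2$by_category["lost_gdp"]), 24000 * 10)
  # living lost-GDP stops at pension age
  lc3 <- lifetime_cost(c(0, 60, 80), c(0, 1200),
                       rbind(c(0, 0, 1, 0), c(0, 0, 1, 0)),
                       salary = 0, pension_age = 66)
  expect_equal(lc3$total, 1200 * 12 * 6)   # only ages 60-66 accrue
})

test_that("scenario comparison uses common random numbers", {
  cfg <- scenario_config(2000, seed = 55)
  m <- default_progression_model()
  zero <- compare_scenarios(m, intervention(2, 0), cfg)
  expect_true(all(zero$saving == 0))
  sc <- compare_scenarios(m, intervention(2, 10), cfg)
  sc2 <- compare_scenarios(m, intervention(2, 10), cfg)
  expect_equal(sc$mean_saving, sc2$mean_saving, tolerance = 1e-12)
  expect_equal(sc$saving, sc$baseline_total - sc$intervention_total)
})
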