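test_that("salary interpolation is monotone and exact at table points", {
  tab <- data.frame(percentile = c(0.25, 0.5, 0.75),
                    annual_salary = c(20000, 27000, 38000))
  expect_equal(sample_salary(0.5, tab), 27000)
  expect_equal(sample_salary(0.625, tab), (27000 + 38000) / 2)
  p <- sort(runif(50, 0.01, 0.99))
  expect_true(all(diff(sample_salary(p, tab)) >= 0))
  expect_equal(sample_salary(0.01, tab), 20000)      # clamped at the edge
  expect_error(sample_salary(0, tab), "percentile")
  expect_error(sample_salary(1.2, tab), "percentile")
})

test_that("lost GDP follows the occupation, pension and death rules", {
  expect_equal(lost_gdp(30000, 3, age = 40), 0)
  expect_equal(lost_gdp(24000, 2, age = 40), 1000)
  expect_equal(lost_gdp(24000, 1, age = 40), 2000)
  expect_equal(lost_gdp(24000, 1, age = 70), 0)        # at/above pension age
  expect_equal(lost_gdp(24000, 3, age = 60, death_age = 56), 2000)
  expect_equal(lost_gdp(24000, 3, age = 70, death_age = 56), 0)
  expect_error(lost_gdp(24000, 4, age = 40), "occupation_status")
})

test_that("benefit tiers sum UC + ESA + PIP and expose PIP", {
  cfg <- cost_config()
  expect_equal(vapply(1:4, function(s) benefits_cost(s, cfg)$total,
                      numeric(1)),
               c(12, 203, 1006, 1586))
  expect_equal(benefits_cost(4, cfg)$pip, 770)
  expect_error(benefits_cost(9, cfg), "tier")
  zero <- cost_config(benefit_tiers = data.frame(state = 1, uc = 0, esa = 0,
                                                 pip = 0))
  expect_equal(benefits_cost(1, zero)$total, 0)
})

test_that("therapy costs are unit x dosage x frequency", {
  expect_equal(therapy_cost(NULL), 0)
  uc <- data.frame(therapy = "x", unit_cost = 2.5)
  rx <- data.frame(therapy = "x", dosage = 2, monthly_frequency = 30)
  expect_equal(therapy_cost(rx, uc), 150)
  expect_error(therapy_cost(data.frame(therapy = "y", dosage = 1,
                                       monthly_frequency = 1), uc),
               "unknown therapy: y")
  # default plans reproduce the reference therapy means
  cfg <- cost_config()
  plan_means <- vapply(cfg$therapy_plans, therapy_cost, numeric(1),
                       unit_costs = cfg$therapy_unit_costs)
  expect_equal(plan_means, unname(uk_cost_table()[, "therapies"]),
               tolerance = 0.01)
})

test_that("care decision follows the TFC decision tree", {
  cfg <- cost_config()
  set.seed(40)
  expect_identical(care_decision(13, "home", "single", 0, cfg)$mode, "none")
  expect_identical(care_decision(9, "home", "single", 0, cfg)$mode, "none")
  cd <- care_decision(6, "care_home", "partnered", 0, cfg)
  expect_identical(cd$mode, "care_home")
  expect_equal(cd$cost, cfg$care_home_monthly)
  # unpartnered home residents needing care always get a care worker
  cw <- care_decision(5, "home", "single", 0, cfg)
  expect_identical(cw$mode, "care_worker")
  expect_equal(cw$cost, 21 * 30 * 52 / 12 - 800)
  # PIP offsets the local-authority funding, never below zero net cost
  cw2 <- care_decision(5, "home", "single", 900, cfg)
  expect_equal(cw2$cost, 21 * 30 * 52 / 12)
  rich <- cost_config(care_worker_hourly = 1, care_hours_per_week = 1,
                      la_funding_monthly = 5000)
  expect_gte(care_decision(5, "home", "single", 0, rich)$cost, 0)
  # partner stops work with probability one half at certain-care TFC
  picks <- with_seed(41, replicate(10000, care_decision(6, "home",
                                                        "partnered", 0,
                                                        cfg)$mode))
  frac <- mean(picks == "partner_stops_work")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(care_decision(14, "home", "single", 0, cfg), "tfc")
})

test_that("visit breakdowns sum exactly and stay non-negative", {
  co <- generate_cohort(cohort_params(120, seed = 42))
  states <- co$truth$true_state
  ct <- cohort_costs(co, states, seed = 7)
  expect_equal(ct$total, ct$benefits + ct$therapies + ct$lost_gdp + ct$care,
               tolerance = 1e-10)
  expect_true(all(ct[, c("benefits", "therapies", "lost_gdp", "care")] >= 0))
  # healthy baseline visits are near-free; later states cost more
  agg <- tapply(ct$total, ct$fitted_state, mean)
  expect_true(all(diff(agg) > 0))
  expect_lt(agg[1], 300)
  # benefits column reproduces the tier table by construction
  expect_equal(as.numeric(tapply(ct$benefits, ct$fitted_state, mean)),
               c(12, 203, 1006, 1586))
  # deterministic given the seed
  expect_identical(ct, cohort_costs(co, states, seed = 7))
})

test_that("per-state cost distributions match moments and quantiles", {
  set.seed(43)
  x <- rlnorm(10000, meanlog = 6, sdlog = 0.7)
  tab <- data.frame(fitted_state = rep(1, 10000), total = x)
  d <- fit_state_cost_distribution(tab)
  expect_lt(abs(state_cost_mean(d, 1) - mean(x)) / mean(x), 0.02)
  expect_lt(abs(state_cost_quantile(d, 1, 0.5) - median(x)) / median(x),
            0.05)
  # degenerate constant totals
  dc <- fit_state_cost_distribution(data.frame(fitted_state = 1,
                                               total = rep(100, 50)))
  expect_equal(state_cost_quantile(dc, 1, 0.3), 100, tolerance = 1e-9)
  expect_equal(state_cost_mean(dc, 1), 100)
  # zero inflation: point mass at zero plus log-normal tail
  xz <- c(rep(0, 3000), rlnorm(7000, 5, 0.5))
  dz <- fit_state_cost_distribution(data.frame(fitted_state = 2,
                                               total = xz))
  expect_equal(state_cost_quantile(dz, 2, 0.2), 0)
  expect_gt(state_cost_quantile(dz, 2, 0.5), 0)
  expect_lt(abs(state_cost_mean(dz, 2) - mean(xz)) / mean(xz), 0.02)
  expect_error(fit_state_cost_distribution(data.frame(fitted_state = 1,
                                                      total = 1:5)),
               "state 1")
})
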