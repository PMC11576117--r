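#' Reference monthly cost table (GBP) by disease state and category
#'
#' Estimated mean monthly UK societal costs per living disease state in the
#' four categories used throughout the package: state benefits (universal
#' credit + employment support allowance + personal independence payment),
#' pharmacological/non-pharmacological therapies, lost contribution to GDP,
#' and care (partner stops work / care worker / care home).  These values
#' calibrate the default [cost_config()] and the default category shares of
#' the scenario simulator.
#'
#' @return A 4 x 4 numeric matrix, rows = states 1-4, columns = categories.
#' @export
uk_cost_table <- function() {
  m <- rbind(c(12, 22, 14, 3),
             c(203, 79, 268, 4),
             c(1006, 158, 1378, 106),
             c(1586, 271, 2056, 1285))
  dimnames(m) <- list(paste0("state", 1:4),
                      c("benefits", "therapies", "lost_gdp", "care"))
  m
}

default_benefit_tiers <- function() {
  data.frame(state = 1:4,
             uc = c(12, 100, 300, 300),
             esa = c(0, 0, 320, 516),
             pip = c(0, 103, 386, 770))
}

default_therapy_unit_costs <- function() {
  data.frame(
    therapy = c("antidepressant", "antipsychotic", "tetrabenazine",
                "physiotherapy", "occupational_therapy", "speech_therapy"),
    unit_cost = c(0.30, 1.20, 2.50, 40, 45, 40))
}

# Per-state default prescription plans (dosage x monthly frequency chosen so
# the plan means reproduce the therapies column of uk_cost_table()).
default_therapy_plans <- function() {
  plan <- function(...) {
    d <- data.frame(...)
    names(d) <- c("therapy", "dosage", "monthly_frequency")
    d
  }
  list(
    plan(t = c("antidepressant", "physiotherapy"),
         d = c(1, 1), f = c(30, 0.325)),
    plan(t = c("antidepressant", "antipsychotic", "physiotherapy",
               "occupational_therapy", "speech_therapy"),
         d = c(2, 0.5, 1, 1, 1), f = c(30, 30, 0.6, 0.2, 0.25)),
    plan(t = c("antidepressant", "antipsychotic", "tetrabenazine",
               "physiotherapy", "occupational_therapy", "speech_therapy"),
         d = c(2, 1, 0.5, 1, 1, 1), f = c(30, 30, 30, 0.8, 0.4, 0.4125)),
    plan(t = c("antidepressant", "antipsychotic", "tetrabenazine",
               "physiotherapy", "occupational_therapy", "speech_therapy"),
         d = c(2, 1.5, 1, 1, 1, 1), f = c(30, 30, 30, 1.2, 0.8, 1.0)))
}

default_salary_table <- function() {
  data.frame(percentile = c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95),
             annual_salary = c(9000, 13000, 20000, 27000, 38000, 53000,
                               65000))
}

#' Monetary parameters of the societal cost model
#'
#' @param benefit_tiers Data frame (`state`, `uc`, `esa`, `pip`) of monthly
#'   GBP benefit amounts by fitted-state eligibility tier; the defaults are
#'   calibrated so a synthetic population reproduces the benefits column of
#'   [uk_cost_table()].
#' @param therapy_unit_costs Data frame (`therapy`, `unit_cost`) of GBP unit
#'   costs.
#' @param therapy_plans List (one per state) of prescription data frames
#'   (`therapy`, `dosage`, `monthly_frequency`).
#' @param therapy_dispersion Gamma shape of the mean-one multiplier applied
#'   to a visit's prescription intensity (larger = less variable).
#' @param salary_quantile_table Data frame (`percentile`, `annual_salary`)
#'   defining the salary distribution (GBP/year); intermediate percentiles
#'   are linearly interpolated.
#' @param pension_age UK state pension age, years.
#' @param care_worker_hourly Care-worker cost, GBP/hour.
#' @param care_hours_per_week Care-worker hours per week.
#' @param care_home_monthly Care-home cost, GBP/month.
#' @param la_funding_monthly Local-authority funding available towards a
#'   care worker before the PIP offset, GBP/month.
#' @param partner_stop_probability Probability that a partnered patient's
#'   partner stops work rather than bringing in a care worker.
#' @param care_tfc_earliest TFC score at which daily care may first be
#'   needed (probability 1/3 there).
#' @param care_tfc_certain TFC score at or below which care is certain.
#' @return A list of class `hd_cost_config`.
#' @export
cost_config <- function(benefit_tiers = default_benefit_tiers(),
                        therapy_unit_costs = default_therapy_unit_costs(),
                        therapy_plans = default_therapy_plans(),
                        therapy_dispersion = 4,
                        salary_quantile_table = default_salary_table(),
                        pension_age = 66,
                        care_worker_hourly = 21,
                        care_hours_per_week = 30,
                        care_home_monthly = 4000,
                        la_funding_monthly = 800,
                        partner_stop_probability = 0.5,
                        care_tfc_earliest = 8,
                        care_tfc_certain = 6) {
  money <- c(unlist(benefit_tiers[, c("uc", "esa", "pip")]),
             therapy_unit_costs$unit_cost,
             salary_quantile_table$annual_salary,
             care_worker_hourly, care_home_monthly, la_funding_monthly)
  if (any(money < 0)) stop("all monetary amounts must be >= 0")
  if (pension_age <= 0) stop("pension_age must be positive")
  if (partner_stop_probability < 0 || partner_stop_probability > 1)
    stop("partner_stop_probability must lie in [0, 1]")
  structure(list(benefit_tiers = benefit_tiers,
                 therapy_unit_costs = therapy_unit_costs,
                 therapy_plans = therapy_plans,
                 therapy_dispersion = therapy_dispersion,
                 salary_quantile_table = salary_quantile_table,
                 pension_age = pension_age,
                 care_worker_hourly = care_worker_hourly,
                 care_hours_per_week = care_hours_per_week,
                 care_home_monthly = care_home_monthly,
                 la_funding_monthly = la_funding_monthly,
                 partner_stop_probability = partner_stop_probability,
                 care_tfc_earliest = care_tfc_earliest,
                 care_tfc_certain = care_tfc_certain),
            class = "hd_cost_config")
}

#' Convert a salary percentile to an annual salary
#'
#' Monotone piecewise-linear interpolation of the configured salary quantile
#' table, clamped at the outermost tabulated percentiles.
#'
#' @param percentile Value(s) in (0, 1).
#' @param table Salary quantile table (`percentile`, `annual_salary`).
#' @return Annual salary in GBP.
#' @export
sample_salary <- function(percentile, table = default_salary_table()) {
  if (any(percentile <= 0 | percentile >= 1))
    stop("salary percentile must lie strictly in (0, 1)")
  stats::approx(table$percentile, table$annual_salary, xout = percentile,
                rule = 2)$y
}

#' Monthly lost contribution to GDP
#'
#' Earnings drop to half salary at occupation status 2 and to zero at
#' status 1; the loss is the gap to the nominal (disease-free) salary.  At
#' or above pension age there is no loss.  After a death before pension
#' age, the full nominal salary is lost until pension age.
#'
#' @param salary Nominal annual salary, GBP.
#' @param occupation_status 3 (normal), 2 (reduced), or 1 (not working).
#' @param age Current age, years.
#' @param death_age Recorded death age, or `NA` while alive.
#' @param pension_age State pension age, years.
#' @return Lost GDP contribution in GBP/month.
#' @export
lost_gdp <- function(salary, occupation_status, age, death_age = NA,
                     pension_age = 66) {
  if (!all(occupation_status %in% 1:3))
    stop("occupation_status must be 1, 2 or 3")
  earning_frac <- c(0, 0.5, 1)[occupation_status]
  dead <- !is.na(death_age) & age >= death_age
  loss <- ifelse(age >= pension_age, 0,
                 ifelse(dead, salary / 12,
                        salary * (1 - earning_frac) / 12))
  loss
}

#' Monthly state-benefit cost for a disease-state eligibility tier
#'
#' @param state Fitted disease state (eligibility tier).
#' @param config An `hd_cost_config`.
#' @return List with `total` (UC + ESA + PIP, GBP/month) and `pip` (the PIP
#'   component, needed for the care-funding offset).
#' @export
benefits_cost <- function(state, config = cost_config()) {
  row <- config$benefit_tiers[config$benefit_tiers$state == state, ]
  if (nrow(row) != 1L)
    stop("no benefit tier configured for state ", state)
  list(total = row$uc + row$esa + row$pip, pip = row$pip)
}

#' Monthly therapy cost of a prescription list
#'
#' @param prescriptions Data frame (`therapy`, `dosage`,
#'   `monthly_frequency`); may be empty.
#' @param unit_costs Data frame (`therapy`, `unit_cost`).
#' @return Total GBP/month.
#' @export
therapy_cost <- function(prescriptions,
                         unit_costs = default_therapy_unit_costs()) {
  if (is.null(prescriptions) || nrow(prescriptions) == 0L) return(0)
  i <- match(prescriptions$therapy, unit_costs$therapy)
  if (anyNA(i))
    stop("unknown therapy: ",
         paste(prescriptions$therapy[is.na(i)], collapse = ", "))
  sum(unit_costs$unit_cost[i] * prescriptions$dosage *
        prescriptions$monthly_frequency)
}

#' Care decision and monthly care cost
#'
#' The probability of needing daily care ramps linearly from 1/3 at the
#' earliest-care TFC (default 8) to certainty at the certain-care TFC
#' (default 6); above the earliest-care TFC it is zero.  If care is needed:
#' a care-home resident incurs the care-home cost; otherwise, with the
#' configured probability, a partnered patient's partner stops work (the
#' cost is the partner's forgone salary, drawn from the salary table with an
#' independent percentile); otherwise a care worker is hired, whose gross
#' cost is offset by local-authority funding net of the patient's PIP.
#'
#' Uses the current RNG stream; seed the caller for reproducibility.
#'
#' @param tfc Total functional capacity score, 0-13.
#' @param residence `"home"` or `"care_home"`.
#' @param maristat `"partnered"` or `"single"`.
#' @param pip_amount Monthly PIP claimed, GBP (offsets LA funding).
#' @param config An `hd_cost_config`.
#' @return List with `mode` (one of `"none"`, `"partner_stops_work"`,
#'   `"care_worker"`, `"care_home"`) and `cost` (GBP/month).
#' @export
care_decision <- function(tfc, residence, maristat, pip_amount,
                          config = cost_config()) {
  if (tfc < 0 || tfc > 13) stop("tfc must lie in [0, 13]")
  e <- config$care_tfc_earliest
  c0 <- config$care_tfc_certain
  # linear ramp: 1/3 at the earliest-care TFC, 1 at the certain-care TFC
  p_need <- if (tfc > e) 0
  else if (tfc <= c0) 1
  else 1 / 3 + (2 / 3) * (e - tfc) / (e - c0)
  p_need <- min(max(p_need, 0), 1)
  if (stats::runif(1) >= p_need)
    return(list(mode = "none", cost = 0))
  if (identical(residence, "care_home"))
    return(list(mode = "care_home", cost = config$care_home_monthly))
  if (identical(maristat, "partnered") &&
      stats::runif(1) < config$partner_stop_probability) {
    partner_salary <- sample_salary(stats::runif(1),
                                    config$salary_quantile_table)
    return(list(mode = "partner_stops_work", cost = partner_salary / 12))
  }
  gross <- config$care_worker_hourly * config$care_hours_per_week * 52 / 12
  net <- max(0, gross - max(0, config$la_funding_monthly - pip_amount))
  list(mode = "care_worker", cost = net)
}

#' Four-category cost breakdown for one visit
#'
#' Assembles the monthly benefits, therapy, lost-GDP and care costs of one
#' visit given the patient's fitted disease state.  Uses the current RNG
#' stream (therapy intensity and the care decision are stochastic).
#'
#' @param patient One row of a cohort's `patients` table.
#' @param visit One row of the `visits` table.
#' @param fitted_state Fitted disease state at the visit.
#' @param config An `hd_cost_config`.
#' @param care_mode_override If `"care_home"`, the care mode is held there
#'   (entering a care home is sticky across later visits).
#' @return List of class `hd_cost_breakdown`: `benefits`, `therapies`,
#'   `lost_gdp`, `care`, `total` (GBP/month), and `care_mode`.
#' @export
visit_cost_breakdown <- function(patient, visit, fitted_state,
                                 config = cost_config(),
                                 care_mode_override = NULL) {
  ben <- benefits_cost(fitted_state, config)
  plan <- config$therapy_plans[[min(fitted_state,
                                    length(config$therapy_plans))]]
  mult <- stats::rgamma(1, shape = config$therapy_dispersion,
                        rate = config$therapy_dispersion)
  plan$dosage <- plan$dosage * mult
  ther <- therapy_cost(plan, config$therapy_unit_costs)
  salary <- sample_salary(patient$salary_percentile,
                          config$salary_quantile_table)
  gdp <- lost_gdp(salary, visit$occupation_status, visit$age_at_visit,
                  death_age = NA, pension_age = config$pension_age)
  if (identical(care_mode_override, "care_home")) {
    care <- list(mode = "care_home", cost = config$care_home_monthly)
  } else {
    care <- care_decision(visit$tfcscore, patient$residence,
                          patient$maristat, ben$pip, config)
  }
  structure(list(benefits = ben$total, therapies = ther, lost_gdp = gdp,
                 care = care$cost,
                 total = ben$total + ther + gdp + care$cost,
                 care_mode = care$mode),
            class = "hd_cost_breakdown")
}

#' Cost breakdowns for every visit of a cohort
#'
#' Applies [visit_cost_breakdown()] across a cohort with sticky care-home
#' status per patient (once a visit resolves to care-home care, later visits
#' keep it).
#'
#' @param cohort An `hd_cohort`.
#' @param states Integer fitted state per visit row.
#' @param config An `hd_cost_config`.
#' @param seed Integer seed.
#' @return Data frame: `patient_id`, `age`, `fitted_state`, `benefits`,
#'   `therapies`, `lost_gdp`, `care`, `total` (GBP/month).
#' @export
cohort_costs <- function(cohort, states, config = cost_config(), seed = 1L) {
  visits <- cohort$visits
  patients <- cohort$patients
  stopifnot(length(states) == nrow(visits))
  with_seed(seed, {
    rows <- vector("list", nrow(visits))
    in_home <- new.env(parent = emptyenv())
    prow <- patients[match(visits$patient_id, patients$patient_id), ]
    for (i in seq_len(nrow(visits))) {
      pid <- visits$patient_id[i]
      ovr <- if (isTRUE(get0(pid, envir = in_home))) "care_home" else NULL
      bd <- visit_cost_breakdown(prow[i, ], visits[i, ], states[i], config,
                                 care_mode_override = ovr)
      if (bd$care_mode == "care_home") assign(pid, TRUE, envir = in_home)
      rows[[i]] <- data.frame(patient_id = pid,
                              age = visits$age_at_visit[i],
                              fitted_state = states[i],
                              benefits = bd$benefits,
                              therapies = bd$therapies,
                              lost_gdp = bd$lost_gdp, care = bd$care,
                              total = bd$total)
    }
    do.call(rbind, rows)
  })
}

#' Fit per-state total-cost distributions
#'
#' For each disease state the monthly totals are modelled as a point mass at
#' zero (visits incurring no cost) plus a log-normal over the positive
#' totals, fitted by matching the mean and variance.  The result exposes a
#' quantile function and mean per state, which drive the quantile-coupled
#' scenario simulation.
#'
#' @param cost_table Output of [cohort_costs()] (columns `fitted_state`,
#'   `total`).
#' @param min_per_state Minimum visits required per state (default 30).
#' @return An object of class `hd_cost_dist`.
#' @export
fit_state_cost_distribution <- function(cost_table, min_per_state = 30L) {
  states <- sort(unique(cost_table$fitted_state))
  fits <- list()
  for (s in states) {
    x <- cost_table$total[cost_table$fitted_state == s]
    if (length(x) < min_per_state)
      stop("state ", s, " has only ", length(x),
           " visits; need at least ", min_per_state)
    p0 <- mean(x == 0)
    pos <- x[x > 0]
    if (length(pos) == 0L) {
      fits[[as.character(s)]] <- list(p0 = 1, mu = -Inf, sigma = 0, mean = 0)
      next
    }
    m <- mean(pos)
    v <- stats::var(pos)
    if (!is.finite(v) || v <= 0) {
      sigma <- 0
      mu <- log(m)
    } else {
      sigma <- sqrt(log(1 + v / m^2))
      mu <- log(m) - sigma^2 / 2
    }
    fits[[as.character(s)]] <- list(p0 = p0, mu = mu, sigma = sigma,
                                    mean = (1 - p0) * m)
  }
  structure(list(states = states, fits = fits), class = "hd_cost_dist")
}

#' Quantile and mean of a fitted per-state cost distribution
#'
#' @param dist An `hd_cost_dist`.
#' @param state Disease state.
#' @param u Quantile level(s) in (0, 1).
#' @return `state_cost_quantile()`: monthly total cost at quantile `u`;
#'   `state_cost_mean()`: the distribution mean.
#' @export
state_cost_quantile <- function(dist, state, u) {
  f <- dist$fits[[as.character(state)]]
  if (is.null(f)) stop("no cost distribution fitted for state ", state)
  ifelse(u < f$p0, 0,
         stats::qlnorm(pmin((u - f$p0) / (1 - f$p0), 1 - 1e-12),
                       f$mu, f$sigma))
}

#' @rdname state_cost_quantile
#' @export
state_cost_mean <- function(dist, state) {
  f <- dist$fits[[as.character(state)]]
  if (is.null(f)) stop("no cost distribution fitted for state ", state)
  f$mean
}
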