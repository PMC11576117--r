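#' Hypothetical intervention delaying one disease-state transition
#'
#' @param from_state Living state whose exit is delayed; the delayed
#'   transition is `from_state -> from_state + 1`.
#' @param delay Delay in years (>= 0).
#' @return A list of class `hd_intervention`.
#' @export
intervention <- function(from_state, delay) {
  if (delay < 0) stop("delay must be >= 0")
  if (from_state < 1L) stop("from_state must be a living state")
  structure(list(from_state = as.integer(from_state),
                 to_state = as.integer(from_state) + 1L,
                 delay = delay),
            class = "hd_intervention")
}

#' Simulate latent disease trajectories for a synthetic population
#'
#' @param model An `hd_model`.
#' @param n Number of synthetic patients.
#' @param seed Integer seed.
#' @return An `n x ns` matrix of state-entry ages (class
#'   `hd_trajectories`); column 1 is 0 (birth into state 1), the last
#'   column is the death age.
#' @export
simulate_progression <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "hd_model"))
  if (any(model$rates <= 0))
    stop("all living states must have positive exit rates")
  nliv <- model$n_states - 1L
  holds <- with_seed(seed, matrix(
    stats::rexp(n * nliv, rate = rep(model$rates, each = n)), n, nliv))
  entries <- cbind(0, t(apply(holds, 1, cumsum)))
  if (n == 1L) entries <- matrix(c(0, cumsum(holds[1, ])), 1)
  colnames(entries) <- paste0("state", seq_len(model$n_states))
  structure(entries, class = c("hd_trajectories", "matrix"))
}

#' Apply an intervention to simulated trajectories
#'
#' Entry into the delayed transition's target state, and every later entry
#' (including death), is shifted `delay` years later, extending the time
#' spent in `from_state`; trajectories are otherwise unchanged.  (With
#' exponential sojourns every simulated trajectory visits every living
#' state, so the shift applies to all patients.)
#'
#' @param trajectories `hd_trajectories` matrix (or a single trajectory data
#'   frame from [sample_trajectory()]).
#' @param intervention An `hd_intervention`.
#' @return Trajectories of the same form with shifted entry ages.
#' @export
apply_intervention <- function(trajectories, intervention) {
  stopifnot(inherits(intervention, "hd_intervention"))
  if (is.data.frame(trajectories)) {
    shift <- trajectories$state >= intervention$to_state
    trajectories$entry_age[shift] <-
      trajectories$entry_age[shift] + intervention$delay
    return(trajectories)
  }
  ns <- ncol(trajectories)
  if (intervention$to_state > ns) stop("to_state beyond the model's states")
  cols <- intervention$to_state:ns
  trajectories[, cols] <- trajectories[, cols] + intervention$delay
  trajectories
}

#' Quantile-coupled per-state monthly costs for synthetic patients
#'
#' One shared uniform variate per patient drives the cost quantile in every
#' disease state, so a patient is consistently cheap or expensive across
#' their whole progression (comonotone coupling); costs are constant for
#' the duration of a state.
#'
#' @param u Uniform variate(s) in (0, 1), one per patient.
#' @param cost_dist An `hd_cost_dist` (see [fit_state_cost_distribution()]
#'   or [cost_dist_from_table()]).
#' @param states Living states to evaluate (default: all fitted).
#' @return Matrix `length(u) x length(states)` of monthly totals (GBP).
#' @export
sample_patient_costs <- function(u, cost_dist, states = cost_dist$states) {
  out <- sapply(states, function(s) state_cost_quantile(cost_dist, s, u))
  if (length(u) == 1L) out <- matrix(out, 1)
  colnames(out) <- paste0("state", states)
  out
}

#' Build a per-state cost distribution from target means
#'
#' Log-normal per state with the given mean and coefficient of variation
#' (no zero mass); a convenient synthetic stand-in when no per-visit cost
#' table is available.
#'
#' @param means Monthly mean total cost per living state, GBP.
#' @param cv Coefficient of variation of each log-normal.
#' @return An `hd_cost_dist`.
#' @export
cost_dist_from_table <- function(means = rowSums(uk_cost_table()), cv = 0.8) {
  sigma <- sqrt(log(1 + cv^2))
  fits <- lapply(means, function(m)
    list(p0 = 0, mu = log(m) - sigma^2 / 2, sigma = sigma, mean = m))
  names(fits) <- as.character(seq_along(means))
  structure(list(states = seq_along(means), fits = fits),
            class = "hd_cost_dist")
}

#' Dirichlet decomposition of a total cost into categories
#'
#' Draws category proportions from a Dirichlet distribution with parameter
#' `concentration * shares` and multiplies by the total, so the components
#' always sum to the total exactly.  Categories with zero share receive
#' exactly zero.
#'
#' @param total Total monthly cost, GBP (>= 0).
#' @param shares Mean category shares, summing to 1.
#' @param concentration Positive Dirichlet concentration; the variance of
#'   proportion `i` is `shares[i] (1 - shares[i]) / (concentration + 1)`.
#' @return Numeric vector of category costs summing to `total`.
#' @export
dirichlet_decompose <- function(total, shares, concentration = 10) {
  if (total < 0) stop("total must be >= 0")
  if (abs(sum(shares) - 1) > 1e-8) stop("shares must sum to 1")
  if (concentration <= 0) stop("concentration must be positive")
  if (total == 0) return(rep(0, length(shares)))
  g <- stats::rgamma(length(shares), shape = concentration * shares)
  if (sum(g) == 0) g[which.max(shares)] <- 1
  total * g / sum(g)
}

# Vectorised Dirichlet proportions: n draws over k categories.
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  rs <- rowSums(g)
  zero <- rs == 0
  if (any(zero)) {
    g[zero, which.max(alpha)] <- 1
    rs <- rowSums(g)
  }
  g / rs
}

#' Scenario-simulation configuration
#'
#' @param n_synthetic_patients Simulated population size (default 10 000).
#' @param seed Integer seed for all scenario randomness.
#' @param cost_dist Per-state total-cost distribution (`hd_cost_dist`).
#' @param category_shares `n_living x 4` matrix of mean category shares per
#'   state (columns: benefits, therapies, lost_gdp, care; rows sum to 1).
#'   Default: row proportions of [uk_cost_table()].
#' @param dirichlet_concentration Concentration of the per-patient category
#'   decomposition (default 10).
#' @param pension_age State pension age, years.
#' @param salary_quantile_table Salary table for nominal salaries (used for
#'   the post-death lost-GDP continuation).
#' @return A list of class `hd_scenario_config`.
#' @export
scenario_config <- function(n_synthetic_patients = 10000L, seed = 1L,
                            cost_dist = cost_dist_from_table(),
                            category_shares = NULL,
                            dirichlet_concentration = 10,
                            pension_age = 66,
                            salary_quantile_table = default_salary_table()) {
  if (is.null(category_shares)) {
    tab <- uk_cost_table()
    category_shares <- tab / rowSums(tab)
  }
  if (any(abs(rowSums(category_shares) - 1) > 1e-8))
    stop("category share rows must sum to 1")
  if (dirichlet_concentration <= 0)
    stop("dirichlet_concentration must be positive")
  structure(list(n_synthetic_patients = as.integer(n_synthetic_patients),
                 seed = as.integer(seed), cost_dist = cost_dist,
                 category_shares = as.matrix(category_shares),
                 dirichlet_concentration = dirichlet_concentration,
                 pension_age = pension_age,
                 salary_quantile_table = salary_quantile_table),
            class = "hd_scenario_config")
}

# Vectorised lifetime cost engine.
# entries: n x ns entry-age matrix; monthly: n x nliv monthly totals;
# props: list of nliv matrices (n x 4 category proportions);
# salary: n nominal annual salaries.
# The lost-GDP category accrues only below pension age (none is lost once
# the patient reaches pension age); after a death before pension age it
# continues at the full nominal salary until pension age.  All other
# categories stop at death.
lifetime_cost_engine <- function(entries, monthly, props, salary,
                                 pension_age) {
  n <- nrow(entries)
  ns <- ncol(entries)
  nliv <- ns - 1L
  cats <- c("benefits", "therapies", "lost_gdp", "care")
  by_cat <- matrix(0, n, 4, dimnames = list(NULL, cats))
  by_state <- matrix(0, n, nliv)
  for (s in seq_len(nliv)) {
    dur <- entries[, s + 1L] - entries[, s]
    dur_pre_pension <- pmax(0, pmin(entries[, s + 1L], pension_age) -
                              pmin(entries[, s], pension_age))
    amt <- monthly[, s] * props[[s]]        # n x 4 monthly category costs
    yrs <- cbind(dur, dur, dur_pre_pension, dur)
    contrib <- 12 * amt * yrs
    by_cat <- by_cat + contrib
    by_state[, s] <- rowSums(contrib)
  }
  death <- entries[, ns]
  post <- pmax(0, pension_age - death) * salary
  by_cat[, "lost_gdp"] <- by_cat[, "lost_gdp"] + post
  list(total = rowSums(by_cat) , by_category = by_cat,
       by_state = by_state, post_death_gdp = post)
}

#' Lifetime societal cost of one simulated trajectory
#'
#' Integrates the per-state monthly costs over the years spent in each
#' living state, splitting the total into the four categories with the
#' given proportions.  The lost-GDP category accrues only below pension
#' age; after a death before pension age it continues at the full nominal
#' salary until pension age, while all other categories stop at death.
#'
#' @param trajectory A trajectory data frame from [sample_trajectory()] or
#'   a single row of [simulate_progression()] entries.
#' @param state_costs Monthly total cost per living state, GBP.
#' @param category_props `n_living x 4` matrix of category proportions
#'   (rows sum to 1); columns benefits, therapies, lost_gdp, care.
#' @param salary Nominal annual salary, GBP (post-death GDP continuation).
#' @param pension_age State pension age, years.
#' @return List with `total` (GBP) and `by_category` (length-4 vector).
#' @export
lifetime_cost <- function(trajectory, state_costs, category_props,
                          salary = 0, pension_age = 66) {
  entries <- if (is.data.frame(trajectory))
    matrix(trajectory$entry_age, 1) else matrix(as.numeric(trajectory), 1)
  nliv <- ncol(entries) - 1L
  stopifnot(length(state_costs) == nliv, nrow(category_props) == nliv)
  props <- lapply(seq_len(nliv), function(s)
    matrix(category_props[s, ], 1))
  res <- lifetime_cost_engine(entries, matrix(state_costs, 1), props,
                              salary, pension_age)
  list(total = res$total[1], by_category = res$by_category[1, ])
}

#' Compare baseline and intervention scenarios by Monte-Carlo simulation
#'
#' Simulates a synthetic population from the progression model, attaches
#' quantile-coupled per-state costs (one shared uniform per patient),
#' decomposes each state's total into the four categories by a Dirichlet
#' draw, and evaluates lifetime costs under the baseline and under the
#' delayed-transition intervention using common random numbers: both arms
#' share the same trajectories, cost quantile, salary and category
#' proportions, so a zero-delay intervention yields exactly zero saving.
#'
#' @param model An `hd_model` (fitted or known progression model).
#' @param intv An `hd_intervention`.
#' @param config An `hd_scenario_config`.
#' @return An object of class `hd_scenario_result`: per-patient lifetime
#'   costs under both arms, per-patient savings, `mean_saving` with a 95%
#'   confidence interval, and per-category mean costs and savings.
#' @export
compare_scenarios <- function(model, intv, config = scenario_config()) {
  stopifnot(inherits(model, "hd_model"), inherits(intv, "hd_intervention"),
            inherits(config, "hd_scenario_config"))
  nliv <- model$n_states - 1L
  if (nrow(config$category_shares) != nliv)
    stop("category_shares must have one row per living state")
  n <- config$n_synthetic_patients
  entries <- simulate_progression(model, n, seed = config$seed)
  draws <- with_seed(config$seed + 1L, {
    u <- stats::runif(n)
    sp <- stats::runif(n)
    props <- lapply(seq_len(nliv), function(s)
      rdirichlet_mat(n, config$dirichlet_concentration *
                       config$category_shares[s, ]))
    list(u = u, sp = sp, props = props)
  })
  monthly <- sample_patient_costs(draws$u, config$cost_dist,
                                  states = seq_len(nliv))
  salary <- sample_salary(pmin(pmax(draws$sp, 1e-6), 1 - 1e-6),
                          config$salary_quantile_table)
  base <- lifetime_cost_engine(entries, monthly, draws$props, salary,
                               config$pension_age)
  ent2 <- apply_intervention(entries, intv)
  intvc <- lifetime_cost_engine(ent2, monthly, draws$props, salary,
                                config$pension_age)
  saving <- base$total - intvc$total
  structure(list(
    baseline_total = base$total, intervention_total = intvc$total,
    saving = saving,
    mean_saving = mean(saving),
    ci_mean_saving = mean(saving) +
      c(-1, 1) * 1.96 * stats::sd(saving) / sqrt(n),
    category_means = rbind(baseline = colMeans(base$by_category),
                           intervention = colMeans(intvc$by_category)),
    category_saving = colMeans(base$by_category) -
      colMeans(intvc$by_category),
    state_means = rbind(baseline = colMeans(base$by_state),
                        intervention = colMeans(intvc$by_state)),
    n = n, intervention = intv),
    class = "hd_scenario_result")
}

#' @export
print.hd_scenario_result <- function(x, ...) {
  cat("Scenario: delay", x$intervention$from_state, "->",
      x$intervention$to_state, "by", x$intervention$delay, "years;",
      x$n, "synthetic patients\n")
  cat(sprintf("Mean lifetime saving: GBP %.0f (95%% CI %.0f to %.0f)\n",
              x$mean_saving, x$ci_mean_saving[1], x$ci_mean_saving[2]))
  cat("Per-category mean saving (GBP):\n")
  print(round(x$category_saving))
  invisible(x)
}
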