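#' Default progressive model for cohort synthesis
#'
#' A five-state progressive CTHMM (four living states plus death) with mean
#' sojourn times of 23.6, 17.6, 12.7 and 11.4 years, representative of
#' staged Huntington's disease progression across an adult lifetime (mean
#' age at death about 65 years).
#'
#' @return An `hd_model` without emission parameters (the cohort generator
#'   draws raw clinical scores from [default_score_model()] instead).
#' @export
default_progression_model <- function() {
  progression_model(rates = 1 / c(23.6, 17.6, 12.7, 11.4))
}

#' Default progressive model with feature emissions
#'
#' The same five-state progression as [default_progression_model()], with
#' Gaussian emission distributions over two PC-score-like features that
#' mirror the structure of fitted HD progression models: the first feature
#' (the dominant severity axis) trends upward with disease state, while the
#' second has a flat mean and a variance that grows as the disease
#' progresses.  Cohorts generated from this model carry these features
#' directly, so the emission model of a refit is correctly specified —
#' the configuration used for parameter-recovery experiments.
#'
#' @return An `hd_model` with emission parameters for features `PC1`, `PC2`.
#' @export
default_emission_model <- function() {
  progression_model(
    rates = 1 / c(23.6, 17.6, 12.7, 11.4),
    emission_means = cbind(PC1 = c(-2, -0.5, 1, 2.5),
                           PC2 = c(0, 0, 0, 0)),
    emission_sds = cbind(PC1 = c(0.8, 0.8, 0.9, 1.0),
                         PC2 = c(0.6, 0.8, 1.0, 1.2)))
}

#' State-conditional observation model for the 12 clinical scores
#'
#' Each score is Gaussian around a per-state mean profile that worsens
#' monotonically across states, then clipped to the score's valid range and
#' rounded where the instrument is integer-valued.  The default profiles
#' make the cognitive battery separate states 1/2 strongly while total
#' functional capacity (TFC) separates states 2/3, mirroring the staggered
#' domain decline seen in observational HD data.  Profiles for other
#' numbers of living states are linearly interpolated along the disease
#' course.
#'
#' @param n_living Number of living states (default 4).
#' @return A list with elements `vars`, `means` (`n_living x 12`), `sds`,
#'   `min`, `max`, `integer`.
#' @export
default_score_model <- function(n_living = 4L) {
  vars <- c("exfscore", "irascore", "aptscore", "fascore", "tfcscore",
            "indepscl", "swrt1", "sit1", "sdmt1", "scnt1", "verfct5",
            "motscore")
  m4 <- rbind(
    exfscore = c(1, 3, 6, 10),
    irascore = c(1, 4, 6, 8),
    aptscore = c(1, 2, 5, 8),
    fascore  = c(0.5, 2, 8, 16),
    tfcscore = c(13, 11.5, 7, 3),
    indepscl = c(100, 92, 75, 50),
    swrt1    = c(95, 70, 50, 30),
    sit1     = c(45, 32, 22, 12),
    sdmt1    = c(50, 35, 22, 10),
    scnt1    = c(75, 55, 38, 22),
    verfct5  = c(22, 16, 11, 6),
    motscore = c(2, 8, 30, 60))
  sds <- c(2, 2.5, 2, 2.5, 1.5, 6, 10, 6, 7, 8, 3, 8)
  mins <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  maxs <- c(48, 48, 48, 25, 13, 100, 120, 80, 110, 120, 60, 124)
  if (n_living == 4L) {
    means <- t(m4)
  } else {
    xs <- seq(0, 1, length.out = 4L)
    xo <- seq(0, 1, length.out = n_living)
    means <- sapply(seq_len(nrow(m4)),
                    function(j) stats::approx(xs, m4[j, ], xout = xo)$y)
  }
  dimnames(means) <- list(NULL, vars)
  list(vars = vars, means = means,
       sds = stats::setNames(sds, vars),
       min = stats::setNames(mins, vars),
       max = stats::setNames(maxs, vars),
       integer = stats::setNames(rep(TRUE, 12L), vars))
}

#' Parameters of the synthetic cohort generator
#'
#' The defaults emulate the structure of longitudinal HD observational
#' visit data: about 2.88 visits per patient on average spanning about
#' 2.35 years, roughly annual irregular visit spacing, study entry in
#' mid-adulthood, and a recorded date of death for only about 5% of
#' patients.
#'
#' @param n_patients Number of patients (>= 1).
#' @param true_model Latent `hd_model` driving progression.
#' @param onset_age Mean and sd (years) of age at study entry (first visit).
#' @param visit_interval Mean, sd and minimum (years) of the gap between
#'   consecutive visits (truncated normal).
#' @param mean_visits_per_patient Average number of visits; visit counts are
#'   drawn as 1 + a negative binomial so that their dispersion resembles
#'   observational data (sd about 1.9 at the default mean).
#' @param visit_count_size Negative-binomial size (dispersion) parameter.
#' @param death_recording_probability Probability that a patient's death
#'   age is recorded (in `[0, 1]`).
#' @param partner_probability Probability of living with a partner.
#' @param care_home_probability Probability of care-home residence.
#' @param entry_age_range Admissible study entry ages (years); draws are
#'   clamped to this range.
#' @param score_model Observation model, see [default_score_model()].
#' @param seed Master integer seed; per-patient substreams are derived by a
#'   stable hash of the patient id so cohorts are reproducible.
#' @return A list of class `hd_cohort_params`.
#' @export
cohort_params <- function(n_patients,
                          true_model = default_progression_model(),
                          onset_age = c(mean = 48, sd = 12),
                          visit_interval = c(mean = 1.1, sd = 0.4, min = 0.1),
                          mean_visits_per_patient = 2.88,
                          visit_count_size = 2.2,
                          death_recording_probability = 0.05,
                          partner_probability = 0.55,
                          care_home_probability = 0.05,
                          entry_age_range = c(18, 90),
                          score_model = NULL,
                          seed = 1L) {
  if (n_patients < 1L) stop("n_patients must be >= 1")
  if (death_recording_probability < 0 || death_recording_probability > 1)
    stop("death_recording_probability must lie in [0, 1]")
  if (partner_probability < 0 || partner_probability > 1)
    stop("partner_probability must lie in [0, 1]")
  if (visit_interval[["min"]] <= 0 || visit_interval[["mean"]] <= 0)
    stop("visit intervals must be strictly positive")
  stopifnot(inherits(true_model, "hd_model"))
  if (is.null(score_model))
    score_model <- default_score_model(true_model$n_states - 1L)
  structure(list(
    n_patients = as.integer(n_patients), true_model = true_model,
    onset_age = onset_age, visit_interval = visit_interval,
    mean_visits_per_patient = mean_visits_per_patient,
    visit_count_size = visit_count_size,
    death_recording_probability = death_recording_probability,
    partner_probability = partner_probability,
    care_home_probability = care_home_probability,
    entry_age_range = entry_age_range,
    score_model = score_model, seed = as.integer(seed)),
    class = "hd_cohort_params")
}

#' Generate a synthetic patient cohort
#'
#' Each patient receives a latent trajectory from [sample_trajectory()],
#' a study entry age (redrawn jointly with the trajectory until entry
#' precedes death, emulating enrolment of living patients), a schedule of
#' irregular visits truncated at death, raw clinical scores drawn from the
#' state-conditional observation model, an occupation status mapped from the
#' latent state (state 1 -> 3, state 2 -> 2, states 3+ -> 1), demographics,
#' and a recorded death age with the configured probability.
#'
#' @param params An `hd_cohort_params` object.
#' @return An object of class `hd_cohort`: list with data frames `visits`
#'   (one row per visit: id, age, 12 raw scores, occupation status, plus
#'   one column per model feature when the true model carries emission
#'   parameters), `patients` (id, maristat, residence, death_age or `NA`,
#'   salary_percentile), and `truth` / `truth_entries` (latent states, kept
#'   for testing only).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "hd_cohort_params"))
  sm <- params$score_model
  mdl <- params$true_model
  nliv <- mdl$n_states - 1L
  occ_map <- c(3L, 2L, rep(1L, max(nliv - 2L, 0L)))
  visits <- vector("list", params$n_patients)
  patients <- vector("list", params$n_patients)
  truth <- vector("list", params$n_patients)
  entries <- vector("list", params$n_patients)
  for (i in seq_len(params$n_patients)) {
    pid <- sprintf("P%05d", i)
    sub <- stable_hash(pid, params$seed)
    res <- with_seed(sub, {
      traj <- sample_trajectory(mdl)
      death_age <- traj$entry_age[mdl$n_states]
      # Entry age: the configured distribution truncated to the patient's
      # living interval.  Truncating (rather than discarding short-lived
      # trajectories) keeps the latent trajectory law exactly the model's,
      # which is the structure the downstream analysis assumes; patients
      # dying young are enrolled correspondingly earlier.
      a <- params$entry_age_range[1]
      b <- min(params$entry_age_range[2], death_age - 0.5)
      if (b <= a) {
        a <- max(death_age / 3, 0.1)
        b <- max(death_age - 0.5, a + 0.1)
      }
      m <- params$onset_age[["mean"]]
      s <- params$onset_age[["sd"]]
      pa <- stats::pnorm(a, m, s)
      pb <- stats::pnorm(b, m, s)
      u <- stats::runif(1, pa, max(pb, pa + 1e-12))
      entry <- min(max(stats::qnorm(u, m, s), a), b)
      nv <- 1L + stats::rnbinom(1, size = params$visit_count_size,
                                mu = params$mean_visits_per_patient - 1)
      gaps <- pmax(stats::rnorm(nv, params$visit_interval[["mean"]],
                                params$visit_interval[["sd"]]),
                   params$visit_interval[["min"]])
      ages <- entry + cumsum(c(0, gaps))[seq_len(nv)]
      ages <- ages[ages < death_age]
      st <- findInterval(ages, traj$entry_age[seq_len(nliv)])
      X <- matrix(NA_real_, length(ages), length(sm$vars),
                  dimnames = list(NULL, sm$vars))
      for (v in sm$vars) {
        x <- stats::rnorm(length(ages), sm$means[st, v], sm$sds[[v]])
        x <- pmin(pmax(x, sm$min[[v]]), sm$max[[v]])
        if (sm$integer[[v]]) x <- round(x)
        X[, v] <- x
      }
      # when the true model carries emission parameters, also draw its own
      # feature vector per visit (correctly specified Gaussian emissions,
      # used by parameter-recovery experiments)
      Fm <- NULL
      if (!is.null(mdl$emission_means)) {
        Fm <- sapply(seq_along(mdl$feature_names), function(f)
          stats::rnorm(length(ages), mdl$emission_means[st, f],
                       mdl$emission_sds[st, f]))
        Fm <- matrix(Fm, nrow = length(ages),
                     dimnames = list(NULL, mdl$feature_names))
      }
      list(traj = traj, death_age = death_age, ages = ages, st = st, X = X,
           Fm = Fm,
           recorded = stats::runif(1) < params$death_recording_probability,
           partnered = stats::runif(1) < params$partner_probability,
           care_home = stats::runif(1) < params$care_home_probability,
           salary_percentile = stats::runif(1))
    })
    vdf <- data.frame(patient_id = pid, age_at_visit = res$ages,
                      res$X,
                      occupation_status = occ_map[res$st])
    if (!is.null(res$Fm)) vdf <- cbind(vdf, res$Fm)
    visits[[i]] <- vdf
    patients[[i]] <- data.frame(
      patient_id = pid,
      maristat = if (res$partnered) "partnered" else "single",
      residence = if (res$care_home) "care_home" else "home",
      death_age = if (res$recorded) res$death_age else NA_real_,
      salary_percentile = res$salary_percentile,
      last_visit_age = max(res$ages))
    truth[[i]] <- data.frame(patient_id = pid, age_at_visit = res$ages,
                             true_state = res$st)
    entries[[i]] <- data.frame(patient_id = pid,
                               state = res$traj$state,
                               entry_age = res$traj$entry_age)
  }
  structure(list(visits = do.call(rbind, visits),
                 patients = do.call(rbind, patients),
                 truth = do.call(rbind, truth),
                 truth_entries = do.call(rbind, entries),
                 params = params),
            class = "hd_cohort")
}

#' @export
print.hd_cohort <- function(x, ...) {
  cat("hd_cohort:", nrow(x$patients), "patients,", nrow(x$visits),
      "visits (", round(mean(table(x$visits$patient_id)), 2),
      "per patient );",
      sum(!is.na(x$patients$death_age)), "recorded deaths\n")
  invisible(x)
}

cohort_visit_columns <- function() {
  c("patient_id", "age_at_visit", default_score_model()$vars,
    "occupation_status")
}

#' Write / read a cohort as CSV files
#'
#' `write_cohort()` writes `visits.csv`, `patients.csv` and (if latent truth
#' is present) `truth.csv` plus `truth_entries.csv` into a directory;
#' `read_cohort()` reads them back, validating the schema.  The round trip
#' is lossless up to floating-point printing for all fields except the
#' latent truth, which lives in separate files used only by tests.
#'
#' @param cohort An `hd_cohort`.
#' @param path Directory to write to / read from (created if needed).
#' @return `read_cohort()` returns an `hd_cohort` (without generator
#'   parameters; truth tables only if present on disk).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "hd_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  extra <- setdiff(names(cohort$visits), cohort_visit_columns())
  utils::write.csv(cohort$visits[, c(cohort_visit_columns(), extra)],
                   file.path(path, "visits.csv"), row.names = FALSE, na = "")
  utils::write.csv(cohort$patients[, c("patient_id", "maristat", "residence",
                                       "death_age", "salary_percentile")],
                   file.path(path, "patients.csv"), row.names = FALSE,
                   na = "")
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, file.path(path, "truth.csv"),
                     row.names = FALSE)
  if (!is.null(cohort$truth_entries))
    utils::write.csv(cohort$truth_entries,
                     file.path(path, "truth_entries.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  vfile <- file.path(path, "visits.csv")
  pfile <- file.path(path, "patients.csv")
  if (!file.exists(vfile) || !file.exists(pfile))
    stop("cohort directory must contain visits.csv and patients.csv")
  visits <- utils::read.csv(vfile, na.strings = "")
  patients <- utils::read.csv(pfile, na.strings = "")
  need_v <- cohort_visit_columns()
  miss <- setdiff(need_v, names(visits))
  if (length(miss))
    stop("visits.csv is missing required column(s): ",
         paste(miss, collapse = ", "))
  need_p <- c("patient_id", "maristat", "residence", "death_age",
              "salary_percentile")
  miss <- setdiff(need_p, names(patients))
  if (length(miss))
    stop("patients.csv is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (pid in unique(visits$patient_id)) {
    a <- visits$age_at_visit[visits$patient_id == pid]
    if (is.unsorted(a, strictly = TRUE))
      stop("visits.csv: visit ages for patient ", pid,
           " are not strictly increasing")
    da <- patients$death_age[patients$patient_id == pid]
    if (length(da) == 1L && !is.na(da) && da <= max(a))
      stop("patients.csv: death age for patient ", pid,
           " does not exceed the last visit age")
  }
  patients$last_visit_age <-
    tapply(visits$age_at_visit, visits$patient_id, max)[patients$patient_id]
  truth <- NULL
  tfile <- file.path(path, "truth.csv")
  if (file.exists(tfile)) truth <- utils::read.csv(tfile)
  entries <- NULL
  efile <- file.path(path, "truth_entries.csv")
  if (file.exists(efile)) entries <- utils::read.csv(efile)
  structure(list(visits = visits, patients = patients, truth = truth,
                 truth_entries = entries, params = NULL),
            class = "hd_cohort")
}
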