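# Shared oracles and fixture builders.  Every oracle here is computed by a
# route independent of the implementation path it checks.

# Truncated Taylor series for expm(Q * dt).
expm_series <- function(Q, dt, terms = 50L) {
  ns <- nrow(Q)
  S <- diag(ns)
  term <- diag(ns)
  for (k in seq_len(terms)) {
    term <- term %*% (Q * dt) / k
    S <- S + term
  }
  S
}

# Log-likelihood of a 3-state progressive model (2 living states + death)
# by direct 2-D quadrature over the two transition times.  Supports a
# sequence of visits with 1-feature Gaussian emissions and either an exact
# death at `death_age`, an interval-censored death in [dlo, dhi], or plain
# right censoring (both NULL).
loglik_quadrature_3state <- function(q1, q2, mu, sd1, visit_ages, x,
                                     death_age = NULL, dlo = NULL,
                                     dhi = NULL, grid_n = 1500L,
                                     horizon = 60) {
  tau1 <- seq(1e-6, horizon, length.out = grid_n)      # 1 -> 2 time
  tau2 <- seq(1e-6, horizon, length.out = grid_n)      # sojourn in state 2
  d1 <- q1 * exp(-q1 * tau1)
  d2 <- q2 * exp(-q2 * tau2)
  h <- tau1[2] - tau1[1]
  total <- 0
  for (i in seq_along(tau1)) {
    t1 <- tau1[i]
    death <- t1 + tau2                                  # death ages
    emis <- 1
    for (v in seq_along(visit_ages)) {
      st <- if (visit_ages[v] < t1) 1L else 2L
      emis <- emis * stats::dnorm(x[v], mu[st], sd1[st]) *
        (death > visit_ages[v])                         # alive at visit
    }
    if (!is.null(death_age)) {
      # exact death: density of tau2 at death_age - t1
      if (death_age > t1) {
        dens <- q2 * exp(-q2 * (death_age - t1))
        st_emis <- 1
        for (v in seq_along(visit_ages)) {
          st <- if (visit_ages[v] < t1) 1L else 2L
          st_emis <- st_emis * stats::dnorm(x[v], mu[st], sd1[st]) *
            (death_age > visit_ages[v])
        }
        total <- total + d1[i] * dens * st_emis * h
      }
    } else if (!is.null(dlo)) {
      ok <- death >= dlo & death <= dhi
      total <- total + d1[i] * sum((d2 * emis)[ok]) * h * h
    } else {
      total <- total + d1[i] * sum(d2 * emis) * h * h
    }
  }
  log(total)
}

# Exhaustive max-product Viterbi for a progressive model over visit events
# (optionally terminated by a death event), enumerating all non-decreasing
# living-state paths.
viterbi_bruteforce <- function(model, visit_ages, X, death = NULL) {
  ns <- model$n_states
  nv <- length(visit_ages)
  Q <- generator_matrix(model)
  paths <- expand.grid(rep(list(seq_len(ns - 1L)), nv))
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    p <- as.integer(paths[r, ])
    lp <- 0
    prev <- 1L
    tprev <- 0
    for (v in seq_len(nv)) {
      P <- transition_matrix(Q, visit_ages[v] - tprev)
      lp <- lp + log(P[prev, p[v]]) +
        sum(stats::dnorm(as.numeric(X[v, ]), model$emission_means[p[v], ],
                         model$emission_sds[p[v], ], log = TRUE))
      prev <- p[v]
      tprev <- visit_ages[v]
    }
    if (!is.null(death)) {
      if (death$kind == "exact") {
        P <- transition_matrix(Q, death$age - tprev)
        lp <- lp + log(P[prev, ns - 1L]) + log(model$rates[ns - 1L])
      } else {
        Pl <- transition_matrix(Q, max(death$lo - tprev, 0))
        Ph <- transition_matrix(Q, max(death$hi - tprev, 0))
        lp <- lp + log(max(Ph[prev, ns] - Pl[prev, ns], 0))
      }
    }
    if (lp > best + 1e-12) {
      best <- lp
      best_path <- p
    }
  }
  best_path
}

# Build an hd_events table for a single patient from plain vectors.
single_patient_events <- function(visit_ages, X, death_age = NULL,
                                  dlo = NULL, dhi = NULL,
                                  feature_names = colnames(X)) {
  nf <- ncol(X)
  blank <- matrix(NA_real_, 1, nf, dimnames = list(NULL, feature_names))
  rows <- data.frame(patient_id = "p1", kind = "birth", age = 0,
                     lo = NA_real_, hi = NA_real_, blank)
  if (length(visit_ages))
    rows <- rbind(rows, data.frame(patient_id = "p1", kind = "visit",
                                   age = visit_ages, lo = NA_real_,
                                   hi = NA_real_, X))
  if (!is.null(death_age))
    rows <- rbind(rows, data.frame(patient_id = "p1", kind = "death_exact",
                                   age = death_age, lo = NA_real_,
                                   hi = NA_real_, blank))
  if (!is.null(dlo))
    rows <- rbind(rows, data.frame(patient_id = "p1",
                                   kind = "death_interval", age = NA_real_,
                                   lo = dlo, hi = dhi, blank))
  as_hd_events(rows, feature_names)
}

# Events for a whole cohort using the model-generated Gaussian features
# (the parameter-recovery configuration).
recovery_events <- function(cohort, upper_bound = NULL) {
  fn <- cohort$params$true_model$feature_names
  build_events(cohort, as.matrix(cohort$visits[, fn]), upper_bound)
}

true_sojourns <- function() c(23.6, 17.6, 12.7, 11.4)
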