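#' CTHMM log-likelihood of observation events
#'
#' Forward algorithm over each patient's ordered events.  The latent state
#' distribution starts pinned at state 1 at age 0; visits contribute
#' state-conditional products of Gaussian feature densities (features are
#' treated as conditionally independent given the state); an exact death
#' contributes the density of entering the absorbing state at that instant
#' (occupancy of the last living state times its exit rate); an interval-
#' censored death contributes the probability of absorption within the
#' interval.  A configuration of probability zero yields `-Inf`, not an
#' error.
#'
#' @param model An `hd_model` with emission parameters.
#' @param events An `hd_events` table whose feature columns include the
#'   model's `feature_names`.
#' @param by_patient If `TRUE`, return the per-patient vector instead of
#'   the total.
#' @return Total log-likelihood in nats (or a named per-patient vector).
#' @export
log_likelihood <- function(model, events, by_patient = FALSE) {
  stopifnot(inherits(model, "hd_model"))
  if (is.null(model$emission_means))
    stop("model has no emission parameters")
  pk <- pack_events(events, model$feature_names)
  ll <- .cthmm_loglik_cpp(pk$offsets, pk$kind, pk$age, pk$lo, pk$hi,
                          pk$feat, model$rates, model$emission_means,
                          model$emission_sds)
  if (by_patient) stats::setNames(ll, pk$patient_ids) else sum(ll)
}

# Reference forward-algorithm evaluator in plain R, using transition_matrix()
# (which falls back to Matrix::expm for close rates).  Much slower than the
# compiled path; used to cross-check its numerics.
loglik_reference <- function(model, events) {
  stopifnot(inherits(model, "hd_model"))
  fn <- model$feature_names
  ns <- model$n_states
  Q <- generator_matrix(model)
  total <- 0
  for (pid in unique(events$patient_id)) {
    rows <- events[events$patient_id == pid, , drop = FALSE]
    a <- c(1, rep(0, ns - 1L))
    t <- 0
    ll <- 0
    for (r in seq_len(nrow(rows))) {
      kind <- rows$kind[r]
      if (kind == "birth") next
      if (kind == "visit") {
        P <- transition_matrix(Q, max(rows$age[r] - t, 0))
        anew <- as.vector(a %*% P)
        x <- as.numeric(rows[r, fn])
        for (s in seq_len(ns - 1L))
          anew[s] <- anew[s] * prod(stats::dnorm(x, model$emission_means[s, ],
                                                 model$emission_sds[s, ]))
        anew[ns] <- 0
        cc <- sum(anew)
        if (cc <= 0) return(-Inf)
        ll <- ll + log(cc)
        a <- anew / cc
        t <- rows$age[r]
      } else if (kind == "death_exact") {
        P <- transition_matrix(Q, max(rows$age[r] - t, 0))
        lik <- sum(a * P[, ns - 1L]) * model$rates[ns - 1L]
        if (lik <= 0) return(-Inf)
        ll <- ll + log(lik)
      } else if (kind == "death_interval") {
        Pl <- transition_matrix(Q, max(rows$lo[r] - t, 0))
        Ph <- transition_matrix(Q, max(rows$hi[r] - t, 0))
        pr <- sum(a * (Ph[, ns] - Pl[, ns]))
        if (pr <= 0) return(-Inf)
        ll <- ll + log(pr)
      }
    }
    total <- total + ll
  }
  total
}

# par <-> model mapping used by the optimizer: log rates, emission means,
# log emission sds.  When `monotone` names a feature column, that feature's
# per-state means are parameterised as a base value plus positive
# (log-scale) increments, which constrains them to increase with the state
# and anchors the state labels along the severity axis.
model_to_par <- function(model, monotone = 0L) {
  mu <- model$emission_means
  if (monotone > 0L && nrow(mu) > 1L) {
    d <- pmax(diff(mu[, monotone]), 1e-3)
    mu[, monotone] <- c(mu[1L, monotone], log(d))
  }
  c(log(model$rates), as.vector(mu), log(as.vector(model$emission_sds)))
}

decode_means <- function(v, nr, nf, monotone) {
  mu <- matrix(v, nr, nf)
  if (monotone > 0L && nr > 1L)
    mu[, monotone] <- mu[1L, monotone] +
      c(0, cumsum(exp(pmin(mu[2:nr, monotone], 10))))
  mu
}

par_to_model <- function(par, ns, feature_names, monotone = 0L) {
  nf <- length(feature_names)
  nr <- ns - 1L
  rates <- exp(par[seq_len(nr)])
  mu <- decode_means(par[nr + seq_len(nr * nf)], nr, nf, monotone)
  sd <- matrix(exp(par[nr + nr * nf + seq_len(nr * nf)]), nr, nf)
  progression_model(rates, mu, sd, feature_names)
}

#' Fit a progressive CTHMM by maximum likelihood
#'
#' Maximises [log_likelihood()] over the log transition rates, emission
#' means and log emission standard deviations (the log transforms enforce
#' positivity), with the initial state fixed at 1.  Optimisation uses
#' quasi-Newton BFGS with finite-difference gradients; convergence is
#' declared at a relative log-likelihood change below `reltol`.
#'
#' @param initial_model Starting `hd_model` (see
#'   [init_model_from_events()]).
#' @param events An `hd_events` table.
#' @param maxit Maximum optimiser iterations per stage (default 500).
#' @param reltol Relative convergence tolerance (default 1e-7).
#' @param restarts Maximum number of quasi-Newton restarts from the current
#'   optimum (each restart resets the Hessian approximation, which lets the
#'   optimiser escape premature line-search stalls); restarting stops once
#'   the log-likelihood improves by less than `restart_tol`.
#' @param restart_tol Minimum log-likelihood gain (nats) that triggers
#'   another restart (default 1e-3).
#' @param stage_rates If `TRUE` (default), first optimise the transition
#'   rates alone with the emissions held at their initial values, then
#'   optimise everything jointly; the low-dimensional first stage is much
#'   less prone to poor local optima.
#' @param monotone Column index of the feature whose per-state emission
#'   means are constrained to be non-decreasing in the state (default 1,
#'   the dominant severity axis; set to 0 to disable).  The constraint
#'   anchors the state ordering and removes label-permuted and
#'   severity-inverted local optima; the initial model's means for that
#'   feature must already be non-decreasing.
#' @param hessian If `TRUE`, also compute approximate standard errors from
#'   the numerically differentiated Hessian at the optimum.
#' @return An object of class `hd_fit`: list with elements `model`,
#'   `log_likelihood`, `converged`, `iterations`, and optionally
#'   `standard_errors` (on the working scale: log rates, means, log sds).
#' @export
fit_cthmm <- function(initial_model, events, maxit = 500L, reltol = 1e-7,
                      restarts = 4L, restart_tol = 1e-3,
                      stage_rates = TRUE, monotone = 1L, hessian = FALSE) {
  stopifnot(inherits(initial_model, "hd_model"))
  if (is.null(initial_model$emission_means))
    stop("initial model must carry emission parameters")
  ns <- initial_model$n_states
  fn <- initial_model$feature_names
  monotone <- as.integer(monotone)
  if (monotone > length(fn)) monotone <- 0L
  pk <- pack_events(events, fn)
  nr <- ns - 1L
  nf <- length(fn)
  negll <- function(par) {
    rates <- exp(par[seq_len(nr)])
    mu <- decode_means(par[nr + seq_len(nr * nf)], nr, nf, monotone)
    sd <- matrix(exp(par[nr + nr * nf + seq_len(nr * nf)]), nr, nf)
    ll <- sum(.cthmm_loglik_cpp(pk$offsets, pk$kind, pk$age, pk$lo, pk$hi,
                                pk$feat, rates, mu, sd))
    if (!is.finite(ll)) 1e10 else -ll
  }
  ctl <- list(maxit = as.integer(maxit), reltol = reltol)
  par0 <- model_to_par(initial_model, monotone)
  nev <- 0L
  if (stage_rates) {
    fixed <- par0[-seq_len(nr)]
    opt1 <- stats::optim(par0[seq_len(nr)],
                         function(r) negll(c(r, fixed)),
                         method = "BFGS", control = ctl)
    par0[seq_len(nr)] <- opt1$par
    nev <- nev + unname(opt1$counts["function"])
  }
  opt <- stats::optim(par0, negll, method = "BFGS", control = ctl)
  nev <- nev + unname(opt$counts["function"])
  for (r in seq_len(restarts)) {
    opt2 <- stats::optim(opt$par, negll, method = "BFGS", control = ctl)
    nev <- nev + unname(opt2$counts["function"])
    gain <- opt$value - opt2$value
    if (opt2$value < opt$value) opt <- opt2
    if (gain < restart_tol) break
  }
  if (hessian)
    opt$hessian <- stats::optimHess(opt$par, negll, control = ctl)
  res <- list(model = par_to_model(opt$par, ns, fn, monotone),
              log_likelihood = -opt$value,
              converged = opt$convergence == 0L,
              iterations = nev,
              optim_message = opt$message)
  if (hessian) {
    se <- rep(NA_real_, length(opt$par))
    ev <- try(eigen(opt$hessian, symmetric = TRUE, only.values = TRUE)$values,
              silent = TRUE)
    if (!inherits(ev, "try-error") && all(ev > 0))
      se <- sqrt(diag(solve(opt$hessian)))
    res$standard_errors <- se
  }
  class(res) <- "hd_fit"
  res
}

#' @export
print.hd_fit <- function(x, ...) {
  cat("CTHMM fit:", if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "likelihood evaluations\n")
  cat("log-likelihood:", format(x$log_likelihood, digits = 10), "\n")
  print(x$model)
  invisible(x)
}

#' Initialise a CTHMM from the empirical feature distribution
#'
#' Visits are clustered on the first feature (the dominant severity axis)
#' with k-means into `ns - 1` groups; clusters are ordered along the
#' disease course, using the sign of the correlation between the first
#' feature and visit age to orient the axis.  Per-cluster feature means and
#' standard deviations seed the emissions.  Initial exit rates are derived
#' from the clusters' mean visit ages: the implied state-entry ages are the
#' midpoints between consecutive cluster mean ages (state 1 entered at age
#' 0), the last exit is anchored at the mean recorded death age when
#' available, and initial sojourns are clamped to a plausible 2-40 year
#' range.  The k-means step runs under a fixed internal seed, so the
#' initialisation is deterministic given the data.
#'
#' @param events An `hd_events` table.
#' @param n_states Total number of states including death.
#' @param feature_names Features to use; default all in `events`.
#' @return An `hd_model` suitable as `initial_model` for [fit_cthmm()].
#' @export
init_model_from_events <- function(events, n_states,
                                   feature_names = attr(events, "features")) {
  stopifnot(inherits(events, "hd_events"), n_states >= 2L)
  vis <- events[events$kind == "visit", , drop = FALSE]
  nliv <- n_states - 1L
  if (nrow(vis) < 3L * nliv)
    stop("too few visits to initialise a ", n_states, "-state model")
  X <- as.matrix(vis[, feature_names, drop = FALSE])
  x1 <- X[, 1]
  km <- with_seed(7919L, tryCatch(
    stats::kmeans(x1, centers = nliv, nstart = 10L, iter.max = 50L),
    error = function(e) NULL))
  if (is.null(km) || length(unique(km$cluster)) < nliv) {
    # degenerate feature (heavy ties): fall back to rank binning
    cl <- as.integer(cut(rank(x1, ties.method = "first"), breaks = nliv))
  } else {
    cl <- km$cluster
  }
  # clusters ordered by ascending first-feature mean: the first feature is
  # expected to be oriented so that higher values mean more advanced
  # disease (see the orient_negative argument of fit_group_pca())
  cmean <- tapply(x1, cl, mean)
  ord <- order(cmean)
  cl <- match(cl, as.integer(names(cmean))[ord])
  mu <- do.call(rbind, lapply(seq_len(nliv), function(s)
    colMeans(X[cl == s, , drop = FALSE])))
  sg <- do.call(rbind, lapply(seq_len(nliv), function(s)
    apply(X[cl == s, , drop = FALSE], 2, stats::sd)))
  floor_sd <- pmax(apply(X, 2, stats::sd) * 0.1, 1e-3)
  sg <- sweep(sg, 2, floor_sd, pmax)
  sg[!is.finite(sg)] <- 1
  # rate seeds from the clusters' age structure
  a <- as.numeric(tapply(vis$age, cl, mean))
  a <- cummax(a)                             # enforce non-decreasing ages
  entry <- c(0, (a[-nliv] + a[-1]) / 2)
  dx <- events$age[events$kind == "death_exact"]
  last_exit <- if (length(dx) >= 5L) mean(dx) else max(vis$age) + 5
  sojourn <- diff(c(entry, max(last_exit, entry[nliv] + 2)))
  sojourn <- pmin(pmax(sojourn, 2), 40)
  progression_model(1 / sojourn, mu, sg, feature_names)
}

#' Viterbi decoding of the most likely state at each visit
#'
#' Max-product dynamic programming over each patient's event sequence,
#' using [transition_matrix()] for the gaps between events.  The path is
#' pinned to state 1 at age 0; exact and interval-censored death events
#' weight the terminal transition into the absorbing state.  Ties are
#' broken toward the lower state.
#'
#' @param model A fitted `hd_model`.
#' @param events An `hd_events` table.
#' @return Data frame with columns `patient_id`, `age`, `state`: the most
#'   likely state at every visit.
#' @export
viterbi <- function(model, events) {
  stopifnot(inherits(model, "hd_model"), inherits(events, "hd_events"))
  fn <- model$feature_names
  ns <- model$n_states
  Q <- generator_matrix(model)
  out <- vector("list", length(unique(events$patient_id)))
  k <- 0L
  for (pid in unique(events$patient_id)) {
    rows <- events[events$patient_id == pid, , drop = FALSE]
    vis <- rows[rows$kind == "visit", , drop = FALSE]
    nv <- nrow(vis)
    if (nv == 0L) next
    death <- rows[rows$kind %in% c("death_exact", "death_interval"), ,
                  drop = FALSE]
    # delta[v, s]: best log-probability of a path ending in state s at
    # visit v; psi for backtracking
    delta <- matrix(-Inf, nv, ns)
    psi <- matrix(1L, nv, ns)
    tprev <- 0
    dprev <- c(0, rep(-Inf, ns - 1L))  # birth pins state 1 at age 0
    for (v in seq_len(nv)) {
      lp <- log(transition_matrix(Q, vis$age[v] - tprev))
      x <- as.numeric(vis[v, fn])
      for (s in seq_len(ns - 1L)) {
        cand <- dprev + lp[, s]
        b <- which.max(cand)  # which.max returns the first (lowest) argmax
        emis <- sum(stats::dnorm(x, model$emission_means[s, ],
                                 model$emission_sds[s, ], log = TRUE))
        delta[v, s] <- cand[b] + emis
        psi[v, s] <- b
      }
      dprev <- delta[v, ]
      tprev <- vis$age[v]
    }
    term <- dprev
    if (nrow(death) == 1L) {
      if (death$kind == "death_exact") {
        lp <- log(transition_matrix(Q, death$age - tprev))
        term <- dprev + lp[, ns - 1L] + log(model$rates[ns - 1L])
      } else {
        Pl <- transition_matrix(Q, max(death$lo - tprev, 0))
        Ph <- transition_matrix(Q, max(death$hi - tprev, 0))
        term <- dprev + log(pmax(Ph[, ns] - Pl[, ns], 0))
      }
    }
    states <- integer(nv)
    states[nv] <- which.max(term[seq_len(ns - 1L)])
    if (nv > 1L)
      for (v in (nv - 1L):1L) states[v] <- psi[v + 1L, states[v + 1L]]
    k <- k + 1L
    out[[k]] <- data.frame(patient_id = pid, age = vis$age, state = states)
  }
  do.call(rbind, out[seq_len(k)])
}
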