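#' Configuration for cross-validated state-count selection
#'
#' @param candidate_n_states Candidate total state counts (death included);
#'   each must be at least 3 (two living states plus death).
#' @param n_folds Number of cross-validation folds (>= 2); patients, never
#'   individual visits, are assigned to folds.
#' @param seed Integer seed controlling the fold assignment.
#' @param maxit,reltol,restarts Optimiser options for the per-fold fits;
#'   the defaults are lighter than [fit_cthmm()]'s because model comparison
#'   needs relative, not absolute, optimisation depth (all candidates are
#'   fitted under the same budget).
#' @return A list of class `hd_selection_config`.
#' @export
selection_config <- function(candidate_n_states = 3:7, n_folds = 5L,
                             seed = 1L, maxit = 60L, reltol = 1e-5,
                             restarts = 0L) {
  if (any(candidate_n_states < 3L))
    stop("candidates must have at least 2 living states plus death")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(list(candidate_n_states = as.integer(candidate_n_states),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 maxit = as.integer(maxit), reltol = reltol,
                 restarts = as.integer(restarts)),
            class = "hd_selection_config")
}

# Seeded fold assignment by patient; sorting first makes the assignment
# invariant to the input ordering of patients.
assign_folds <- function(patient_ids, n_folds, seed) {
  ids <- sort(unique(as.character(patient_ids)))
  perm <- with_seed(seed, sample(length(ids)))
  stats::setNames(rep_len(seq_len(n_folds), length(ids))[order(perm)], ids)
}

#' Cross-validated held-out log-likelihood for one state count
#'
#' Patients are partitioned into folds; for each fold a CTHMM with
#' `n_states` states is fitted on the training patients (initialised from
#' the training data) and evaluated on the held-out patients.  Folds whose
#' fit does not converge are flagged and excluded from the mean, with a
#' warning.
#'
#' @param events An `hd_events` table.
#' @param n_states Total number of states including death.
#' @param config An `hd_selection_config`.
#' @return List with `fold_loglik` (held-out log-likelihood per fold),
#'   `converged` (per-fold flags), and `mean` over converged folds.
#' @export
cross_validated_loglik <- function(events, n_states,
                                   config = selection_config()) {
  stopifnot(inherits(events, "hd_events"),
            inherits(config, "hd_selection_config"))
  folds <- assign_folds(events$patient_id, config$n_folds, config$seed)
  fl <- rep(NA_real_, config$n_folds)
  ok <- rep(FALSE, config$n_folds)
  for (f in seq_len(config$n_folds)) {
    test_ids <- names(folds)[folds == f]
    tr <- events[!(events$patient_id %in% test_ids), , drop = FALSE]
    te <- events[events$patient_id %in% test_ids, , drop = FALSE]
    attr(tr, "features") <- attr(te, "features") <- attr(events, "features")
    class(tr) <- class(te) <- class(events)
    fit <- try(fit_cthmm(init_model_from_events(tr, n_states), tr,
                         maxit = config$maxit, reltol = config$reltol,
                         restarts = config$restarts),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    fl[f] <- log_likelihood(fit$model, te)
    ok[f] <- fit$converged && is.finite(fl[f])
  }
  if (!all(ok))
    warning(sum(!ok), " fold(s) did not converge for ns = ", n_states,
            "; the mean is over converged folds")
  if (!any(ok)) stop("no fold converged for ns = ", n_states)
  list(fold_loglik = fl, converged = ok, mean = mean(fl[ok]))
}

#' Select the number of disease states by cross-validated likelihood
#'
#' Runs [cross_validated_loglik()] for every candidate and selects the
#' state count by mean held-out log-likelihood, breaking statistical ties
#' toward parsimony: with the one-standard-error rule (the default), the
#' chosen candidate is the smallest one whose mean deficit relative to the
#' best candidate is within one standard error of that deficit, where the
#' standard error is computed from the fold-paired differences (each fold
#' evaluates both candidates on the same held-out patients, so pairing
#' removes the large common fold-to-fold variation).  Candidates whose mean
#' held-out log-likelihood is genuinely lower are never promoted; with
#' `one_se = FALSE` the raw argmax is returned (exact ties still resolve to
#' the smaller candidate).
#'
#' @param events An `hd_events` table.
#' @param config An `hd_selection_config`.
#' @param one_se Use the fold-paired one-standard-error parsimony rule
#'   (default `TRUE`).
#' @return List of class `hd_selection`: `chosen` (selected total state
#'   count), `argmax` (raw argmax of the mean), `table` (data frame of
#'   candidate, mean, sd), and `folds` (per-candidate fold detail).
#' @export
select_num_states <- function(events, config = selection_config(),
                              one_se = TRUE) {
  res <- lapply(config$candidate_n_states, function(ns)
    try(cross_validated_loglik(events, ns, config), silent = TRUE))
  ok <- !vapply(res, inherits, logical(1), "try-error")
  if (!any(ok)) stop("all candidate state counts failed to fit")
  means <- ifelse(ok, vapply(res, function(r)
    if (is.list(r)) r$mean else NA_real_, numeric(1)), NA_real_)
  sds <- vapply(seq_along(res), function(i) {
    if (!ok[i]) return(NA_real_)
    stats::sd(res[[i]]$fold_loglik[res[[i]]$converged])
  }, numeric(1))
  tab <- data.frame(n_states = config$candidate_n_states,
                    mean_heldout_loglik = means, sd_heldout_loglik = sds)
  ibest <- which.max(means)                  # first max: smaller ns on ties
  chosen <- config$candidate_n_states[ibest]
  if (one_se) {
    for (i in seq_len(ibest - 1L)) {
      if (!ok[i]) next
      both <- res[[i]]$converged & res[[ibest]]$converged
      if (sum(both) < 2L) next
      d <- res[[ibest]]$fold_loglik[both] - res[[i]]$fold_loglik[both]
      se <- stats::sd(d) / sqrt(sum(both))
      if (mean(d) <= se) {
        chosen <- config$candidate_n_states[i]
        break
      }
    }
  }
  structure(list(chosen = chosen,
                 argmax = config$candidate_n_states[ibest], table = tab,
                 folds = stats::setNames(res, config$candidate_n_states)),
            class = "hd_selection")
}

#' @export
print.hd_selection <- function(x, ...) {
  cat("Cross-validated state-count selection; chosen ns =", x$chosen, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
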