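#' Feature-construction configuration
#'
#' @param log_transformed_variables Scores mapped by `x -> log(1 + x)`
#'   before PCA (the offset keeps zero scores finite).
#' @param n_pcs Number of principal components kept as CTHMM observations.
#' @param age_bracket_width Width (years) of the half-open age brackets used
#'   for the initial grouped PCA; brackets are built to span the observed
#'   ages.
#' @param age_brackets Optional explicit breakpoints (ascending, half-open
#'   `[lo, hi)` bins) overriding `age_bracket_width`.
#' @param correlation_threshold Stop threshold for the maximum absolute
#'   within-state Pearson correlation between PC scores (default 0.2).
#' @param max_iterations Maximum PCA/CTHMM re-grouping iterations.
#' @return A list of class `hd_feature_config`.
#' @export
feature_config <- function(log_transformed_variables =
                             c("exfscore", "irascore", "aptscore",
                               "fascore", "motscore"),
                           n_pcs = 2L,
                           age_bracket_width = 10,
                           age_brackets = NULL,
                           correlation_threshold = 0.2,
                           max_iterations = 10L) {
  if (n_pcs < 1L) stop("n_pcs must be >= 1")
  if (correlation_threshold <= 0 || correlation_threshold >= 1)
    stop("correlation_threshold must lie in (0, 1)")
  structure(list(log_transformed_variables = log_transformed_variables,
                 n_pcs = as.integer(n_pcs),
                 age_bracket_width = age_bracket_width,
                 age_brackets = age_brackets,
                 correlation_threshold = correlation_threshold,
                 max_iterations = as.integer(max_iterations)),
            class = "hd_feature_config")
}

#' Log-transform skewed clinical scores
#'
#' Maps each listed variable by `x -> log(1 + x)` (scores can be zero, hence
#' the unit offset); all other columns pass through unchanged.
#'
#' @param scores Data frame of raw scores.
#' @param variables Variables to transform.
#' @return The data frame with the listed columns transformed.
#' @export
log_transform <- function(scores,
                          variables = feature_config()$log_transformed_variables) {
  scores <- as.data.frame(scores)
  vars <- intersect(variables, names(scores))
  for (v in vars) {
    if (any(scores[[v]] < 0, na.rm = TRUE))
      stop("negative values in `", v, "` cannot be log-transformed")
    scores[[v]] <- log1p(scores[[v]])
  }
  scores
}

#' Build half-open age brackets spanning a set of ages
#'
#' @param ages Numeric visit ages (years).
#' @param width Bracket width in years.
#' @return Ascending breakpoints suitable for [assign_age_brackets()].
#' @export
make_age_brackets <- function(ages, width = 10) {
  lo <- floor(min(ages) / width) * width
  hi <- ceiling((max(ages) + 1e-9) / width) * width
  seq(lo, hi, by = width)
}

#' Assign visits to age brackets
#'
#' Ages outside the bracket range are assigned to the nearest bracket.
#'
#' @param ages Numeric visit ages.
#' @param breaks Ascending breakpoints defining half-open bins `[lo, hi)`.
#' @return A factor with one level per bracket, labelled `"[lo,hi)"`.
#' @export
assign_age_brackets <- function(ages, breaks) {
  nb <- length(breaks) - 1L
  idx <- findInterval(ages, breaks)
  idx[idx < 1L] <- 1L
  idx[idx > nb] <- nb
  labs <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1])
  factor(labs[idx], levels = labs)
}

#' Grouped principal component analysis with sign alignment
#'
#' Within each group the variables are standardised to zero mean and unit
#' variance and the correlation matrix is eigendecomposed; the leading
#' `n_pcs` eigenvectors are kept as loadings.  Components are oriented
#' consistently across groups: in the first group each component's
#' largest-magnitude loading is made positive, and in every subsequent group
#' each component is flipped if needed so its dot product with the matched
#' component of the previous group is non-negative (so scores are
#' comparable across groups).
#'
#' @param scores Data frame or matrix of (transformed) scores.
#' @param group Factor assigning each row to a group; empty levels are
#'   dropped.
#' @param n_pcs Number of components to keep.
#' @param grouping_kind Label recording how the groups were formed
#'   (`"age_bracket"`, `"fitted_state"`, ...).
#' @param orient_negative Optional variable names whose combined loading on
#'   the first component must be negative (after the cross-group
#'   alignment, all groups' first components are flipped together if
#'   needed).  Passing the scores that are clinically known to decline with
#'   disease severity pins the orientation of the severity axis, so that a
#'   higher PC1 score always means a sicker visit regardless of the sample;
#'   the default (none) keeps the arbitrary largest-loading-positive
#'   convention.
#' @param center `"group"` (default) centres each group's projection at its
#'   own variable means; `"pooled"` centres every group at the pooled means
#'   while keeping per-group scales and loadings.  Pearson correlation is
#'   translation-invariant, so pooled centring preserves the exact
#'   within-group decorrelation of the scores while retaining the
#'   between-group location signal — essential when the groups are fitted
#'   disease states, whose separation along the severity axis must survive
#'   the projection.
#' @return An object of class `hd_pca`: per-group centering, scaling,
#'   loadings and explained-variance fractions.
#' @export
fit_group_pca <- function(scores, group, n_pcs = 2L,
                          grouping_kind = "age_bracket",
                          orient_negative = NULL,
                          center = c("group", "pooled")) {
  center <- match.arg(center)
  X <- as.matrix(scores)
  if (!is.numeric(X)) stop("scores must be numeric")
  group <- droplevels(as.factor(group))
  if (length(group) != nrow(X)) stop("group length must match rows")
  nv <- ncol(X)
  if (n_pcs > nv) stop("n_pcs cannot exceed the number of variables")
  pooled <- colMeans(X)
  groups <- list()
  prev <- NULL
  for (g in levels(group)) {
    Xg <- X[group == g, , drop = FALSE]
    if (nrow(Xg) <= nv)
      stop("group ", g, " has too few visits (", nrow(Xg),
           ") for PCA over ", nv, " variables")
    ctr <- colMeans(Xg)
    scl <- apply(Xg, 2, stats::sd)
    if (any(scl == 0))
      stop("zero-variance variable `",
           colnames(X)[which(scl == 0)[1]], "` in group ", g)
    R <- stats::cor(Xg)
    eg <- eigen(R, symmetric = TRUE)
    L <- eg$vectors[, seq_len(n_pcs), drop = FALSE]
    for (k in seq_len(n_pcs)) {
      if (is.null(prev)) {
        if (L[which.max(abs(L[, k])), k] < 0) L[, k] <- -L[, k]
      } else if (sum(L[, k] * prev[, k]) < 0) {
        L[, k] <- -L[, k]
      }
    }
    rownames(L) <- colnames(X)
    colnames(L) <- paste0("PC", seq_len(n_pcs))
    groups[[g]] <- list(center = if (center == "pooled") pooled else ctr,
                        scale = scl, loadings = L,
                        explained_variance = eg$values / sum(eg$values))
    prev <- L
  }
  if (!is.null(orient_negative)) {
    ov <- intersect(orient_negative, colnames(X))
    if (length(ov) &&
        sum(groups[[1]]$loadings[ov, 1]) > 0) {
      for (g in seq_along(groups))
        groups[[g]]$loadings[, 1] <- -groups[[g]]$loadings[, 1]
    }
  }
  structure(list(grouping_kind = grouping_kind, groups = groups,
                 n_pcs = as.integer(n_pcs), variables = colnames(X)),
            class = "hd_pca")
}

#' @export
print.hd_pca <- function(x, ...) {
  cat("Grouped PCA (", x$grouping_kind, "): ", length(x$groups),
      " group(s), ", x$n_pcs, " component(s) over ",
      length(x$variables), " variables\n", sep = "")
  ev <- sapply(x$groups, function(g)
    g$explained_variance[seq_len(x$n_pcs)])
  print(round(ev, 3))
  invisible(x)
}

#' Project visits onto a fitted grouped PCA
#'
#' Each row is standardised with its group's means and scales and multiplied
#' by that group's loadings.
#'
#' @param scores Data frame or matrix with the PCA's variables.
#' @param pc_model An `hd_pca`.
#' @param group Factor assigning each row to one of the PCA's groups.
#' @return Matrix of PC scores (rows aligned to `scores`).
#' @export
project <- function(scores, pc_model, group) {
  stopifnot(inherits(pc_model, "hd_pca"))
  X <- as.matrix(as.data.frame(scores)[, pc_model$variables, drop = FALSE])
  group <- as.character(group)
  unknown <- setdiff(unique(group), names(pc_model$groups))
  if (length(unknown))
    stop("rows assigned to group(s) unknown to the PCA: ",
         paste(unknown, collapse = ", "))
  out <- matrix(NA_real_, nrow(X), pc_model$n_pcs,
                dimnames = list(NULL, paste0("PC", seq_len(pc_model$n_pcs))))
  for (g in unique(group)) {
    gi <- which(group == g)
    gm <- pc_model$groups[[g]]
    Z <- sweep(sweep(X[gi, , drop = FALSE], 2, gm$center), 2, gm$scale, "/")
    out[gi, ] <- Z %*% gm$loadings
  }
  out
}

#' Within-state correlation check between PC scores
#'
#' Pearson correlations between the PC columns are computed within each
#' fitted disease state; the maximum absolute off-diagonal value drives the
#' stop rule of [iterative_fit()].  States with fewer than 3 visits are
#' skipped with a warning.
#'
#' @param scores Matrix of PC scores.
#' @param states Integer fitted state per row.
#' @return List with `per_state` correlation matrices and `max_abs_r`.
#' @export
state_correlation_check <- function(scores, states) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L)
    return(list(per_state = list(), max_abs_r = 0))
  per_state <- list()
  mx <- 0
  for (s in sort(unique(states))) {
    Xs <- scores[states == s, , drop = FALSE]
    if (nrow(Xs) < 3L) {
      warning("state ", s, " has fewer than 3 visits; skipped in the ",
              "correlation check")
      next
    }
    R <- stats::cor(Xs)
    per_state[[as.character(s)]] <- R
    off <- abs(R[upper.tri(R)])
    off <- off[is.finite(off)]
    if (length(off)) mx <- max(mx, off)
  }
  list(per_state = per_state, max_abs_r = mx)
}

# Merge groups too small for PCA into their nearest neighbouring level.
merge_small_groups <- function(group, min_size) {
  group <- droplevels(as.factor(group))
  repeat {
    sizes <- table(group)
    small <- names(sizes)[sizes < min_size]
    if (!length(small) || nlevels(group) == 1L) break
    lev <- levels(group)
    i <- match(small[1], lev)
    target <- if (i > 1L) lev[i - 1L] else lev[i + 1L]
    levels(group)[levels(group) == small[1]] <- target
    group <- droplevels(group)
  }
  group
}

#' Iterative grouped-PCA / CTHMM fitting loop
#'
#' Implements the three-step fitting algorithm: (i) grouped PCA on age
#' brackets, (ii) CTHMM fit on the PC scores, (iii) Viterbi decoding and a
#' within-state correlation check.  If any absolute within-state Pearson
#' correlation between PCs reaches the threshold, the PCA is recomputed with
#' the fitted states as the grouping and the loop repeats, stopping at
#' convergence or `max_iterations` (in which case the best model is returned
#' flagged as non-converged).  The CTHMM's conditional-independence
#' assumption on its observed features is exactly what the threshold
#' enforces.
#'
#' @param cohort An `hd_cohort` (or anything with `visits` and `patients`
#'   data frames in the same schema).
#' @param config An `hd_feature_config`.
#' @param n_states Number of CTHMM states including death.
#' @param upper_bound Optional calibrated artificial death-age upper bound;
#'   when supplied, censored patients contribute interval-censored death
#'   events (see [build_events()]).
#' @param maxit,reltol Optimiser options passed to [fit_cthmm()].
#' @return A list of class `hd_pipeline_fit`: `pc_model`, `fit` (the
#'   `hd_fit`), `scores`, `states` (per-visit Viterbi decode), `iterations`,
#'   `max_abs_r`, `converged`.
#' @export
iterative_fit <- function(cohort, config = feature_config(), n_states = 5L,
                          upper_bound = NULL, maxit = 500L, reltol = 1e-7) {
  stopifnot(inherits(config, "hd_feature_config"))
  visits <- cohort$visits
  trans <- log_transform(visits, config$log_transformed_variables)
  vars <- default_score_model()$vars
  X <- trans[, vars, drop = FALSE]
  breaks <- config$age_brackets
  if (is.null(breaks))
    breaks <- make_age_brackets(visits$age_at_visit, config$age_bracket_width)
  group <- merge_small_groups(
    assign_age_brackets(visits$age_at_visit, breaks),
    min_size = length(vars) + 2L)
  grouping_kind <- "age_bracket"
  # scores that decline as HD progresses pin the severity orientation of PC1
  declining <- c("swrt1", "sit1", "sdmt1", "scnt1", "verfct5",
                 "tfcscore", "indepscl")
  best <- NULL
  for (it in seq_len(config$max_iterations)) {
    pcm <- fit_group_pca(X, group, config$n_pcs, grouping_kind,
                         orient_negative = declining,
                         center = if (grouping_kind == "fitted_state")
                           "pooled" else "group")
    scores <- project(X, pcm, group)
    ev <- build_events(cohort, scores, upper_bound)
    init <- init_model_from_events(ev, n_states)
    fit <- fit_cthmm(init, ev, maxit = maxit, reltol = reltol)
    vit <- viterbi(fit$model, ev)
    key_v <- paste(visits$patient_id, round(visits$age_at_visit, 9))
    key_s <- paste(vit$patient_id, round(vit$age, 9))
    st <- vit$state[match(key_v, key_s)]
    cc <- state_correlation_check(scores, st)
    res <- structure(list(pc_model = pcm, fit = fit, scores = scores,
                          states = st, events = ev, iterations = it,
                          max_abs_r = cc$max_abs_r,
                          converged = cc$max_abs_r <
                            config$correlation_threshold),
                     class = "hd_pipeline_fit")
    if (is.null(best) || res$max_abs_r < best$max_abs_r) best <- res
    if (res$converged) return(res)
    group <- merge_small_groups(factor(st), min_size = length(vars) + 2L)
    grouping_kind <- "fitted_state"
  }
  warning("iterative fit did not reach the correlation threshold within ",
          config$max_iterations, " iteration(s); returning the best model")
  best
}

#' @export
print.hd_pipeline_fit <- function(x, ...) {
  cat("Iterative PCA/CTHMM fit:",
      if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "iteration(s); max within-state |r| =",
      signif(x$max_abs_r, 3), "\n")
  print(x$fit)
  invisible(x)
}
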