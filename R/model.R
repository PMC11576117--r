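#' Construct a progressive disease-progression model
#'
#' A progressive continuous-time hidden Markov model (CTHMM) over states
#' `1, ..., ns` in which the only permitted transitions are `i -> i + 1`
#' (no skipping, no recovery) and the last state (`ns`, death) is absorbing.
#' Living states optionally carry Gaussian emission distributions over a
#' feature vector (one mean and standard deviation per state and feature).
#'
#' The latent process always starts in state 1; time is measured in years
#' with age 0 (birth) as the origin of state 1.
#'
#' @param rates Positive transition rates `q[i]` out of each living state
#'   `i` into `i + 1`, per year; length `ns - 1`.
#' @param emission_means Optional numeric matrix, `(ns - 1) x n_features`,
#'   of per-state emission means (living states only).
#' @param emission_sds Optional matrix of matching shape with positive
#'   per-state emission standard deviations.
#' @param feature_names Optional character vector of feature names.
#' @return An object of class `hd_model`.
#' @seealso [transition_matrix()], [mean_sojourn_times()],
#'   [sample_trajectory()], [fit_cthmm()]
#' @examples
#' m <- progression_model(rates = 1 / c(23.6, 17.6, 12.7, 11.4))
#' mean_sojourn_times(m)
#' @export
progression_model <- function(rates, emission_means = NULL,
                              emission_sds = NULL, feature_names = NULL) {
  rates <- as.numeric(rates)
  if (length(rates) < 1L || any(!is.finite(rates)) || any(rates < 0))
    stop("`rates` must be finite, non-negative transition rates (per year)")
  ns <- length(rates) + 1L
  if (!is.null(emission_means)) {
    emission_means <- as.matrix(emission_means)
    if (is.null(emission_sds))
      stop("`emission_sds` must accompany `emission_means`")
    emission_sds <- as.matrix(emission_sds)
    if (!identical(dim(emission_means), dim(emission_sds)))
      stop("emission mean and sd matrices must have identical shape")
    if (nrow(emission_means) != ns - 1L)
      stop("emission parameters must have one row per living state (",
           ns - 1L, ")")
    if (any(!is.finite(emission_means)) || any(!is.finite(emission_sds)) ||
        any(emission_sds <= 0))
      stop("emission sds must be finite and strictly positive")
    if (is.null(feature_names)) {
      feature_names <- colnames(emission_means)
      if (is.null(feature_names))
        feature_names <- paste0("PC", seq_len(ncol(emission_means)))
    }
    colnames(emission_means) <- colnames(emission_sds) <- feature_names
  }
  structure(
    list(n_states = ns, rates = rates,
         emission_means = emission_means, emission_sds = emission_sds,
         feature_names = feature_names),
    class = "hd_model")
}

#' @export
print.hd_model <- function(x, ...) {
  cat("Progressive CTHMM:", x$n_states, "states (",
      x$n_states - 1L, "living + death )\n")
  soj <- mean_sojourn_times(x)
  cat("Mean sojourn times (y):", paste(signif(soj, 4), collapse = ", "), "\n")
  if (!is.null(x$emission_means)) {
    cat("Emissions over", ncol(x$emission_means), "feature(s):",
        paste(x$feature_names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Generator (transition-intensity) matrix of a progression model
#'
#' @param model An `hd_model`.
#' @return An `ns x ns` intensity matrix `Q` with `Q[i, i + 1] = rates[i]`,
#'   `Q[i, i] = -rates[i]`, and an all-zero absorbing death row.
#' @export
generator_matrix <- function(model) {
  stopifnot(inherits(model, "hd_model"))
  ns <- model$n_states
  Q <- matrix(0, ns, ns)
  for (i in seq_len(ns - 1L)) {
    Q[i, i + 1L] <- model$rates[i]
    Q[i, i] <- -model$rates[i]
  }
  Q
}

#' Mean sojourn time in each living state
#'
#' The expected holding time in state `i` is `1 / (-q_ii)`; the absorbing
#' death state is excluded.  A living state with zero exit rate has infinite
#' mean sojourn.
#'
#' @param model An `hd_model`, or a generator matrix `Q`.
#' @return Numeric vector of length `ns - 1`, in years.
#' @export
mean_sojourn_times <- function(model) {
  rates <- if (inherits(model, "hd_model")) model$rates else {
    Q <- validate_generator(model)
    -diag(Q)[-nrow(Q)]
  }
  ifelse(rates > 0, 1 / rates, Inf)
}

# Validate that Q is a progressive generator: non-negative off-diagonals,
# zero row sums, only the superdiagonal nonzero off the diagonal, absorbing
# final row.  Returns Q invisibly.
validate_generator <- function(Q) {
  Q <- as.matrix(Q)
  ns <- nrow(Q)
  if (ns != ncol(Q) || ns < 2L) stop("Q must be a square matrix, ns >= 2")
  if (any(!is.finite(Q))) stop("Q must be finite")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal intensities must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-8 * (1 + max(abs(Q)))))
    stop("generator rows must sum to zero")
  allowed <- cbind(seq_len(ns - 1L), 2:ns)
  bad <- off
  bad[allowed] <- 0
  if (any(bad != 0))
    stop("generator is not progressive: only i -> i+1 intensities allowed")
  if (any(Q[ns, ] != 0)) stop("final (death) state must be absorbing")
  Q
}

# Transition probabilities of a progressive chain with out-rates `q`
# (length ns, q[ns] = 0) over elapsed time dt, by the closed form for a
# hypoexponential chain with distinct rates:
#   P_ij(t) = prod(q[i:(j-1)]) * sum_{k in i:j} exp(-q_k t) /
#             prod_{l in i:j, l != k} (q_l - q_k)
# Requires all q[i:j] distinct; callers fall back to a matrix exponential
# when rates collide.
prog_tpm_closed <- function(q, dt) {
  ns <- length(q)
  P <- diag(exp(-q * dt), ns)
  for (i in seq_len(ns - 1L)) {
    cp <- 1
    for (j in (i + 1L):ns) {
      cp <- cp * q[j - 1L]
      if (cp == 0) break
      idx <- i:j
      acc <- 0
      for (k in idx) {
        acc <- acc + exp(-q[k] * dt) / prod(q[idx[idx != k]] - q[k])
      }
      P[i, j] <- cp * acc
    }
  }
  # clip tiny negative round-off
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probability matrix over an elapsed time
#'
#' Computes `expm(Q * dt)` for a progressive generator.  When the exit rates
#' are pairwise distinct the hypoexponential closed form is used; otherwise
#' the computation falls back to [Matrix::expm()].
#'
#' @param Q A progressive generator matrix, or an `hd_model`.
#' @param dt Elapsed time in years; must be `>= 0`.
#' @return A row-stochastic `ns x ns` matrix.
#' @examples
#' Q <- generator_matrix(progression_model(c(0.5, 0.2)))
#' transition_matrix(Q, 2)[1, 2]
#' @export
transition_matrix <- function(Q, dt) {
  if (inherits(Q, "hd_model")) Q <- generator_matrix(Q)
  Q <- validate_generator(Q)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("`dt` must be a single non-negative number of years")
  ns <- nrow(Q)
  if (dt == 0) return(diag(ns))
  q <- -diag(Q)
  gaps <- abs(outer(q, q, "-"))
  # the closed form loses ~1/gap in precision to cancellation; use the
  # general matrix exponential when rates are too close
  distinct <- all(gaps[upper.tri(gaps)] > 1e-3 * (1 + max(q)))
  if (distinct) {
    prog_tpm_closed(q, dt)
  } else {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * dt)))
    P[P < 0] <- 0
    P / rowSums(P)
  }
}

#' Sample one latent disease trajectory
#'
#' Draws the exponential holding time of each living state from the model's
#' generator and returns the state-entry ages of the progressive sequence
#' `1, 2, ..., ns` (death).  State 1 is entered at age 0 (birth).
#'
#' @param model An `hd_model` whose living exit rates are all strictly
#'   positive (death must be reachable from every living state).
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame with columns `state` and `entry_age` (years),
#'   strictly increasing in `entry_age`, ending with the death state.
#' @examples
#' sample_trajectory(progression_model(1 / c(23.6, 17.6, 12.7, 11.4)), seed = 1)
#' @export
sample_trajectory <- function(model, seed = NULL) {
  stopifnot(inherits(model, "hd_model"))
  if (any(model$rates <= 0))
    stop("non-progressive structure: death is unreachable (a living state ",
         "has zero exit rate)")
  draw <- function() {
    holds <- stats::rexp(length(model$rates), rate = model$rates)
    data.frame(state = seq_len(model$n_states),
               entry_age = c(0, cumsum(holds)))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash of a string, for per-patient RNG substreams.
stable_hash <- function(x, salt = 0L) {
  m <- 2147483647
  h <- as.numeric(salt) %% m
  for (cc in utf8ToInt(as.character(x))) h <- (h * 31 + cc) %% m
  as.integer(h)
}
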