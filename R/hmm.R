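# Hidden Markov models over the discretized emission alphabet.
#
# Conventions: all stochastic matrices are column-stochastic, i.e. the column
# indexes the conditioning variable. T[j, i] = p(x_n = j | x_{n-1} = i) and
# E[y, j] = p(y_n = y | x_n = j). Probabilities are reported in log2 (bits)
# throughout, matching the trajectory-entropy definition H(y_{1:n}) =
# -log2 p(y_{1:n}).

#' Construct a hidden Markov model
#'
#' @param pi Initial distribution over the `K` hidden states.
#' @param T K x K column-stochastic hidden-state transition matrix,
#'   `T[j, i] = p(x_n = j | x_{n-1} = i)`.
#' @param E K_E x K column-stochastic emission matrix,
#'   `E[y, j] = p(y_n = y | x_n = j)`.
#' @param emission_floor Floor applied to `E` (then renormalized) so that no
#'   observed symbol has exactly zero likelihood; required when one condition's
#'   trajectories are scored under another condition's model.
#' @return An object of class `"hmm"`.
#' @export
hmm_model <- function(pi, T, E, emission_floor = 0) {
  pi <- as.numeric(pi); T <- as.matrix(T); E <- as.matrix(E)
  K <- length(pi)
  stopifnot(nrow(T) == K, ncol(T) == K, ncol(E) == K)
  check_stochastic(pi, "pi"); check_stochastic(T, "T"); check_stochastic(E, "E")
  if (emission_floor > 0) {
    E <- normalize_columns(pmax(E, emission_floor))
  }
  structure(list(K = K, K_E = nrow(E), pi = pi, T = T, E = E,
                 emission_floor = emission_floor),
            class = "hmm")
}

check_stochastic <- function(x, name) {
  if (any(x < 0)) dynmi_stop("dynmi_bad_model", sprintf("%s has negative entries", name))
  s <- if (is.matrix(x)) colSums(x) else sum(x)
  if (any(abs(s - 1) > 1e-12))
    dynmi_stop("dynmi_bad_model", sprintf("%s columns must sum to 1 (max dev %.3g)",
                                          name, max(abs(s - 1))))
  invisible(TRUE)
}

#' @export
print.hmm <- function(x, ...) {
  cat(sprintf("Hidden Markov model: %d hidden states, %d emission symbols", x$K, x$K_E))
  if (!is.null(x$loglik)) cat(sprintf(", train log-lik %.2f bits", x$loglik))
  cat("\n")
  invisible(x)
}

## Vectorized scaled forward pass over a whole ensemble.
## states: m x N integer matrix (1-based symbols). Returns m x N matrix of
## log2 p(y_{1:n}) prefix values. Scaling per trajectory avoids underflow for
## arbitrarily long trajectories.
hmm_prefix_matrix <- function(model, states) {
  m <- nrow(states); N <- ncol(states)
  if (any(states < 1L) || any(states > model$K_E))
    dynmi_stop("dynmi_bad_state", "trajectory symbol outside the model's emission alphabet")
  out <- matrix(NA_real_, m, N)
  alpha <- model$pi * t(model$E[states[, 1L], , drop = FALSE]) # K x m
  cn <- colSums(alpha)
  lp <- log2(cn)
  out[, 1L] <- lp
  alpha <- sweep(alpha, 2L, pmax(cn, .Machine$double.xmin), "/")
  if (N >= 2L) for (n in 2:N) {
    alpha <- (model$T %*% alpha) * t(model$E[states[, n], , drop = FALSE])
    cn <- colSums(alpha)
    lp <- lp + log2(cn)
    out[, n] <- lp
    alpha <- sweep(alpha, 2L, pmax(cn, .Machine$double.xmin), "/")
  }
  out
}

#' Cumulative log2 trajectory probabilities under a hidden Markov model
#'
#' Runs the forward recursion
#' `p(y_{1:n}, x_n) = E(y_n | x_n) * sum_{x_{n-1}} T(x_n | x_{n-1}) p(y_{1:n-1}, x_{n-1})`
#' with per-step scaling, and returns `log2 p(y_{1:n}) = log2 sum_x p(y_{1:n}, x_n)`
#' for every prefix length `n`. Values are non-increasing in `n` and all <= 0.
#'
#' @param model An [hmm_model()].
#' @param trajectory Integer vector of emission symbols in `1..K_E`.
#' @return Numeric vector of length `length(trajectory)`.
#' @export
forward_prefix_log_probs <- function(model, trajectory) {
  stopifnot(inherits(model, "hmm"))
  drop(hmm_prefix_matrix(model, matrix(as.integer(trajectory), nrow = 1L)))
}

#' Fit a hidden Markov model by Baum-Welch
#'
#' Expectation-maximization over all trajectories of the ensemble jointly, with
#' seeded random restarts; the restart with the highest total log-likelihood is
#' returned. The emission matrix is floored at `emission_floor` and renormalized
#' after fitting so cross-condition scoring stays finite.
#'
#' @param ensemble A [discrete_ensemble()].
#' @param n_hidden Number of hidden states. Default `2 * K_E` (hidden:emission
#'   ratio 2:1).
#' @param restarts Number of seeded random initializations (default 5).
#' @param tol Relative log-likelihood improvement below which EM stops.
#' @param max_iter Iteration cap per restart.
#' @param seed Integer seed; identical seeds give bitwise-identical models.
#' @param emission_floor See [hmm_model()].
#' @return An `"hmm"` with extra fields `loglik` (total training log2-likelihood),
#'   `loglik_trace` (per EM iteration of the winning restart) and `n_iter`.
#' @export
fit_hmm <- function(ensemble, n_hidden = NULL, restarts = 5, tol = 1e-6,
                    max_iter = 500, seed = 1, emission_floor = 1e-6) {
  stopifnot(inherits(ensemble, "discrete_ensemble"))
  K_E <- ensemble$K_E
  if (K_E < 2) dynmi_stop("dynmi_bad_alphabet", "need an emission alphabet of >= 2 symbols")
  if (is.null(n_hidden)) n_hidden <- 2L * K_E
  if (!is_count(n_hidden) || n_hidden < 1) dynmi_stop("dynmi_bad_model", "n_hidden must be >= 1")
  states <- ensemble$states
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- list(pi = as.vector(random_stochastic(n_hidden, 1L)),
                   T = random_stochastic(n_hidden, n_hidden),
                   E = random_stochastic(K_E, n_hidden))
      fit <- baum_welch(states, K_E, init, tol = tol, max_iter = max_iter)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  E <- normalize_columns(pmax(best$E, emission_floor))
  model <- structure(list(K = as.integer(n_hidden), K_E = as.integer(K_E),
                          pi = best$pi, T = best$T, E = E,
                          emission_floor = emission_floor,
                          loglik = best$loglik, loglik_trace = best$trace,
                          n_iter = length(best$trace),
                          scheme_id = ensemble$scheme_id),
                     class = "hmm")
  model
}

## One Baum-Welch run from a given initialization. states: m x N.
## Rabiner-style scaling: alpha_hat sums to 1 per trajectory and step; with the
## matched beta_hat scaling, gamma = alpha_hat * beta_hat needs no renormalizing.
baum_welch <- function(states, K_E, init, tol, max_iter) {
  m <- nrow(states); N <- ncol(states); K <- length(init$pi)
  pi <- init$pi; T <- init$T; E <- init$E
  statesv <- as.vector(states)                       # cell index fastest, then time
  ## index of each (cell, time) observation into the flattened K x (m*N) layout
  sym_cols <- lapply(seq_len(K_E), function(s) which(statesv == s))
  trace <- numeric(0)
  ll_prev <- -Inf
  tiny <- .Machine$double.xmin
  for (iter in seq_len(max_iter)) {
    ## per-observation emission likelihood columns, K x (m*N), reused by both passes
    Eobs <- t(E)[, statesv, drop = FALSE]
    ## forward
    alpha <- array(0, c(K, m, N))
    csc <- matrix(0, m, N)                           # scaling factors c_n per trajectory
    a <- pi * Eobs[, seq_len(m), drop = FALSE]
    cn <- pmax(.colSums(a, K, m), tiny)
    a <- a * rep(1 / cn, each = K)
    alpha[, , 1L] <- a
    csc[, 1L] <- cn
    if (N >= 2L) for (n in 2:N) {
      a <- (T %*% a) * Eobs[, ((n - 1L) * m + 1L):(n * m), drop = FALSE]
      cn <- pmax(.colSums(a, K, m), tiny)
      a <- a * rep(1 / cn, each = K)
      alpha[, , n] <- a
      csc[, n] <- cn
    }
    ll <- sum(log2(csc))
    trace <- c(trace, ll)
    ## backward + accumulators; gamma posteriors collected per observation
    beta <- matrix(1, K, m)
    xi_sum <- matrix(0, K, K)
    gammas <- matrix(0, K, m * N)
    gammas[, ((N - 1L) * m + 1L):(N * m)] <- alpha[, , N]
    gamma1 <- alpha[, , N]
    if (N >= 2L) for (n in N:2) {
      Eyb <- Eobs[, ((n - 1L) * m + 1L):(n * m), drop = FALSE] * beta  # K x m
      Eyb <- Eyb * rep(1 / csc[, n], each = K)
      an1 <- alpha[, , n - 1L]
      xi_sum <- xi_sum + T * tcrossprod(Eyb, an1)
      beta <- crossprod(T, Eyb)                                 # beta_{n-1}
      g <- an1 * beta
      gammas[, ((n - 2L) * m + 1L):((n - 1L) * m)] <- g
      if (n == 2L) gamma1 <- g
    }
    ## M-step
    pi <- rowSums(gamma1) / m
    if (N >= 2L) T <- normalize_columns(xi_sum)
    E_num <- matrix(0, K_E, K)
    for (s in seq_len(K_E)) {
      idx <- sym_cols[[s]]
      if (length(idx))
        E_num[s, ] <- .rowSums(gammas[, idx, drop = FALSE], K, length(idx))
    }
    E <- normalize_columns(E_num)
    if (is.finite(ll_prev) && (ll - ll_prev) < tol * abs(ll_prev)) break
    ll_prev <- ll
  }
  list(pi = pi, T = T, E = E, loglik = ll, trace = trace)
}

#' Sample trajectories from a fitted or ground-truth model
#'
#' Ancestral sampling; seeded and reproducible.
#'
#' @param model An `"hmm"` or `"timm"` object.
#' @param n_traj Number of trajectories.
#' @param length Trajectory length (for a time-inhomogeneous model at most its
#'   fitted number of timepoints).
#' @param seed Integer seed.
#' @param condition_label Label attached to the sampled ensemble.
#' @return A [discrete_ensemble()].
#' @export
sample_model <- function(model, n_traj, length, seed = 1,
                         condition_label = "sampled") {
  UseMethod("sample_model")
}

#' @export
sample_model.hmm <- function(model, n_traj, length, seed = 1,
                             condition_label = "sampled") {
  K <- model$K
  with_seed(seed, {
    x <- matrix(0L, n_traj, length)
    y <- matrix(0L, n_traj, length)
    x[, 1L] <- sample.int(K, n_traj, replace = TRUE, prob = model$pi)
    for (n in seq_len(length)) {
      if (n > 1L) {
        for (i in seq_len(K)) {
          idx <- which(x[, n - 1L] == i)
          if (base::length(idx))
            x[idx, n] <- sample.int(K, base::length(idx), replace = TRUE, prob = model$T[, i])
        }
      }
      for (i in seq_len(K)) {
        idx <- which(x[, n] == i)
        if (base::length(idx))
          y[idx, n] <- sample.int(model$K_E, base::length(idx), replace = TRUE,
                                  prob = model$E[, i])
      }
    }
    discrete_ensemble(y, condition_label, model$K_E,
                      scheme_id = if (is.null(model$scheme_id)) "model-alphabet" else model$scheme_id)
  })
}
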