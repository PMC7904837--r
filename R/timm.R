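# Time-inhomogeneous Markov models: one column-stochastic transition matrix per
# consecutive timepoint pair, fitted by column-normalized transition counts.

#' Fit a time-inhomogeneous Markov model
#'
#' For every pair of consecutive timepoints, transitions `l -> l'` are counted
#' across cells into a count matrix (row `l'`, column `l`), a pseudocount is
#' added to every cell, and the matrix is normalized by column. The initial
#' distribution is the (pseudocounted) empirical symbol distribution at the
#' first timepoint.
#'
#' @param ensemble A [discrete_ensemble()] with at least 2 timepoints.
#' @param pseudocount Non-negative count added to every transition cell before
#'   normalization (default 0.5, Jeffreys-style). With 0, transitions never
#'   observed have probability 0 and scoring unseen steps yields `-Inf`.
#' @return An object of class `"timm"` with fields `initial` (length `K_E`) and
#'   `transitions` (`K_E x K_E x (N-1)` array; slice `n` maps timepoint `n` to `n+1`).
#' @export
fit_time_inhomogeneous <- function(ensemble, pseudocount = 0.5) {
  stopifnot(inherits(ensemble, "discrete_ensemble"))
  states <- ensemble$states
  K <- ensemble$K_E
  N <- ncol(states)
  if (N < 2L) dynmi_stop("dynmi_bad_shape", "need >= 2 timepoints")
  if (pseudocount < 0) dynmi_stop("dynmi_bad_model", "pseudocount must be >= 0")
  init <- tabulate(states[, 1L], nbins = K) + pseudocount
  if (sum(init) == 0) init <- rep(1, K)
  init <- init / sum(init)
  trans <- array(0, c(K, K, N - 1L))
  for (n in seq_len(N - 1L)) {
    counts <- matrix(pseudocount, K, K)
    tab <- table(factor(states[, n + 1L], levels = seq_len(K)),
                 factor(states[, n], levels = seq_len(K)))
    counts <- counts + as.matrix(tab)
    trans[, , n] <- normalize_columns_allow_zero(counts)
  }
  structure(list(K_E = as.integer(K), initial = init, transitions = trans,
                 N = N, pseudocount = pseudocount,
                 scheme_id = ensemble$scheme_id),
            class = "timm")
}

## Columns with zero total count (possible only at pseudocount 0) are set
## uniform: the source state was never visited in training, so any convention
## works; uniform keeps every matrix column-stochastic.
normalize_columns_allow_zero <- function(m) normalize_columns(m)

#' @export
print.timm <- function(x, ...) {
  cat(sprintf("Time-inhomogeneous Markov model: %d states, %d timepoints (%d transition matrices)\n",
              x$K_E, x$N, dim(x$transitions)[3L]))
  invisible(x)
}

## Vectorized prefix log2 probabilities for a whole ensemble (m x N).
timm_prefix_matrix <- function(model, states) {
  m <- nrow(states); N <- ncol(states)
  if (N > model$N)
    dynmi_stop("dynmi_bad_shape", "trajectories longer than the fitted model")
  if (any(states < 1L) || any(states > model$K_E))
    dynmi_stop("dynmi_bad_state", "trajectory symbol outside the model's alphabet")
  out <- matrix(NA_real_, m, N)
  lp <- log2(model$initial[states[, 1L]])
  out[, 1L] <- lp
  if (N >= 2L) for (n in 2:N) {
    p <- model$transitions[cbind(states[, n], states[, n - 1L], n - 1L)]
    lp <- lp + log2(p)
    out[, n] <- lp
  }
  if (any(!is.finite(out[, N])))
    warning("zero-probability step encountered; -Inf prefixes returned")
  out
}

#' Cumulative log2 trajectory probabilities under a time-inhomogeneous model
#'
#' `values[n] = log2[ initial(y_1) * prod_{m=2..n} p(y_m | y_{m-1}) ]`.
#' With pseudocount 0 a never-observed step makes the prefix (and all later
#' prefixes) `-Inf`, with a warning.
#'
#' @param model A `"timm"` from [fit_time_inhomogeneous()].
#' @param trajectory Integer vector of symbols in `1..K_E`, length at most the
#'   model's number of timepoints.
#' @return Numeric vector of prefix log2 probabilities.
#' @export
timm_prefix_log_probs <- function(model, trajectory) {
  stopifnot(inherits(model, "timm"))
  drop(timm_prefix_matrix(model, matrix(as.integer(trajectory), nrow = 1L)))
}

#' @export
sample_model.timm <- function(model, n_traj, length, seed = 1,
                              condition_label = "sampled") {
  if (length > model$N)
    dynmi_stop("dynmi_bad_shape", "cannot sample more timepoints than the model was fitted on")
  K <- model$K_E
  with_seed(seed, {
    y <- matrix(0L, n_traj, length)
    y[, 1L] <- sample.int(K, n_traj, replace = TRUE, prob = model$initial)
    if (length >= 2L) for (n in 2:length) {
      for (l in seq_len(K)) {
        idx <- which(y[, n - 1L] == l)
        if (base::length(idx))
          y[idx, n] <- sample.int(K, base::length(idx), replace = TRUE,
                                  prob = model$transitions[, l, n - 1L])
      }
    }
    discrete_ensemble(y, condition_label, K,
                      scheme_id = if (is.null(model$scheme_id)) "model-alphabet" else model$scheme_id)
  })
}

## Shared dispatcher used by the dMI layer: ensemble-level prefix matrix.
prefix_matrix <- function(model, states) {
  if (inherits(model, "hmm")) hmm_prefix_matrix(model, states)
  else if (inherits(model, "timm")) timm_prefix_matrix(model, states)
  else dynmi_stop("dynmi_bad_model", "model must be of class 'hmm' or 'timm'")
}

#' Cumulative log2 prefix probabilities (generic over model families)
#'
#' @param model An `"hmm"` or `"timm"` model.
#' @param trajectory Integer symbol vector.
#' @return Numeric vector of `log2 p(y_{1:n})` for `n = 1..length(trajectory)`.
#' @export
prefix_log_probs <- function(model, trajectory) {
  drop(prefix_matrix(model, matrix(as.integer(trajectory), nrow = 1L)))
}
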