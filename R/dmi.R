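# Dynamical mutual information (dMI).
#
# Given per-condition generative models and the observed discretized ensembles,
# every trajectory j of condition i is scored under every condition k's model,
# giving log2 p(y_{1:n}^{i,j} | S = k) for all prefix lengths n. The trajectory
# entropy of a single trajectory is H(y_{1:n}) = -log2 p(y_{1:n}); the
# conditional and unconditional trajectory entropies are sample averages of
# such terms under the stimulus-weight distribution q, and
#   I(R_{1:n}; S) = H(R_{1:n}) - H(R_{1:n} | S)
# is maximized over q on the probability simplex at each cumulative timepoint.

#' Trajectory entropy from a log2 probability
#'
#' `H(y_{1:n}) = -log2 p(y_{1:n})`, the entropy of a single trajectory (not an
#' ensemble average).
#'
#' @param log2_prob Log2 probability (or vector thereof), all `<= 0`.
#' @return `-log2_prob`, in bits.
#' @export
trajectory_entropy <- function(log2_prob) {
  if (any(log2_prob > 0))
    dynmi_stop("dynmi_bad_logprob", "log2 probabilities must be <= 0")
  -log2_prob
}

#' Score every condition's trajectories under every condition's model
#'
#' @param models List of `M` fitted models (all `"hmm"` or all `"timm"`, sharing
#'   one emission alphabet / discretization scheme).
#' @param ensembles List of `M` [discrete_ensemble()] objects, same order.
#' @return An object of class `"condition_scores"`: field `logp` is a list whose
#'   element `i` is an `m_i x M x N` array with entry `(j, k, n)` equal to
#'   `log2 p(y_{1:n}^{i,j} | S = k)`; plus `M`, `N` and condition `labels`.
#' @export
score_conditions <- function(models, ensembles) {
  M <- length(models)
  stopifnot(M == length(ensembles), M >= 1L)
  classes <- vapply(models, function(m) class(m)[1L], character(1))
  if (length(unique(classes)) != 1L)
    dynmi_stop("dynmi_mixed_families",
               "all conditions must use the same model family in one dMI computation")
  schemes <- c(vapply(models, function(m) as.character(m$scheme_id %||% NA), character(1)),
               vapply(ensembles, function(e) as.character(e$scheme_id %||% NA), character(1)))
  schemes <- schemes[!is.na(schemes)]
  if (length(unique(schemes)) > 1L)
    dynmi_stop("dynmi_scheme_mismatch",
               "models and ensembles must share one discretization scheme")
  K_E <- unique(vapply(models, `[[`, numeric(1), "K_E"))
  if (length(K_E) != 1L || any(vapply(ensembles, `[[`, numeric(1), "K_E") != K_E))
    dynmi_stop("dynmi_scheme_mismatch", "all models and ensembles must share K_E")
  N <- unique(vapply(ensembles, function(e) ncol(e$states), numeric(1)))
  if (length(N) != 1L)
    dynmi_stop("dynmi_bad_shape", "all ensembles must have the same number of timepoints")
  logp <- lapply(seq_len(M), function(i) {
    m_i <- nrow(ensembles[[i]]$states)
    arr <- array(NA_real_, c(m_i, M, N))
    for (k in seq_len(M))
      arr[, k, ] <- prefix_matrix(models[[k]], ensembles[[i]]$states)
    arr
  })
  structure(list(logp = logp, M = M, N = N,
                 labels = vapply(ensembles, `[[`, character(1), "condition_label")),
            class = "condition_scores")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.condition_scores <- function(x, ...) {
  cat(sprintf("Condition scores: %d conditions x %d timepoints (%s trajectories)\n",
              x$M, x$N, paste(vapply(x$logp, nrow, numeric(1)), collapse = "/")))
  invisible(x)
}

check_weights <- function(q, M) {
  if (length(q) != M || any(q < 0) || abs(sum(q) - 1) > 1e-10)
    dynmi_stop("dynmi_bad_weights",
               "stimulus weights must be a length-M probability vector")
  q
}

## Extract, for timepoint n, the list of m_i x M log2-score matrices.
score_slice <- function(scores, n) {
  if (!is_count(n) || n < 1 || n > scores$N)
    dynmi_stop("dynmi_bad_shape", sprintf("timepoint n must be in 1..%d", scores$N))
  lapply(scores$logp, function(a) matrix(a[, , n], nrow = dim(a)[1L], ncol = dim(a)[2L]))
}

#' Conditional trajectory entropy
#'
#' `H(R_{1:n} | S) = -sum_i q_i (1/m_i) sum_j log2 p(y_{1:n}^{i,j} | S = i)`:
#' each condition's mean self-model trajectory entropy, weighted by q.
#'
#' @param scores A [score_conditions()] result.
#' @param q Stimulus weights (length `M`, non-negative, summing to 1).
#' @param n Cumulative timepoint.
#' @return Entropy in bits.
#' @export
conditional_entropy <- function(scores, q, n) {
  q <- check_weights(q, scores$M)
  L <- score_slice(scores, n)
  diag_means <- vapply(seq_len(scores$M), function(i) mean(L[[i]][, i]), numeric(1))
  -sum(q * diag_means)
}

#' Unconditional trajectory entropy
#'
#' `H(R_{1:n}) = -sum_i q_i (1/m_i) sum_j log2 [ sum_k q_k p(y_{1:n}^{i,j} | S = k) ]`.
#' The inner mixture over conditions is computed by log-sum-exp from the
#' log-domain scores (no underflow for long trajectories); terms with `q_k = 0`
#' are dropped exactly.
#'
#' @inheritParams conditional_entropy
#' @return Entropy in bits.
#' @export
unconditional_entropy <- function(scores, q, n) {
  q <- check_weights(q, scores$M)
  L <- score_slice(scores, n)
  -sum(q * vapply(seq_len(scores$M), function(i) mean(mixture_log2(L[[i]], q)), numeric(1)))
}

## Per-trajectory log2 of sum_k q_k 2^L[, k], with q_k = 0 columns dropped.
mixture_log2 <- function(L, q) {
  keep <- q > 0
  row_lse2(sweep(L[, keep, drop = FALSE], 2L, log2(q[keep]), "+"))
}

#' Dynamical mutual information at a cumulative timepoint
#'
#' `I(R_{1:n}; S) = H(R_{1:n}) - H(R_{1:n} | S)`. Finite-sample estimates can
#' dip microscopically below zero; values are clipped at 0 and a warning is
#' emitted if the raw value is below `-1e-9` bits.
#'
#' @inheritParams conditional_entropy
#' @return Mutual information in bits, `>= 0`.
#' @export
dmi <- function(scores, q, n) {
  q <- check_weights(q, scores$M)
  L <- score_slice(scores, n)
  val <- dmi_value(L, q)
  if (val < -1e-9)
    warning(sprintf("dMI estimate %.3g bits clipped to 0", val))
  max(0, val)
}

## I(q) = sum_i q_i * mean_j [ L[i][j,i] - log2 sum_k q_k 2^L[i][j,k] ]
dmi_value <- function(L, q) {
  sum(vapply(seq_along(L), function(i) {
    if (q[i] == 0) return(0)
    q[i] * mean(L[[i]][, i] - mixture_log2(L[[i]], q))
  }, numeric(1)))
}

## Gradient of dmi_value wrt q (ignoring the simplex constraint):
## dI/dq_a = mean_j(L[a][j,a] - log2 mix_aj)
##           - (1/ln 2) * sum_i q_i mean_j 2^(L[i][j,a] - log2 mix_ij)
dmi_gradient <- function(L, q) {
  M <- length(L)
  mixes <- lapply(seq_len(M), function(i) mixture_log2(L[[i]], q))
  direct <- vapply(seq_len(M), function(a) mean(L[[a]][, a] - mixes[[a]]), numeric(1))
  coupling <- numeric(M)
  for (i in seq_len(M)) {
    if (q[i] == 0) next
    w <- 2^(L[[i]] - mixes[[i]])   # m_i x M, ratios p_ija / mix_ij
    coupling <- coupling + q[i] * colMeans(w)
  }
  direct - coupling / log(2)
}

## Euclidean projection of a vector onto the probability simplex.
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  pmax(v + (1 - css[rho]) / rho, 0)
}

## Projected-gradient ascent with backtracking line search on the simplex.
## `objective`/`gradient` are closures of q. Concave objectives only.
simplex_maximize <- function(objective, gradient, M, q0 = rep(1 / M, M),
                             tol = 1e-6, max_iter = 10000) {
  q <- q0 / sum(q0)
  f <- objective(q)
  step <- 1
  for (it in seq_len(max_iter)) {
    g <- gradient(q)
    s <- step
    q_new <- q; f_new <- f; improved <- FALSE
    while (s >= 1e-14) {
      cand <- project_simplex(q + s * g)
      fc <- objective(cand)
      if (fc > f_new) { q_new <- cand; f_new <- fc; improved <- TRUE; break }
      s <- s / 2
    }
    if (!improved)  # projected gradient gives no ascent: at the maximum
      return(list(value = f, q = q, iterations = it, converged = TRUE))
    delta <- f_new - f
    q <- q_new; f <- f_new
    step <- min(s * 4, 1e4)
    if (delta < tol)
      return(list(value = f, q = q, iterations = it, converged = TRUE))
  }
  cond <- errorCondition(
    sprintf("simplex maximization did not converge in %d iterations", max_iter),
    best = list(value = f, q = q),
    class = c("dynmi_no_convergence", "dynmi_error", "error", "condition"))
  stop(cond)
}

#' Maximize the dMI over the stimulus-weight distribution
#'
#' Maximizes the concave map `q -> I(R_{1:n}; S)` over the probability simplex
#' (`sum q_i = 1`, `q_i >= 0`) by projected-gradient ascent with backtracking.
#' The maximum dMI bounds how well the `M` conditions can be distinguished from
#' the cumulative response up to timepoint `n` and approximates the channel
#' capacity of the supplied condition set.
#'
#' @inheritParams conditional_entropy
#' @param tol Convergence tolerance in bits (default `1e-6`).
#' @param max_iter Iteration cap; exceeding it raises an error carrying the best
#'   iterate in its condition.
#' @return List with `value` (I_max, bits), `q` (the optimal weights),
#'   `iterations`, `converged`.
#' @export
maximize_dmi <- function(scores, n, tol = 1e-6, max_iter = 10000) {
  if (scores$M < 2)
    dynmi_stop("dynmi_bad_shape", "mutual information needs M >= 2 conditions")
  L <- score_slice(scores, n)
  res <- simplex_maximize(function(q) dmi_value(L, q),
                          function(q) dmi_gradient(L, q),
                          scores$M, tol = tol, max_iter = max_iter)
  res$value <- max(0, res$value)
  res
}

#' Cumulative maximum-dMI curve
#'
#' Scores all conditions once, then maximizes the dMI over the stimulus weights
#' independently at every cumulative timepoint `n = 1..N`; the uniform-weight
#' dMI curve is recorded alongside. The curve need not be monotone in `n`:
#' conditions can transiently converge in their dynamics.
#'
#' @param models,ensembles As in [score_conditions()], or a precomputed
#'   `"condition_scores"` object passed as `models` (with `ensembles` missing).
#' @param tol,max_iter Optimizer settings, see [maximize_dmi()].
#' @return An object of class `"dmi_curve"`: data frame `curve` with columns
#'   `timepoint`, `max_dmi`, `uniform_dmi` and one `q_<label>` column per
#'   condition, plus fields `M` and `labels`.
#' @export
dmi_curve <- function(models, ensembles, tol = 1e-6, max_iter = 10000) {
  scores <- if (inherits(models, "condition_scores")) models
            else score_conditions(models, ensembles)
  M <- scores$M
  uq <- rep(1 / M, M)
  rows <- lapply(seq_len(scores$N), function(n) {
    opt <- maximize_dmi(scores, n, tol = tol, max_iter = max_iter)
    c(timepoint = n, max_dmi = opt$value,
      uniform_dmi = max(0, dmi_value(score_slice(scores, n), uq)), opt$q)
  })
  curve <- as.data.frame(do.call(rbind, rows))
  names(curve) <- c("timepoint", "max_dmi", "uniform_dmi",
                    paste0("q_", scores$labels))
  structure(list(curve = curve, M = M, labels = scores$labels),
            class = "dmi_curve")
}

#' @export
print.dmi_curve <- function(x, ...) {
  n <- nrow(x$curve)
  cat(sprintf("dMI curve over %d conditions, %d timepoints; final max dMI = %.3f bits (ceiling log2 M = %.3f)\n",
              x$M, n, x$curve$max_dmi[n], log2(x$M)))
  invisible(x)
}

#' Serialize a dMI curve as delimited text
#'
#' Writes the curve as a TSV (`timepoint`, `max_dmi`, `uniform_dmi`, weight
#' columns) plus a YAML metadata sidecar (`<path>.meta.yaml`) when `metadata`
#' is supplied.
#'
#' @param x A `"dmi_curve"`.
#' @param path Output TSV path.
#' @param metadata Optional named list (seed, state counts, tolerances, ...).
#' @return `path`, invisibly.
#' @export
write_dmi_curve <- function(x, path, metadata = NULL) {
  stopifnot(inherits(x, "dmi_curve"))
  utils::write.table(x$curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata))
    yaml::write_yaml(metadata, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Randomly permute timepoints, identically across conditions
#'
#' Applies one seeded random permutation of the column indices to every
#' ensemble. Trajectory information carried by the temporal ordering is
#' destroyed while per-column marginals are preserved; a drop of the dMI after
#' permutation shows that the genuine ordering of timepoints carries stimulus
#' information.
#'
#' @param ensembles List of [trajectory_ensemble()] or [discrete_ensemble()]
#'   objects sharing the same number of timepoints.
#' @param seed Integer seed.
#' @return List with `ensembles` (permuted, same classes) and `permutation`
#'   (the column order applied).
#' @export
permute_timepoints <- function(ensembles, seed = 1) {
  mat_name <- function(e) if (inherits(e, "discrete_ensemble")) "states" else "values"
  Ns <- vapply(ensembles, function(e) ncol(e[[mat_name(e)]]), numeric(1))
  if (length(unique(Ns)) != 1L)
    dynmi_stop("dynmi_bad_shape", "all ensembles must share the number of timepoints")
  N <- Ns[[1L]]
  perm <- with_seed(seed, sample.int(N))
  out <- lapply(ensembles, function(e) {
    nm <- mat_name(e)
    e[[nm]] <- e[[nm]][, perm, drop = FALSE]
    e
  })
  list(ensembles = out, permutation = perm)
}

#' Single-timepoint mutual information baseline
#'
#' The classical timepoint method: per-condition empirical symbol distributions
#' at column `n` (pseudocount added to every symbol) define a discrete
#' memoryless channel whose mutual information is maximized over the stimulus
#' weights with the same simplex optimizer as [maximize_dmi()]. Ignores all
#' trajectory (ordering) information.
#'
#' @param ensembles List of [discrete_ensemble()] objects on a shared alphabet.
#' @param n Timepoint (column index).
#' @param pseudocount Added to every symbol count before normalization.
#' @param tol,max_iter Optimizer settings.
#' @return List with `value` (I_max, bits) and `q` (optimal weights).
#' @export
timepoint_mi <- function(ensembles, n, pseudocount = 0.5, tol = 1e-6,
                         max_iter = 10000) {
  K_E <- unique(vapply(ensembles, `[[`, numeric(1), "K_E"))
  if (length(K_E) != 1L)
    dynmi_stop("dynmi_scheme_mismatch", "ensembles must share one alphabet")
  P <- vapply(ensembles, function(e) {
    cnt <- tabulate(e$states[, n], nbins = K_E) + pseudocount
    cnt / sum(cnt)
  }, numeric(K_E))
  res <- channel_capacity(P, tol = tol, max_iter = max_iter)
  res$value <- max(0, res$value)
  res
}

#' Capacity of a discrete memoryless channel
#'
#' Maximizes `I(q) = sum_i q_i sum_y P[y,i] log2(P[y,i] / sum_k q_k P[y,k])`
#' over input weights `q` on the simplex.
#'
#' @param P Column-stochastic matrix; column `i` is the output distribution for
#'   input `i`.
#' @param tol,max_iter Optimizer settings.
#' @return List with `value` (bits), `q`, `iterations`, `converged`.
#' @export
channel_capacity <- function(P, tol = 1e-6, max_iter = 10000) {
  P <- as.matrix(P)
  check_stochastic(P, "P")
  M <- ncol(P)
  plogp <- colSums(ifelse(P > 0, P * log2(P), 0))
  value <- function(q) {
    mix <- as.vector(P %*% q)
    pos <- P > 0
    sum(q * (plogp - colSums(ifelse(pos, P * log2(pmax(mix, .Machine$double.xmin)), 0))))
  }
  grad <- function(q) {
    mix <- pmax(as.vector(P %*% q), .Machine$double.xmin)
    d <- plogp - colSums(P * log2(mix))
    d - 1 / log(2)
  }
  simplex_maximize(value, grad, M, tol = tol, max_iter = max_iter)
}
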