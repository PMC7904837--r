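# Independent oracles and small fixtures. Everything here is deliberately
# brute-force and written without reusing the package's recursions, so the
# tests cross-check two independent routes to the same quantity.

## Random column-stochastic matrix built with plain base R.
rand_stoch <- function(nr, nc) {
  m <- matrix(runif(nr * nc) + 1e-3, nr, nc)
  sweep(m, 2, colSums(m), "/")
}

make_random_hmm <- function(K, K_E, seed, emission_floor = 0) {
  set.seed(seed)
  hmm_model(pi = as.vector(rand_stoch(K, 1)),
            T = rand_stoch(K, K),
            E = rand_stoch(K_E, K),
            emission_floor = emission_floor)
}

## Joint probability of an observed sequence by exhaustive enumeration of all
## K^n hidden paths: sum over paths of pi(x1) E(y1|x1) prod T(x_t|x_{t-1}) E(y_t|x_t).
enum_sequence_prob <- function(model, y) {
  n <- length(y)
  K <- model$K
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    x <- paths[r, ]
    p <- model$pi[x[1]] * model$E[y[1], x[1]]
    if (n >= 2) for (t in 2:n) p <- p * model$T[x[t], x[t - 1]] * model$E[y[t], x[t]]
    total <- total + p
  }
  total
}

## Sequence probability under a time-inhomogeneous Markov model (plain product).
timm_sequence_prob <- function(model, y) {
  p <- model$initial[y[1]]
  if (length(y) >= 2) for (t in 2:length(y))
    p <- p * model$transitions[y[t], y[t - 1], t - 1]
  p
}

model_sequence_prob <- function(model, y) {
  if (inherits(model, "hmm")) enum_sequence_prob(model, y) else timm_sequence_prob(model, y)
}

## Brute-force dMI at prefix length n: per-trajectory probabilities by
## enumeration, then the conditional / unconditional trajectory entropies and
## their difference, all written directly from the defining sums.
brute_force_dmi <- function(models, ensembles, q, n) {
  M <- length(models)
  logp <- lapply(seq_len(M), function(i) {
    st <- ensembles[[i]]$states[, seq_len(n), drop = FALSE]
    t(apply(st, 1, function(y)
      vapply(models, function(mod) log2(model_sequence_prob(mod, y)), numeric(1))))
  })
  h_cond <- -sum(vapply(seq_len(M), function(i) q[i] * mean(logp[[i]][, i]), numeric(1)))
  h_unc <- -sum(vapply(seq_len(M), function(i) {
    mix <- log2(as.vector(2^logp[[i]] %*% q))
    q[i] * mean(mix)
  }, numeric(1)))
  h_unc - h_cond
}

## All symbol sequences of length n over 1..K_E (rows).
all_sequences <- function(K_E, n) {
  as.matrix(expand.grid(rep(list(seq_len(K_E)), n)))
}

## Dense grid search over the 2-simplex for the maximum dMI of a two-condition
## score set at timepoint n; `value_fn(q)` evaluates the objective.
grid_max_2 <- function(value_fn, step = 1e-3) {
  grid <- seq(0, 1, by = step)
  vals <- vapply(grid, function(a) value_fn(c(a, 1 - a)), numeric(1))
  list(value = max(vals), q1 = grid[which.max(vals)])
}

## Exact mutual information of a discrete memoryless channel at weights q.
channel_mi <- function(P, q) {
  mix <- as.vector(P %*% q)
  sum(vapply(which(q > 0), function(i) {
    pos <- P[, i] > 0
    q[i] * sum(P[pos, i] * (log2(P[pos, i]) - log2(mix[pos])))
  }, numeric(1)))
}

## Small discrete ensemble straight from a state matrix.
mk_densemble <- function(states, K_E, label = "cond", scheme = "shared") {
  discrete_ensemble(states, label, K_E, scheme)
}

## Synthetic condition_scores object with hand-set log2 scores.
## logp_list[[i]] is an m_i x M x N array.
mk_scores <- function(logp_list, labels = paste0("c", seq_along(logp_list))) {
  structure(list(logp = logp_list, M = length(logp_list),
                 N = dim(logp_list[[1]])[3], labels = labels),
            class = "condition_scores")
}
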