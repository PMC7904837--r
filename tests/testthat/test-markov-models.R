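# Model fitting and trajectory-probability machinery, cross-checked against
# brute-force enumeration oracles.

test_that("time-inhomogeneous fit reproduces hand-computed column normalizations", {
  # all trajectories go 1 -> 2 at the first step
  d <- mk_densemble(rbind(c(1, 2, 1), c(1, 2, 2), c(1, 2, 1)), K_E = 2)
  m0 <- fit_time_inhomogeneous(d, pseudocount = 0)
  expect_equal(m0$transitions[2, 1, 1], 1)
  # a column with counts (3, 1) normalizes to (0.75, 0.25)
  d2 <- mk_densemble(cbind(rep(1, 4), c(1, 1, 1, 2)), K_E = 2)
  m2 <- fit_time_inhomogeneous(d2, pseudocount = 0)
  expect_equal(m2$transitions[, 1, 1], c(0.75, 0.25))
  # a never-visited source state gets a uniform column under a pseudocount
  m3 <- fit_time_inhomogeneous(d2, pseudocount = 0.5)
  expect_equal(m3$transitions[, 2, 1], c(0.5, 0.5))
  expect_true(all(abs(apply(m3$transitions, 3, colSums) - 1) < 1e-12))
})

test_that("Markov prefix log-probabilities match direct products of matrix entries", {
  # deterministic chain scores its own trajectory at probability 1
  d <- mk_densemble(matrix(rep(c(1, 2, 1, 2), 3), 3, 4, byrow = TRUE), K_E = 2)
  m <- fit_time_inhomogeneous(d, pseudocount = 0)
  expect_equal(timm_prefix_log_probs(m, c(1, 2, 1, 2)), rep(0, 4))
  # uniform model: -n bits for any trajectory
  du <- mk_densemble(rbind(c(1, 1, 1), c(1, 2, 2), c(2, 1, 2), c(2, 2, 1),
                           c(1, 1, 2), c(1, 2, 1), c(2, 1, 1), c(2, 2, 2)), K_E = 2)
  mu <- fit_time_inhomogeneous(du, pseudocount = 0)
  expect_equal(timm_prefix_log_probs(mu, c(1, 2, 2)), -(1:3))
  # random 3-state model: prefix values equal looked-up entry products
  set.seed(7)
  dr <- mk_densemble(matrix(sample.int(3, 60, replace = TRUE), 15, 4), K_E = 3)
  mr <- fit_time_inhomogeneous(dr, pseudocount = 0.5)
  y <- c(2, 3, 1, 3)
  expect_equal(timm_prefix_log_probs(mr, y),
               log2(cumprod(c(mr$initial[2],
                              mr$transitions[3, 2, 1],
                              mr$transitions[1, 3, 2],
                              mr$transitions[3, 1, 3]))))
})

test_that("an unseen step at pseudocount 0 yields -Inf prefixes with a warning", {
  d <- mk_densemble(rbind(c(1, 1), c(1, 1)), K_E = 2)
  m <- fit_time_inhomogeneous(d, pseudocount = 0)
  expect_warning(lp <- timm_prefix_log_probs(m, c(1, 2)), "zero-probability")
  expect_equal(lp[2], -Inf)
})

test_that("forward algorithm agrees with exhaustive hidden-path enumeration", {
  for (seed in 1:6) {
    K <- 1 + seed %% 3          # 1..3 hidden states
    K_E <- 2 + seed %% 2        # 2..3 symbols
    n <- 3 + seed %% 4          # lengths 3..6
    model <- make_random_hmm(K, K_E, seed = 100 + seed)
    set.seed(seed)
    y <- sample.int(K_E, n, replace = TRUE)
    lp <- forward_prefix_log_probs(model, y)
    for (m in seq_len(n))
      expect_equal(lp[m], log2(enum_sequence_prob(model, y[seq_len(m)])),
                   tolerance = 1e-12)
  }
})

test_that("forward recursion handles the degenerate corners", {
  # K = 1: prefix values are running sums of emission log-probabilities
  m1 <- make_random_hmm(1, 3, seed = 5)
  y <- c(2, 1, 3, 3)
  expect_equal(forward_prefix_log_probs(m1, y), cumsum(log2(m1$E[y, 1])))
  # deterministic single-path model scores its own output at probability 1
  md <- hmm_model(pi = c(1, 0), T = diag(2), E = matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(forward_prefix_log_probs(md, c(1, 1, 1)), rep(0, 3))
  expect_error(forward_prefix_log_probs(md, c(1, 3)), class = "dynmi_bad_state")
})

test_that("model-assigned probabilities over all sequences sum to one", {
  model <- make_random_hmm(3, 3, seed = 21)
  seqs <- all_sequences(3, 4)
  tot_h <- sum(apply(seqs, 1, function(y) 2^forward_prefix_log_probs(model, y)[4]))
  expect_equal(tot_h, 1, tolerance = 1e-8)
  set.seed(22)
  d <- mk_densemble(matrix(sample.int(2, 40, replace = TRUE), 10, 4), K_E = 2)
  timm <- fit_time_inhomogeneous(d, pseudocount = 0.5)
  seqs2 <- all_sequences(2, 4)
  tot_t <- sum(apply(seqs2, 1, function(y) 2^timm_prefix_log_probs(timm, y)[4]))
  expect_equal(tot_t, 1, tolerance = 1e-8)
})

test_that("prefix log-probabilities are non-positive and non-increasing", {
  model <- make_random_hmm(2, 4, seed = 31)
  set.seed(31)
  for (r in 1:20) {
    y <- sample.int(4, 12, replace = TRUE)
    lp <- forward_prefix_log_probs(model, y)
    expect_true(all(lp <= 1e-12))
    expect_true(all(diff(lp) <= 1e-12))
  }
})

test_that("Baum-Welch is deterministic under a seed and monotone in likelihood", {
  set.seed(41)
  d <- mk_densemble(matrix(sample.int(3, 200, replace = TRUE), 20, 10), K_E = 3)
  f1 <- fit_hmm(d, n_hidden = 2, restarts = 3, seed = 9)
  f2 <- fit_hmm(d, n_hidden = 2, restarts = 3, seed = 9)
  expect_identical(f1$T, f2$T)
  expect_identical(f1$E, f2$E)
  expect_identical(f1$pi, f2$pi)
  expect_true(all(diff(f1$loglik_trace) >= -1e-9))
})

test_that("emission flooring keeps never-observed symbols scoreable", {
  set.seed(43)
  st <- matrix(sample.int(2, 100, replace = TRUE), 10, 10)  # symbol 3 never occurs
  d <- mk_densemble(st, K_E = 3)
  f <- fit_hmm(d, n_hidden = 2, restarts = 2, seed = 3, emission_floor = 1e-6)
  expect_true(all(f$E[3, ] > 0))
  expect_equal(unname(f$E[3, ]), rep(1e-6, 2), tolerance = 1e-3)
  lp <- forward_prefix_log_probs(f, c(3, 3))
  expect_true(all(is.finite(lp)))
})

test_that("likelihood is invariant under relabeling the hidden states", {
  m <- make_random_hmm(3, 3, seed = 51)
  perm <- c(3, 1, 2)
  m2 <- hmm_model(m$pi[perm], m$T[perm, perm], m$E[, perm])
  set.seed(51)
  y <- sample.int(3, 8, replace = TRUE)
  expect_equal(forward_prefix_log_probs(m, y), forward_prefix_log_probs(m2, y),
               tolerance = 1e-12)
})

test_that("sampling reproduces a model's analytic single-timepoint marginals", {
  model <- make_random_hmm(3, 4, seed = 61)
  e <- sample_model(model, n_traj = 10000, length = 6, seed = 62)
  e2 <- sample_model(model, n_traj = 10000, length = 6, seed = 62)
  expect_identical(e$states, e2$states)
  # analytic marginal at timepoint n: E %*% T^(n-1) %*% pi
  hid <- model$pi
  for (n in 1:6) {
    if (n > 1) hid <- model$T %*% hid
    marg <- as.vector(model$E %*% hid)
    emp <- tabulate(e$states[, n], 4) / 10000
    expect_lt(sum(abs(emp - marg)) / 2, 0.02)
  }
  # deterministic model: every sampled trajectory identical
  md <- hmm_model(pi = c(1, 0), T = matrix(c(0, 1, 1, 0), 2, 2),
                  E = matrix(c(1, 0, 0, 1), 2, 2))
  ed <- sample_model(md, 5, 4, seed = 1)
  expect_true(all(apply(ed$states, 2, function(col) length(unique(col)) == 1)))
  expect_equal(ed$states[1, ], c(1L, 2L, 1L, 2L))
})

test_that("Markov-model sampling matches its fitted marginals and respects length caps", {
  set.seed(71)
  d <- mk_densemble(matrix(sample.int(2, 400, replace = TRUE), 40, 10), K_E = 2)
  m <- fit_time_inhomogeneous(d, pseudocount = 0.5)
  s <- sample_model(m, 5000, 10, seed = 72)
  expect_lt(sum(abs(tabulate(s$states[, 1], 2) / 5000 - m$initial)) / 2, 0.03)
  expect_error(sample_model(m, 5, 11, seed = 1), class = "dynmi_bad_shape")
})
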