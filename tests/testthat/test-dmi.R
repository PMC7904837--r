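# Trajectory entropies, dMI, simplex maximization and the baselines.

test_that("trajectory entropy is the negated log2 probability", {
  expect_equal(trajectory_entropy(log2(1)), 0)
  expect_equal(trajectory_entropy(log2(0.5)), 1)
  expect_equal(trajectory_entropy(-10), 10)
  expect_equal(trajectory_entropy(c(0, -2)), c(0, 2))
  expect_error(trajectory_entropy(0.1), class = "dynmi_bad_logprob")
})

test_that("score_conditions fills the trajectory-by-model-by-time array correctly", {
  models <- lapply(1:2, function(i) {
    m <- make_random_hmm(2, 3, seed = i)
    m$scheme_id <- "shared"
    m
  })
  set.seed(9)
  ens <- lapply(1:2, function(i)
    mk_densemble(matrix(sample.int(3, 12, replace = TRUE), 4, 3),
                 K_E = 3, label = paste0("c", i)))
  sc <- score_conditions(models, ens)
  expect_equal(sc$M, 2); expect_equal(sc$N, 3)
  for (i in 1:2) for (k in 1:2) for (j in 1:4) for (n in 1:3)
    expect_equal(sc$logp[[i]][j, k, n],
                 log2(enum_sequence_prob(models[[k]], ens[[i]]$states[j, seq_len(n)])),
                 tolerance = 1e-10)
})

test_that("cross-condition scoring rejects mismatched schemes and mixed families", {
  m1 <- make_random_hmm(2, 3, seed = 1); m1$scheme_id <- "A"
  m2 <- make_random_hmm(2, 3, seed = 2); m2$scheme_id <- "B"
  e1 <- mk_densemble(matrix(1L, 2, 3), 3, "c1", scheme = "A")
  e2 <- mk_densemble(matrix(2L, 2, 3), 3, "c2", scheme = "B")
  expect_error(score_conditions(list(m1, m2), list(e1, e2)),
               class = "dynmi_scheme_mismatch")
  d <- mk_densemble(rbind(c(1, 2, 1), c(2, 1, 2)), 3, scheme = "A")
  timm <- fit_time_inhomogeneous(d); timm$scheme_id <- "A"
  expect_error(score_conditions(list(m1, timm), list(e1, e1)),
               class = "dynmi_mixed_families")
})

test_that("conditional and unconditional entropies reproduce hand-evaluated sums", {
  # hand-set scores: 2 conditions, 2 trajectories each, 1 timepoint
  L1 <- array(c(-1, -2, -4, -5), c(2, 2, 1))   # cond 1: self scores -1,-2; cross -4,-5
  L2 <- array(c(-6, -3, -2, -1), c(2, 2, 1))   # cond 2: cross -6,-3; self -2,-1
  sc <- mk_scores(list(L1, L2))
  q <- c(0.5, 0.5)
  expect_equal(conditional_entropy(sc, q, 1), -(0.5 * mean(c(-1, -2)) + 0.5 * mean(c(-2, -1))))
  mix1 <- log2(0.5 * 2^c(-1, -2) + 0.5 * 2^c(-4, -5))
  mix2 <- log2(0.5 * 2^c(-6, -3) + 0.5 * 2^c(-2, -1))
  expect_equal(unconditional_entropy(sc, q, 1), -(0.5 * mean(mix1) + 0.5 * mean(mix2)))
  expect_equal(dmi(sc, q, 1),
               unconditional_entropy(sc, q, 1) - conditional_entropy(sc, q, 1))
  # degenerate weights reduce to condition 1's own mean trajectory entropy
  expect_equal(conditional_entropy(sc, c(1, 0), 1), 1.5)
  expect_equal(unconditional_entropy(sc, c(1, 0), 1), 1.5)
  # uniform binary self-scores of -n give H = n for any q
  Ln <- array(rep(-3, 8), c(2, 2, 3)); Ln[, , 1] <- -1; Ln[, , 2] <- -2
  scn <- mk_scores(list(Ln, Ln))
  for (n in 1:3) expect_equal(conditional_entropy(scn, c(0.3, 0.7), n), n)
})

test_that("identical models across conditions give zero dMI", {
  m <- make_random_hmm(2, 3, seed = 4); m$scheme_id <- "s"
  set.seed(5)
  ens <- lapply(1:2, function(i)
    mk_densemble(matrix(sample.int(3, 30, replace = TRUE), 10, 3), 3,
                 paste0("c", i), scheme = "s"))
  sc <- score_conditions(list(m, m), ens)
  for (n in 1:3) {
    expect_equal(dmi(sc, c(0.5, 0.5), n), 0, tolerance = 1e-9)
    expect_equal(unconditional_entropy(sc, c(0.4, 0.6), n),
                 conditional_entropy(sc, c(0.4, 0.6), n), tolerance = 1e-12)
  }
})

test_that("disjoint deterministic conditions carry exactly one bit at every prefix", {
  mk_det <- function(sym) {
    m <- hmm_model(pi = 1, T = matrix(1), E = {
      E <- matrix(1e-9, 2, 1); E[sym, ] <- 1 - 1e-9; E
    })
    m$scheme_id <- "s"; m
  }
  models <- list(mk_det(1), mk_det(2))
  ens <- list(mk_densemble(matrix(1L, 5, 4), 2, "a", "s"),
              mk_densemble(matrix(2L, 5, 4), 2, "b", "s"))
  sc <- score_conditions(models, ens)
  for (n in 1:4) expect_equal(dmi(sc, c(0.5, 0.5), n), 1, tolerance = 1e-6)
})

test_that("full dMI pipeline equals brute-force sequence enumeration", {
  for (seed in 1:4) {
    K <- 1 + seed %% 3; K_E <- 2 + seed %% 2; n <- 2 + seed %% 3
    models <- lapply(1:2, function(i) {
      m <- make_random_hmm(K, K_E, seed = 10 * seed + i); m$scheme_id <- "s"; m
    })
    set.seed(seed)
    ens <- lapply(1:2, function(i)
      mk_densemble(matrix(sample.int(K_E, 5 * n, replace = TRUE), 5, n), K_E,
                   paste0("c", i), "s"))
    sc <- score_conditions(models, ens)
    q <- c(0.3, 0.7)
    # the ensembles are not draws from the models, so the sample-based
    # estimate may be genuinely negative; both routes clip at 0
    expect_equal(suppressWarnings(dmi(sc, q, n)),
                 max(0, brute_force_dmi(models, ens, q, n)),
                 tolerance = 1e-8)
  }
})

test_that("dMI is invariant under a common relabeling of emission symbols", {
  K_E <- 3
  perm <- c(3, 1, 2)
  models <- lapply(1:2, function(i) {
    m <- make_random_hmm(2, K_E, seed = 70 + i); m$scheme_id <- "s"; m
  })
  set.seed(77)
  ens <- lapply(1:2, function(i)
    mk_densemble(matrix(sample.int(K_E, 40, replace = TRUE), 10, 4), K_E,
                 paste0("c", i), "s"))
  relab_models <- lapply(models, function(m) {
    m2 <- hmm_model(m$pi, m$T, m$E[order(perm), ]); m2$scheme_id <- "s"; m2
  })
  relab_ens <- lapply(ens, function(e) {
    e$states <- matrix(perm[e$states], nrow(e$states)); e
  })
  sc <- score_conditions(models, ens)
  sc2 <- score_conditions(relab_models, relab_ens)
  for (n in c(1, 4))
    expect_equal(maximize_dmi(sc, n)$value, maximize_dmi(sc2, n)$value, tolerance = 1e-9)
})

test_that("the simplex optimizer matches a dense grid search and closed forms", {
  # asymmetric single-timepoint channel with closed-form capacity:
  # p(y|1) = (1, 0), p(y|2) = (0.5, 0.5) has capacity log2(5/4)
  P <- cbind(c(1, 0), c(0.5, 0.5))
  res <- channel_capacity(P)
  expect_equal(res$value, log2(5 / 4), tolerance = 1e-4)
  g <- grid_max_2(function(q) channel_mi(P, q))
  expect_equal(res$value, g$value, tolerance = 1e-3)
  # random sample-based score instances, M = 2
  for (seed in 1:6) {
    set.seed(seed)
    L <- lapply(1:2, function(i) array(-abs(matrix(rnorm(8, 3, 2), 4, 2)), c(4, 2, 1)))
    L[[1]][, 1, ] <- L[[1]][, 1, ] / 4   # make self-scores higher
    L[[2]][, 2, ] <- L[[2]][, 2, ] / 4
    sc <- mk_scores(L)
    opt <- maximize_dmi(sc, 1)
    g <- grid_max_2(function(q) suppressWarnings(dmi(sc, q, 1)))
    expect_equal(opt$value, g$value, tolerance = 1e-3)
    expect_lte(opt$value, 1 + 1e-9)                       # log2 M bound
    expect_gte(opt$value, suppressWarnings(dmi(sc, c(0.5, 0.5), 1)) - 1e-9)
    # concavity: optimum dominates random simplex points
    qs <- matrix(rexp(2 * 1000), 1000, 2)
    qs <- qs / rowSums(qs)
    vals <- apply(qs, 1, function(q) suppressWarnings(dmi(sc, q, 1)))
    expect_gte(opt$value, max(vals) - 1e-6)
  }
})

test_that("symmetric two-condition instances are maximized at uniform weights", {
  L1 <- array(c(-1, -1, -5, -5), c(2, 2, 1))
  L2 <- array(c(-5, -5, -1, -1), c(2, 2, 1))   # mirror image of condition 1
  sc <- mk_scores(list(L1, L2))
  opt <- maximize_dmi(sc, 1)
  expect_equal(opt$q, c(0.5, 0.5), tolerance = 1e-4)
  expect_equal(opt$value, dmi(sc, c(0.5, 0.5), 1), tolerance = 1e-9)
})

test_that("dMI curves respect the information bounds at every timepoint", {
  spec <- toy_spec(M = 2, K = 2, K_E = 4, separation = 0.6, n_traj = 60,
                   length = 10, seed = 12)
  toy <- generate_toy_hmm_ensembles(spec)
  models <- lapply(toy$ensembles, fit_time_inhomogeneous)
  cv <- dmi_curve(models, toy$ensembles)
  expect_equal(nrow(cv$curve), 10)
  expect_true(all(cv$curve$max_dmi >= 0))
  expect_true(all(cv$curve$max_dmi <= log2(2) + 1e-9))
  expect_true(all(cv$curve$max_dmi >= cv$curve$uniform_dmi - 1e-9))
  # optimal-weight entropy also bounds the information
  qmat <- as.matrix(cv$curve[, c("q_toy_condition_1", "q_toy_condition_2")])
  hq <- apply(qmat, 1, function(q) -sum(ifelse(q > 0, q * log2(q), 0)))
  expect_true(all(cv$curve$max_dmi <= hq + 1e-6))
})

test_that("a one-timepoint dMI run with pseudocount-free Markov models equals the timepoint baseline", {
  set.seed(31)
  sts <- lapply(1:2, function(i)
    cbind(sample.int(2, 50, replace = TRUE, prob = c(0.2 + 0.5 * (i - 1), 0.8 - 0.5 * (i - 1))),
          sample.int(2, 50, replace = TRUE)))
  # ensure both symbols occur at timepoint 1 in both conditions
  for (i in 1:2) sts[[i]][1:2, 1] <- c(1L, 2L)
  ens <- lapply(1:2, function(i) mk_densemble(sts[[i]], 2, paste0("c", i), "s"))
  models <- lapply(ens, fit_time_inhomogeneous, pseudocount = 0)
  for (i in 1:2) models[[i]]$scheme_id <- "s"
  sc <- score_conditions(models, ens)
  opt_traj <- maximize_dmi(sc, 1)
  opt_tp <- timepoint_mi(ens, 1, pseudocount = 0)
  expect_equal(opt_traj$value, opt_tp$value, tolerance = 1e-5)
})

test_that("timepoint baseline: identical marginals give zero, disjoint give ~1 bit", {
  e_same <- lapply(1:2, function(i) mk_densemble(matrix(rep(1:2, 10), 10, 2), 2,
                                                 paste0("c", i), "s"))
  expect_equal(timepoint_mi(e_same, 1)$value, 0, tolerance = 1e-9)
  e_disj <- list(mk_densemble(matrix(1L, 200, 2), 2, "a", "s"),
                 mk_densemble(matrix(2L, 200, 2), 2, "b", "s"))
  expect_equal(timepoint_mi(e_disj, 1)$value, 1, tolerance = 0.05)
  # arbitrary 2x2 channel against the grid oracle
  set.seed(8)
  P <- rand_stoch(2, 2)
  expect_equal(channel_capacity(P)$value,
               grid_max_2(function(q) channel_mi(P, q))$value, tolerance = 1e-3)
})

test_that("timepoint permutation is seeded, shared across conditions, and invertible", {
  set.seed(15)
  ens <- lapply(1:2, function(i)
    mk_densemble(matrix(sample.int(3, 40, replace = TRUE), 5, 8), 3, paste0("c", i), "s"))
  p1 <- permute_timepoints(ens, seed = 4)
  p2 <- permute_timepoints(ens, seed = 4)
  expect_identical(p1$permutation, p2$permutation)
  expect_identical(p1$ensembles[[1]]$states, p2$ensembles[[1]]$states)
  # inverting the recorded permutation restores the original ensembles
  inv <- order(p1$permutation)
  expect_identical(p1$ensembles[[2]]$states[, inv], ens[[2]]$states)
  short <- ens; short[[2]]$states <- short[[2]]$states[, 1:5]
  expect_error(permute_timepoints(short, seed = 1), class = "dynmi_bad_shape")
})
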