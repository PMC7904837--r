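# Model-quality metrics and the split-half overfitting protocol.

#' Relative KL-divergence between data and model-sampled marginals
#'
#' At each timepoint, the Kullback-Leibler divergence between the data's and the
#' sample's symbol marginals is divided by the entropy of the data marginal
#' ("relative KL-divergence"); both marginals receive a pseudocount per symbol
#' before normalization, since finite-sample KL is undefined on empty bins.
#' Values near 0 indicate that the model reproduces the per-timepoint
#' distributions; below ~0.1 is typical of a well-trained model.
#'
#' @param data,sample [discrete_ensemble()] objects on a shared alphabet; row
#'   counts may differ.
#' @param pseudocount Added per symbol to both marginals (default 0.5).
#' @return List with `per_timepoint` (ratios, `NA` where undefined), `mean`
#'   (over defined timepoints) and `excluded` (indices of undefined timepoints).
#' @export
relative_kl_per_timepoint <- function(data, sample, pseudocount = 0.5) {
  stopifnot(inherits(data, "discrete_ensemble"), inherits(sample, "discrete_ensemble"))
  if (data$K_E != sample$K_E)
    dynmi_stop("dynmi_scheme_mismatch", "data and sample must share one alphabet")
  if (ncol(data$states) != ncol(sample$states))
    dynmi_stop("dynmi_bad_shape", "data and sample must share the number of timepoints")
  K <- data$K_E
  N <- ncol(data$states)
  ratios <- numeric(N)
  excluded <- integer(0)
  for (n in seq_len(N)) {
    p <- tabulate(data$states[, n], nbins = K) + pseudocount
    p <- p / sum(p)
    q <- tabulate(sample$states[, n], nbins = K) + pseudocount
    q <- q / sum(q)
    kl <- kl_bits(p, q)
    h <- entropy_bits(p)
    if (h == 0) {
      if (kl == 0) ratios[n] <- 0
      else { ratios[n] <- NA_real_; excluded <- c(excluded, n) }
    } else ratios[n] <- kl / h
  }
  if (length(excluded))
    warning(sprintf("%d timepoint(s) with zero data entropy but nonzero KL excluded from the mean",
                    length(excluded)))
  list(per_timepoint = ratios, mean = mean(ratios, na.rm = TRUE), excluded = excluded)
}

#' False k-nearest-neighbor mixing probability
#'
#' Mixes the two ensembles into one pool of full-length trajectory vectors and,
#' for every trajectory of `sample`, counts how many of its `k` nearest
#' neighbors (Euclidean distance, self excluded) come from the *other* ensemble
#' ("false" neighbors). The count histogram is fitted to a binomial law by
#' maximum likelihood (`p_hat = mean(count) / k`); the fitted probabilities are
#' averaged over `k_values`. A value of 0.5 indicates optimal mixing
#' (indistinguishable ensembles); 0 indicates complete separation.
#'
#' @param data,sample [trajectory_ensemble()] or [discrete_ensemble()] objects
#'   with the same number of timepoints (continuous values are used when
#'   available, otherwise the integer state indices).
#' @param k_values Neighborhood sizes (default `c(1, 5, 10)`).
#' @param seed Seed for the random tie-break among equidistant neighbors.
#' @return List with `p` (mean fitted probability), `per_k` (named vector) and
#'   the `k_values` used.
#' @export
false_knn_probability <- function(data, sample, k_values = c(1, 5, 10), seed = 1) {
  X_data <- ensemble_matrix(data)
  X_sample <- ensemble_matrix(sample)
  if (ncol(X_data) != ncol(X_sample))
    dynmi_stop("dynmi_bad_shape", "ensembles must share the number of timepoints")
  pool <- rbind(X_sample, X_data)
  n_s <- nrow(X_sample); n_total <- nrow(pool)
  if (max(k_values) >= n_total)
    dynmi_stop("dynmi_bad_shape", "k must be smaller than the pooled trajectory count")
  from_data <- c(rep(FALSE, n_s), rep(TRUE, nrow(X_data)))
  d <- as.matrix(stats::dist(pool))
  per_k <- with_seed(seed, {
    counts <- vapply(seq_len(n_s), function(j) {
      # fresh tie-break jitter per query keeps equidistant-neighbor choices
      # independent across trajectories (ties are common for integer states)
      ord <- order(d[j, ], stats::runif(n_total), method = "radix")
      ord <- ord[ord != j]
      vapply(k_values, function(k) sum(from_data[ord[seq_len(k)]]), numeric(1))
    }, numeric(length(k_values)))
    counts <- matrix(counts, nrow = length(k_values))
    vapply(seq_along(k_values), function(ki) mean(counts[ki, ]) / k_values[ki], numeric(1))
  })
  names(per_k) <- paste0("k", k_values)
  list(p = mean(per_k), per_k = per_k, k_values = k_values)
}

ensemble_matrix <- function(e) {
  if (inherits(e, "trajectory_ensemble")) e$values
  else if (inherits(e, "discrete_ensemble")) {
    m <- e$states; storage.mode(m) <- "double"; m
  } else dynmi_stop("dynmi_bad_shape", "expected a trajectory or discrete ensemble")
}

#' Rescaled held-out log-likelihood
#'
#' The per-step log-likelihood ratio of the model against the null hypothesis of
#' independent uniform emission over the `K_E` symbols: for a trajectory of
#' length `n`, `(1/n) * (log2 p(y_{1:n}) + n * log2 K_E)`, averaged over the
#' test trajectories. The rescaling counteracts the per-step decay of trajectory
#' probabilities with alphabet size; positive values mean the model beats the
#' uniform null, and the null model itself scores exactly 0.
#'
#' @param model A fitted `"hmm"` or `"timm"`.
#' @param test A [discrete_ensemble()] scoreable by the model.
#' @return Mean rescaled log-likelihood (bits per step).
#' @export
rescaled_log_likelihood <- function(model, test) {
  stopifnot(inherits(test, "discrete_ensemble"))
  lp <- prefix_matrix(model, test$states)
  n <- ncol(test$states)
  mean(lp[, n] / n + log2(model$K_E))
}

#' Split an ensemble into training and held-out test trajectories
#'
#' @param ensemble A [discrete_ensemble()] or [trajectory_ensemble()].
#' @param n_test Held-out trajectory count (default 30), must be smaller than
#'   the number of trajectories.
#' @param seed Integer seed; splits are disjoint, reproducible, and their union
#'   is the original ensemble.
#' @return List with `train` and `test` ensembles.
#' @export
train_test_split <- function(ensemble, n_test = 30, seed = 1) {
  nm <- if (inherits(ensemble, "discrete_ensemble")) "states" else "values"
  m <- nrow(ensemble[[nm]])
  if (n_test >= m)
    dynmi_stop("dynmi_bad_shape",
               sprintf("n_test (%d) must be smaller than the trajectory count (%d)", n_test, m))
  idx <- with_seed(seed, sample.int(m, n_test))
  test <- ensemble; train <- ensemble
  test[[nm]] <- ensemble[[nm]][idx, , drop = FALSE]
  train[[nm]] <- ensemble[[nm]][-idx, , drop = FALSE]
  list(train = train, test = test)
}

#' Split-half overfitting check
#'
#' For each condition, the trajectory ensemble is randomly bipartitioned into
#' two equal halves, one model is fitted per half at the requested state counts,
#' and the maximum dMI between the two halves (treated as two pseudo-conditions,
#' final timepoint) is computed. Both halves come from the same condition, so
#' the maximum dMI should be near zero; values clearly above zero reveal that
#' the models encode half-specific sampling noise, i.e. overfitting at this
#' configuration.
#'
#' @param ensembles List of [discrete_ensemble()] objects (one per condition).
#' @param family `"hmm"` or `"timm"`.
#' @param n_hidden Hidden states for the HMM family (default `2 * K_E`).
#' @param pseudocount Pseudocount for the TIMM family.
#' @param restarts,tol,max_iter EM settings for the HMM family.
#' @param seed Integer seed (bipartitions and EM initializations).
#' @return List with `mean` (bits), `per_condition` (named vector) and a
#'   `config` echo.
#' @export
split_half_overfit_check <- function(ensembles, family = c("hmm", "timm"),
                                     n_hidden = NULL, pseudocount = 0.5,
                                     restarts = 3, tol = 1e-5, max_iter = 200,
                                     seed = 1) {
  family <- match.arg(family)
  if (inherits(ensembles, "discrete_ensemble")) ensembles <- list(ensembles)
  per <- vapply(seq_along(ensembles), function(i) {
    e <- ensembles[[i]]
    m <- nrow(e$states)
    if (m < 4L)
      dynmi_stop("dynmi_bad_shape",
                 sprintf("condition '%s' has too few trajectories (%d) for a split-half check",
                         e$condition_label, m))
    idx <- with_seed(seed + i, sample.int(m, m %/% 2L))
    halves <- list(e, e)
    halves[[1L]]$states <- e$states[idx, , drop = FALSE]
    halves[[2L]]$states <- e$states[-idx, , drop = FALSE]
    halves[[1L]]$condition_label <- paste0(e$condition_label, "_half1")
    halves[[2L]]$condition_label <- paste0(e$condition_label, "_half2")
    models <- lapply(seq_along(halves), function(h) {
      if (family == "hmm")
        fit_hmm(halves[[h]], n_hidden = n_hidden, restarts = restarts, tol = tol,
                max_iter = max_iter, seed = seed + 101L * i + h)
      else fit_time_inhomogeneous(halves[[h]], pseudocount = pseudocount)
    })
    scores <- score_conditions(models, halves)
    maximize_dmi(scores, scores$N)$value
  }, numeric(1))
  names(per) <- vapply(ensembles, `[[`, character(1), "condition_label")
  list(mean = mean(per), per_condition = per,
       config = list(family = family, n_hidden = n_hidden,
                     pseudocount = pseudocount, seed = seed))
}
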