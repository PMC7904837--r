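# End-to-end workflow: simulate ensembles, fit and evaluate per-condition
# models, compute dMI curves. These functions back the command-line front end
# at inst/cli/dynmi.R; each writes delimited-text outputs plus a YAML config
# echo sufficient to reproduce the run.

#' Assemble a run configuration
#'
#' @param manifest Path to a condition manifest (see [read_manifest()]).
#' @param family Model family, `"hmm"` or `"markov"`.
#' @param n_emission Emission symbols for discretization (default 32).
#' @param n_hidden Hidden states; default `2 * n_emission` (2:1
#'   hidden:emission ratio).
#' @param restarts,em_tol,max_iter Baum-Welch settings.
#' @param pseudocount Transition pseudocount for the Markov family.
#' @param k_values Neighborhood sizes for the false k-NN metric.
#' @param n_test Held-out trajectories for the rescaled log-likelihood.
#' @param optimizer_tol Simplex-optimizer tolerance in bits.
#' @param overfit_threshold Split-half dMI (bits) above which a configuration is
#'   flagged as overfitted (default 0.1).
#' @param seed Mandatory integer seed.
#' @param out_dir Output directory.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(manifest = NULL, family = c("hmm", "markov"),
                       n_emission = 32, n_hidden = NULL, restarts = 5,
                       em_tol = 1e-6, max_iter = 500, pseudocount = 0.5,
                       k_values = c(1, 5, 10), n_test = 30,
                       optimizer_tol = 1e-6, overfit_threshold = 0.1,
                       seed, out_dir = ".") {
  family <- match.arg(family)
  if (missing(seed) || !is_count(seed))
    dynmi_stop("dynmi_bad_config", "an integer seed is mandatory")
  stopifnot(is_count(n_emission), n_emission >= 2, restarts >= 1,
            em_tol > 0, max_iter >= 1, pseudocount >= 0, n_test >= 1,
            optimizer_tol > 0)
  if (is.null(n_hidden)) n_hidden <- 2L * as.integer(n_emission)
  structure(list(manifest = manifest, family = family,
                 n_emission = as.integer(n_emission), n_hidden = as.integer(n_hidden),
                 restarts = restarts, em_tol = em_tol, max_iter = max_iter,
                 pseudocount = pseudocount, k_values = k_values, n_test = n_test,
                 optimizer_tol = optimizer_tol, overfit_threshold = overfit_threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_echo <- function(config, extra = list()) {
  yaml::write_yaml(c(unclass(config), extra),
                   file.path(config$out_dir, "run_config.yaml"))
}

#' Simulate a synthetic dataset and write it to disk
#'
#' Presets: `"toy2"`/`"toy4"` write discretized toy hidden-Markov ensembles
#' (2 or 4 fully distinguishable conditions) as integer matrices; `"nfkb"`
#' writes continuous oscillatory/pulse-like ensembles. Ground-truth toy models
#' are stored as text sidecars.
#'
#' @param config A [run_config()] (`out_dir`, `seed` used).
#' @param preset `"toy2"`, `"toy4"` or `"nfkb"`.
#' @return The manifest path, invisibly.
#' @export
cmd_simulate <- function(config, preset = c("toy2", "toy4", "nfkb")) {
  preset <- match.arg(preset)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (preset %in% c("toy2", "toy4")) {
    M <- if (preset == "toy2") 2L else 4L
    spec <- toy_spec(M = M, K = 2L, K_E = 2L * M, separation = 1,
                     n_traj = 200, length = 60, seed = config$seed)
    toy <- generate_toy_hmm_ensembles(spec)
    ensembles <- lapply(toy$ensembles, function(e)
      trajectory_ensemble(matrix(as.numeric(e$states), nrow(e$states)),
                          e$condition_label, time_step = 1))
    man <- write_ensembles(ensembles, config$out_dir)
    for (i in seq_along(toy$models))
      write_model(toy$models[[i]],
                  file.path(config$out_dir, sprintf("ground_truth_model_%d.txt", i)))
  } else {
    specs <- list(
      oscillatory = dynamics_spec(amplitude = 1, period = 12, damping = 0.02,
                                  oscillatory = TRUE, noise_sd = 0.05,
                                  cell_variability = 0.3, phase_jitter = 3,
                                  n_traj = 200, length = 60, seed = config$seed),
      sustained = dynamics_spec(amplitude = 1, duration = 40, oscillatory = FALSE,
                                damping = 0.01, noise_sd = 0.05,
                                cell_variability = 0.3,
                                n_traj = 200, length = 60, seed = config$seed + 1L))
    ensembles <- Map(function(s, lbl) generate_dynamic_ensemble(s, condition_label = lbl),
                     specs, names(specs))
    man <- write_ensembles(unname(ensembles), config$out_dir)
  }
  config_echo(config, list(preset = preset))
  invisible(attr(man, "path"))
}

## Read + discretize all conditions of a manifest under one pooled scheme.
load_discretized <- function(config) {
  ensembles <- read_ensembles(config$manifest)
  scheme <- fit_discretization(ensembles, K_E = config$n_emission)
  list(continuous = ensembles,
       discrete = lapply(ensembles, discretize, scheme = scheme),
       scheme = scheme)
}

fit_condition_model <- function(config, densemble, seed) {
  if (config$family == "hmm")
    fit_hmm(densemble, n_hidden = config$n_hidden, restarts = config$restarts,
            tol = config$em_tol, max_iter = config$max_iter, seed = seed)
  else fit_time_inhomogeneous(densemble, pseudocount = config$pseudocount)
}

#' Fit per-condition models and write an evaluation report
#'
#' For every condition: fits the configured model on a training split, writes
#' the model as text, and reports the relative KL-divergence curve (data vs a
#' model-sampled ensemble), the false k-NN mixing probability, the rescaled
#' log-likelihood on the held-out trajectories, and the split-half maximum dMI.
#' A summary TSV across conditions flags overfitting when the split-half dMI
#' exceeds `config$overfit_threshold` bits.
#'
#' @param config A [run_config()] with a readable `manifest`.
#' @return The summary data frame, invisibly.
#' @export
cmd_fit_evaluate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dat <- load_discretized(config)
  rows <- list()
  for (i in seq_along(dat$discrete)) {
    de <- dat$discrete[[i]]
    label <- de$condition_label
    split <- train_test_split(de, n_test = min(config$n_test, nrow(de$states) - 1L),
                              seed = config$seed + i)
    model <- fit_condition_model(config, split$train, seed = config$seed + 7L * i)
    write_model(model, file.path(config$out_dir, sprintf("model_%s.txt", label)))
    sampled <- sample_model(model, n_traj = nrow(de$states), length = ncol(de$states),
                            seed = config$seed + 13L * i, condition_label = label)
    kl <- relative_kl_per_timepoint(de, sampled)
    knn <- false_knn_probability(de, sampled, k_values = config$k_values,
                                 seed = config$seed + 17L * i)
    rll <- rescaled_log_likelihood(model, split$test)
    utils::write.table(
      data.frame(timepoint = seq_along(kl$per_timepoint), relative_kl = kl$per_timepoint),
      file.path(config$out_dir, sprintf("relative_kl_%s.tsv", label)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    rows[[i]] <- data.frame(condition = label,
                            n_trajectories = nrow(de$states),
                            mean_relative_kl = kl$mean,
                            false_knn_p = knn$p,
                            rescaled_loglik = rll)
  }
  overfit <- split_half_overfit_check(
    dat$discrete, family = if (config$family == "hmm") "hmm" else "timm",
    n_hidden = config$n_hidden, pseudocount = config$pseudocount,
    restarts = min(config$restarts, 3), tol = max(config$em_tol, 1e-5),
    max_iter = min(config$max_iter, 200), seed = config$seed)
  summary <- do.call(rbind, rows)
  summary$split_half_dmi <- overfit$per_condition[summary$condition]
  summary$overfit_flag <- summary$split_half_dmi > config$overfit_threshold
  utils::write.table(summary, file.path(config$out_dir, "evaluation_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  config_echo(config)
  invisible(summary)
}

#' Compute and write dMI curves
#'
#' Fits one model per condition and writes the cumulative maximum-dMI curve
#' (all conditions jointly). With `pairwise = TRUE`, one curve per condition
#' pair is written as well; with `shuffle = TRUE`, the whole computation is
#' repeated after one random permutation of the timepoints (applied identically
#' to every condition) as a control for dynamically encoded information.
#'
#' @param config A [run_config()].
#' @param pairwise Also compute curves for every condition pair.
#' @param shuffle Also compute the timepoint-shuffled control curve.
#' @return Named list of `"dmi_curve"` objects, invisibly (`joint`, optional
#'   `shuffled`, optional `pair_<a>_<b>` entries).
#' @export
cmd_dmi <- function(config, pairwise = FALSE, shuffle = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dat <- load_discretized(config)
  meta <- list(seed = config$seed, family = config$family,
               n_emission = config$n_emission, n_hidden = config$n_hidden,
               optimizer_tol = config$optimizer_tol)
  fit_all <- function(densembles, seed_offset = 0L) {
    lapply(seq_along(densembles), function(i)
      fit_condition_model(config, densembles[[i]],
                          seed = config$seed + seed_offset + 7L * i))
  }
  out <- list()
  models <- fit_all(dat$discrete)
  out$joint <- dmi_curve(models, dat$discrete, tol = config$optimizer_tol)
  write_dmi_curve(out$joint, file.path(config$out_dir, "dmi_curve.tsv"), meta)
  if (shuffle) {
    perm <- permute_timepoints(dat$discrete, seed = config$seed)
    models_s <- fit_all(perm$ensembles, seed_offset = 1000L)
    out$shuffled <- dmi_curve(models_s, perm$ensembles, tol = config$optimizer_tol)
    write_dmi_curve(out$shuffled, file.path(config$out_dir, "dmi_curve_shuffled.tsv"),
                    c(meta, list(permutation = perm$permutation)))
  }
  if (pairwise) {
    M <- length(dat$discrete)
    for (a in seq_len(M - 1L)) for (b in (a + 1L):M) {
      cv <- dmi_curve(models[c(a, b)], dat$discrete[c(a, b)], tol = config$optimizer_tol)
      nm <- sprintf("pair_%s_%s", dat$discrete[[a]]$condition_label,
                    dat$discrete[[b]]$condition_label)
      out[[nm]] <- cv
      write_dmi_curve(cv, file.path(config$out_dir, paste0("dmi_curve_", nm, ".tsv")), meta)
    }
  }
  config_echo(config, list(pairwise = pairwise, shuffle = shuffle))
  invisible(out)
}

#' Write a fitted model as structured text
#'
#' @param model An `"hmm"` or `"timm"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wr <- function(...) writeLines(sprintf(...), con)
  num <- function(x) paste(format(x, digits = 17), collapse = " ")
  if (inherits(model, "hmm")) {
    wr("family: hmm"); wr("K: %d", model$K); wr("K_E: %d", model$K_E)
    wr("emission_floor: %s", format(model$emission_floor, digits = 17))
    wr("pi: %s", num(model$pi))
    wr("T:"); for (i in seq_len(model$K)) wr("  %s", num(model$T[i, ]))
    wr("E:"); for (i in seq_len(model$K_E)) wr("  %s", num(model$E[i, ]))
  } else if (inherits(model, "timm")) {
    wr("family: timm"); wr("K_E: %d", model$K_E); wr("N: %d", model$N)
    wr("pseudocount: %s", format(model$pseudocount, digits = 17))
    wr("initial: %s", num(model$initial))
    for (n in seq_len(dim(model$transitions)[3L])) {
      wr("transition %d:", n)
      for (i in seq_len(model$K_E)) wr("  %s", num(model$transitions[i, , n]))
    }
  } else dynmi_stop("dynmi_bad_model", "unknown model class")
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path Text model file.
#' @return An `"hmm"` or `"timm"` object.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  val <- function(key) sub(paste0("^", key, ": "), "", grep(paste0("^", key, ":"), lines, value = TRUE)[1L])
  nums <- function(s) as.numeric(strsplit(trimws(s), " +")[[1L]])
  family <- val("family")
  if (family == "hmm") {
    K <- as.integer(val("K")); K_E <- as.integer(val("K_E"))
    pi <- nums(val("pi"))
    tline <- which(lines == "T:"); eline <- which(lines == "E:")
    T <- t(vapply(lines[(tline + 1L):(tline + K)], nums, numeric(K), USE.NAMES = FALSE))
    E <- t(vapply(lines[(eline + 1L):(eline + K_E)], nums, numeric(K), USE.NAMES = FALSE))
    hmm_model(pi, T, E, emission_floor = as.numeric(val("emission_floor")))
  } else if (family == "timm") {
    K_E <- as.integer(val("K_E")); N <- as.integer(val("N"))
    init <- nums(val("initial"))
    trans <- array(0, c(K_E, K_E, N - 1L))
    for (n in seq_len(N - 1L)) {
      start <- which(lines == sprintf("transition %d:", n))
      trans[, , n] <- t(vapply(lines[(start + 1L):(start + K_E)], nums, numeric(K_E),
                               USE.NAMES = FALSE))
    }
    structure(list(K_E = K_E, initial = init, transitions = trans, N = N,
                   pseudocount = as.numeric(val("pseudocount")), scheme_id = NULL),
              class = "timm")
  } else dynmi_stop("dynmi_bad_model", "unknown model family in file")
}
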