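# Seeded generators for ground-truth synthetic trajectory ensembles.
#
# Two families: (i) toy hidden-Markov ensembles with a controllable
# distinguishability dial ("separation"), used to validate that the dMI
# saturates at log2(M) bits for M fully distinguishable conditions; and
# (ii) NFkB-like continuous ensembles with stimulus-specific amplitude,
# oscillation (period of order 1-2 h), damping, duration and measurement noise.

#' Specification of a toy hidden-Markov ensemble set
#'
#' @param M Number of stimulus conditions (>= 1).
#' @param K Hidden states per ground-truth model.
#' @param K_E Emission symbols of the shared alphabet. Must satisfy `K_E >= M`
#'   whenever `separation > 0` (each condition needs its own symbol block).
#' @param separation In `[0, 1]`: 0 = all conditions share one model (no
#'   stimulus information), 1 = per-condition emission supports are disjoint
#'   symbol blocks (fully distinguishable, dMI saturates at `log2(M)` bits).
#'   Intermediate values linearly blend the shared and block emissions.
#' @param n_traj Trajectories per condition.
#' @param length Timepoints per trajectory.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `"toy_spec"`.
#' @export
toy_spec <- function(M = 2, K = 2, K_E = 2 * M, separation = 1,
                     n_traj = 200, length = 60, seed = 1) {
  stopifnot(is_count(M), M >= 1, is_count(K), K >= 1, is_count(K_E), K_E >= 2,
            is.numeric(separation), separation >= 0, separation <= 1,
            is_count(n_traj), n_traj >= 1, is_count(length), length >= 2)
  if (separation > 0 && K_E < M)
    dynmi_stop("dynmi_bad_alphabet",
               sprintf("separation > 0 needs K_E >= M (got K_E = %d, M = %d)", K_E, M))
  structure(list(M = as.integer(M), K = as.integer(K), K_E = as.integer(K_E),
                 separation = separation, n_traj = as.integer(n_traj),
                 length = as.integer(length), seed = as.integer(seed)),
            class = "toy_spec")
}

#' Generate toy hidden-Markov ensembles with known ground truth
#'
#' Builds `M` ground-truth hidden Markov models over one shared emission
#' alphabet and samples one ensemble from each. Condition `i`'s emission matrix
#' is a linear blend `(1 - s) * E_shared + s * E_block_i`, where `E_block_i` is
#' supported on condition `i`'s own block of `floor(K_E / M)` symbols: at
#' `s = 1` the conditions' empirical symbol supports are disjoint; at `s = 0`
#' all conditions follow the identical shared model. All conditions share the
#' transition matrix and a uniform initial distribution.
#'
#' @param spec A [toy_spec()].
#' @return List with `ensembles` (list of [discrete_ensemble()]) and `models`
#'   (list of ground-truth `"hmm"` objects), both in condition order.
#' @export
generate_toy_hmm_ensembles <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  M <- spec$M; K <- spec$K; K_E <- spec$K_E; s <- spec$separation
  scheme_id <- sprintf("toy-alphabet-K%d-seed%d", K_E, spec$seed)
  models <- with_seed(spec$seed, {
    T_shared <- random_stochastic(K, K)
    E_shared <- random_stochastic(K_E, K)
    block_size <- max(1L, K_E %/% M)
    lapply(seq_len(M), function(i) {
      if (s > 0) {
        block <- ((i - 1L) * block_size + 1L):(i * block_size)
        E_block <- matrix(0, K_E, K)
        E_block[block, ] <- random_stochastic(block_size, K)
        E_i <- (1 - s) * E_shared + s * E_block
      } else {
        E_i <- E_shared
      }
      m <- hmm_model(rep(1 / K, K), T_shared, E_i, emission_floor = 0)
      m$scheme_id <- scheme_id
      m
    })
  })
  ensembles <- lapply(seq_len(M), function(i) {
    e <- sample_model(models[[i]], spec$n_traj, spec$length,
                      seed = spec$seed + i,
                      condition_label = sprintf("toy_condition_%d", i))
    e$scheme_id <- scheme_id
    e
  })
  list(ensembles = ensembles, models = models)
}

#' Specification of an NFkB-like continuous trajectory ensemble
#'
#' Emulates heterogeneous single-cell signaling dynamics: each cell's trajectory
#' is `scale_c * amplitude * exp(-damping * t) * w(t) + noise`, clipped at 0,
#' where `w` is either a rectified sinusoid with the given period (oscillatory
#' responses; nuclear NFkB oscillates with a 1-2 h period) or a saturating
#' pulse of the given duration, and `scale_c` is a per-cell lognormal scale.
#'
#' @param amplitude Peak signal scale (arbitrary units).
#' @param period Oscillation period in timepoints (used when `oscillatory`).
#' @param damping Exponential decay rate per timepoint (>= 0).
#' @param duration Timepoints of sustained activity (used when not oscillatory).
#' @param oscillatory Logical.
#' @param noise_sd Additive Gaussian measurement noise SD (>= 0).
#' @param cell_variability Lognormal sdlog of the per-cell scale (>= 0).
#' @param phase_jitter Per-cell random phase offset, drawn uniformly from
#'   `[0, phase_jitter)` timepoints (0 = all cells in phase).
#' @param n_traj,length Ensemble dimensions.
#' @param time_step Minutes per timepoint.
#' @param seed Integer seed.
#' @return An object of class `"dynamics_spec"`.
#' @export
dynamics_spec <- function(amplitude = 1, period = 12, damping = 0, duration = 20,
                          oscillatory = TRUE, noise_sd = 0.05,
                          cell_variability = 0.3, phase_jitter = 0,
                          n_traj = 200, length = 60, time_step = 5, seed = 1) {
  stopifnot(is.numeric(amplitude), amplitude > 0,
            is.numeric(damping), damping >= 0,
            is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(cell_variability), cell_variability >= 0,
            is.numeric(phase_jitter), phase_jitter >= 0,
            is_count(n_traj), n_traj >= 1, is_count(length), length >= 2)
  if (oscillatory && (!is.numeric(period) || period <= 0))
    dynmi_stop("dynmi_bad_spec", "oscillatory dynamics need period > 0")
  if (!oscillatory && (!is.numeric(duration) || duration <= 0))
    dynmi_stop("dynmi_bad_spec", "pulse dynamics need duration > 0")
  structure(list(amplitude = amplitude, period = period, damping = damping,
                 duration = duration, oscillatory = isTRUE(oscillatory),
                 noise_sd = noise_sd, cell_variability = cell_variability,
                 phase_jitter = phase_jitter, n_traj = as.integer(n_traj),
                 length = as.integer(length), time_step = time_step,
                 seed = as.integer(seed)),
            class = "dynamics_spec")
}

## Deterministic waveform at times t (1-based timepoints) with phase offset (tp).
dyn_waveform <- function(spec, t, phase = 0) {
  if (spec$oscillatory) {
    pmax(0, sin(2 * pi * (t - 1 - phase) / spec$period))
  } else {
    rise <- pmin(1, pmax(0, (t - phase) / max(1, spec$duration / 5)))
    rise * as.numeric((t - phase) <= spec$duration & (t - phase) > 0)
  }
}

#' Generate an NFkB-like continuous trajectory ensemble
#'
#' @param spec A [dynamics_spec()].
#' @param condition_label Label for the ensemble.
#' @param phase Deterministic phase offset (timepoints) applied to every cell,
#'   on top of any per-cell `phase_jitter`.
#' @return A [trajectory_ensemble()] of dimension `n_traj x length`.
#' @export
generate_dynamic_ensemble <- function(spec, condition_label = "synthetic", phase = 0) {
  stopifnot(inherits(spec, "dynamics_spec"))
  with_seed(spec$seed, {
    t <- seq_len(spec$length)
    scales <- if (spec$cell_variability > 0)
      stats::rlnorm(spec$n_traj, meanlog = 0, sdlog = spec$cell_variability)
    else rep(1, spec$n_traj)
    phases <- phase + if (spec$phase_jitter > 0)
      stats::runif(spec$n_traj, 0, spec$phase_jitter) else rep(0, spec$n_traj)
    env <- exp(-spec$damping * (t - 1))
    vals <- t(vapply(seq_len(spec$n_traj), function(c_) {
      scales[c_] * spec$amplitude * env * dyn_waveform(spec, t, phases[c_])
    }, numeric(spec$length)))
    if (spec$noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(length(vals), 0, spec$noise_sd),
                            nrow(vals), ncol(vals))
    vals <- pmax(vals, 0)
    trajectory_ensemble(vals, condition_label, spec$time_step)
  })
}

#' Generate a phase-shifted pair of oscillatory ensembles
#'
#' The two ensembles share all dynamical and amplitude statistics and differ
#' only by a temporal phase shift of the waveform, so (up to edge effects) each
#' cell's marginal value distribution over time is identical between the two
#' conditions and only the temporal ordering distinguishes them.
#'
#' @param spec A [dynamics_spec()] (typically oscillatory).
#' @param shift Phase shift in timepoints, `0 <= shift < length`.
#' @return List of two [trajectory_ensemble()] objects, labels `"reference"`
#'   and `"shifted"`.
#' @export
phase_shifted_pair <- function(spec, shift) {
  stopifnot(inherits(spec, "dynamics_spec"), is.numeric(shift), shift >= 0)
  if (shift >= spec$length)
    dynmi_stop("dynmi_bad_spec", "shift must be smaller than the trajectory length")
  a <- generate_dynamic_ensemble(spec, condition_label = "reference", phase = 0)
  spec_b <- spec
  spec_b$seed <- spec$seed + 1L
  b <- generate_dynamic_ensemble(spec_b, condition_label = "shifted", phase = shift)
  list(a, b)
}

#' Generate an oscillation-period contrast pair for the permutation control
#'
#' Two oscillatory ensembles with identical amplitude statistics and per-cell
#' uniform random phase, differing only in oscillation period. Because the phase
#' is uniform over a full period in both conditions, the per-timepoint marginal
#' value distributions are identical across conditions: the stimulus information
#' lives solely in the temporal ordering (fast vs slow dynamics), which a random
#' permutation of timepoints destroys. This is the package's benchmark for the
#' control that timepoint shuffling must decrease the dMI.
#'
#' @param spec A [dynamics_spec()]; its `period` is used for the first condition.
#' @param period2 Oscillation period of the second condition (timepoints).
#' @return List of two [trajectory_ensemble()] objects.
#' @export
period_contrast_pair <- function(spec, period2) {
  stopifnot(inherits(spec, "dynamics_spec"), spec$oscillatory)
  a_spec <- spec
  a_spec$phase_jitter <- spec$period
  b_spec <- spec
  b_spec$period <- period2
  b_spec$phase_jitter <- period2
  b_spec$seed <- spec$seed + 1L
  list(generate_dynamic_ensemble(a_spec, condition_label = sprintf("period_%g", spec$period)),
       generate_dynamic_ensemble(b_spec, condition_label = sprintf("period_%g", period2)))
}

#' Canonical benchmark hidden Markov model
#'
#' A fixed, well-mixing reference model (4 hidden states, 8 emission symbols;
#' sticky-but-mixing transitions, distinct yet overlapping per-state emission
#' profiles) used by the package's calibration benchmarks: two independent
#' ensembles sampled from it are exchangeable, so the false k-NN mixing
#' probability must read 0.5. A fixed model keeps that calibration's sampling
#' variance small and independent of the run seed.
#'
#' @return An `"hmm"` object.
#' @export
benchmark_hmm <- function() {
  K <- 4L; K_E <- 8L
  T <- matrix(0.15, K, K); diag(T) <- 0.55
  E <- matrix(0.04, K_E, K)
  peaks <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(7L, 8L))
  for (j in seq_len(K)) E[peaks[[j]], j] <- (1 - 0.04 * (K_E - 2)) / 2
  hmm_model(rep(1 / K, K), T, E)
}
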