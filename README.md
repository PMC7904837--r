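# dynmi — dynamical mutual information from single-cell signaling trajectories

Cells identify extracellular stimuli from the *temporal pattern* of signaling
activity (NFκB nuclear translocation being the motivating example), but
single cells respond heterogeneously, and the number of possible trajectory
configurations explodes with the number of timepoints. `dynmi` quantifies how
much information about the stimulus condition accumulates in the response
trajectories over time, for anyone with ensembles of single-cell time series
measured under two or more conditions.

## Method

One stochastic generative model is fitted per condition — a
time-inhomogeneous Markov chain (column-normalized transition counts per
timepoint pair) or a hidden Markov model (Baum–Welch EM, forward-algorithm
scoring, hidden:emission state ratio 2:1 by default) — on trajectories
discretized into a shared emission alphabet. Each trajectory's probability
gives its trajectory entropy `H(y_{1:n}) = -log2 p(y_{1:n})`, and with
stimulus weights `q` over the `M` conditions:

```
H(R_{1:n} | S) = - Σ_i q_i (1/m_i) Σ_j log2 p(y_{1:n}^{i,j} | S = i)
H(R_{1:n})     = - Σ_i q_i (1/m_i) Σ_j log2 [ Σ_k q_k p(y_{1:n}^{i,j} | S = k) ]
I(R_{1:n}; S)  = H(R_{1:n}) - H(R_{1:n} | S)
```

The **maximum dMI**, `I_max(R_{1:n}; S) = max_q I(R_{1:n}; S)` on the
probability simplex, is computed by projected-gradient ascent at every
cumulative timepoint; it is bounded by `log2 M` and approximates the channel
capacity of the condition set. The package also provides model-quality
metrics (relative KL-divergence, false k-nearest-neighbor mixing probability,
rescaled held-out log-likelihood), a split-half protocol that detects
overfitting as spurious dMI between halves of one condition, a
timepoint-permutation control, the classical single-timepoint MI baseline,
and seeded synthetic-data generators. See the vignette
(`vignettes/dynamical-mutual-information.Rmd`) for the full methods account.

## Worked example

Two fully distinguishable synthetic conditions must yield exactly 1 bit:

```r
library(dynmi)

# two fully distinguishable synthetic conditions (ground truth known)
spec <- toy_spec(M = 2, K = 2, K_E = 4, separation = 1,
                 n_traj = 200, length = 60, seed = 1)
toy <- generate_toy_hmm_ensembles(spec)
toy$ensembles[[1]]
#> Discrete ensemble 'toy_condition_1': 200 cells x 60 timepoints, alphabet 1..4

# one hidden Markov model per condition (hidden:emission ratio 2:1)
models <- lapply(1:2, function(i) fit_hmm(toy$ensembles[[i]], seed = i))
models[[1]]
#> Hidden Markov model: 8 hidden states, 4 emission symbols, train log-lik -11491.82 bits

# cumulative maximum dMI over the stimulus-weight simplex
curve <- dmi_curve(models, toy$ensembles)
curve
#> dMI curve over 2 conditions, 60 timepoints; final max dMI = 1.000 bits (ceiling log2 M = 1.000)
head(curve$curve[, 1:3], 3)
#>   timepoint   max_dmi uniform_dmi
#> 1         1 0.9999971   0.9999971
#> 2         2 1.0000000   1.0000000
#> 3         3 1.0000000   1.0000000

# model quality: how well does the fit reproduce condition 1?
sampled <- sample_model(models[[1]], 200, 60, seed = 3)
round(relative_kl_per_timepoint(toy$ensembles[[1]], sampled)$mean, 4)
#> [1] 0.0069
round(false_knn_probability(toy$ensembles[[1]], sampled, seed = 4)$p, 3)
#> [1] 0.5

# overfitting check: split-half dMI should be near zero
round(split_half_overfit_check(toy$ensembles, family = "hmm",
                               n_hidden = 4, seed = 5)$mean, 4)
#> [1] 0.0067
```

Reading the numbers: the curve saturates at the 1-bit ceiling from the first
timepoints because the two conditions emit from disjoint symbol blocks; the
mean relative KL of 0.007 and the false k-NN mixing probability of 0.50 say
the fitted model's samples are statistically indistinguishable from the data;
the split-half dMI of 0.007 bits says the configuration is not overfitted.

For real data, write one delimited matrix (cells × timepoints, header row)
per condition plus a YAML manifest, then `read_ensembles()`,
`fit_discretization()` (pooled across conditions), `discretize()`, and the
same calls as above — or use the command line:

```sh
Rscript inst/cli/dynmi.R simulate     --preset toy2 --seed 1 --out runs/toy
Rscript inst/cli/dynmi.R fit-evaluate --manifest runs/toy/manifest.yaml \
    --emission-states 4 --seed 1 --out runs/eval
Rscript inst/cli/dynmi.R dmi          --manifest runs/toy/manifest.yaml \
    --emission-states 4 --seed 1 --out runs/dmi --pairwise --shuffle
```

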