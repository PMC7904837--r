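---
title: "Quantifying information accumulation in signaling dynamics with dynmi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying information accumulation in signaling dynamics with dynmi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Signaling molecules such as NF&kappa;B convey the identity of an extracellular
stimulus through the *temporal pattern* of their activity, and different single
cells respond with different trajectories to the same stimulus. The mutual
information (MI) between the stimulus condition $S$ (one of $M$ conditions) and
the response trajectory $R_{1:n}$ observed up to timepoint $n$ measures how well
the conditions can, in principle, be distinguished from the responses available
by that time. Estimating this MI directly is intractable: the number of possible
trajectory configurations grows exponentially with the number of timepoints.

`dynmi` takes the model-based route. A stochastic generative model is fitted to
the trajectory ensemble of each condition; the fitted models assign every
observed trajectory a probability, and those probabilities feed a sample-based
MI estimate — the *dynamical mutual information* (dMI) — that is maximized over
the stimulus-weight distribution and traced cumulatively over timepoints.

## The estimator

For a single trajectory the **trajectory entropy** is
$H(y_{1:n}) = -\log_2 p(y_{1:n})$, evaluated under the fitted model of the
trajectory's own condition. With $m_i$ trajectories $y^{i,j}$ under condition
$i$ and stimulus weights $q = (q_1, \dots, q_M)$:

* conditional entropy:
  $H(R_{1:n} \mid S) = -\sum_i q_i \frac{1}{m_i} \sum_j \log_2 p(y^{i,j}_{1:n} \mid S = i)$;
* unconditional entropy:
  $H(R_{1:n}) = -\sum_i q_i \frac{1}{m_i} \sum_j \log_2 \big[ \sum_k q_k\, p(y^{i,j}_{1:n} \mid S = k) \big]$,
  which requires every trajectory to be scored under every condition's model;
* dMI: $I(R_{1:n}; S) = H(R_{1:n}) - H(R_{1:n} \mid S)$, and the **maximum
  dMI** $I_{\max}(R_{1:n}; S) = \max_q I(R_{1:n}; S)$ subject to
  $\sum_i q_i = 1$, $q_i \ge 0$, re-optimized independently at every
  cumulative timepoint $n$.

$I_{\max}$ is bounded by $\log_2 M$ and approximates the channel capacity of
the signaling pathway for the supplied condition set. The cumulative curve is
*not* asserted to be monotone in $n$: conditions whose dynamics transiently
converge genuinely lose distinguishability over that window, and the estimator
is allowed to report that.

## Models

Two model families are provided; both operate on trajectories discretized into
a shared emission alphabet of $K_E$ symbols.

**Time-inhomogeneous Markov model** (`fit_time_inhomogeneous`). One
column-stochastic transition matrix per consecutive timepoint pair, estimated by
column-normalized transition counts, with a pseudocount (default 0.5 per cell,
Jeffreys-style) so that cross-condition scoring never hits a hard zero. It
captures synchronized, time-locked features well, but its parameter count grows
linearly with trajectory length, which makes it prone to overfitting on small
ensembles.

**Hidden Markov model** (`fit_hmm`). One $K \times K$ hidden-state transition
matrix and one $K_E \times K$ emission matrix, fitted by Baum–Welch EM jointly
over all trajectories with seeded random restarts (default 5), relative
log-likelihood tolerance $10^{-6}$ and a 500-iteration cap. Being
time-homogeneous, it has far fewer parameters, can represent history-dependent
dynamics such as oscillations at various frequencies, and is the family of
choice for oscillatory data. The hidden:emission state ratio defaults to 2:1
(`n_hidden = 2 * K_E`), overridable.

All stochastic matrices in the package are **column-stochastic** — the column
indexes the conditioning variable — matching the column-normalization used in
the count-based fit; tests assert this orientation throughout.

Trajectory probabilities come from the forward recursion
$p(y_{1:n}, x_n) = E(y_n \mid x_n) \sum_{x_{n-1}} T(x_n \mid x_{n-1})\, p(y_{1:n-1}, x_{n-1})$,
implemented with per-step scaling so prefix log-probabilities are exact (no
underflow) for trajectories of hundreds of timepoints. The suite cross-checks
the recursion against exhaustive hidden-path enumeration, and both families
against total-probability normalization over all $K_E^n$ sequences.

## Tunable parameters

| Parameter | Default | Role |
|---|---|---|
| `K_E` (emission symbols) | 32 for full runs, 4–8 in small examples | resolution of the signal discretization |
| `n_hidden` | `2 * K_E` | hidden-state count (2:1 ratio) |
| `strategy` | `"quantile"` | bin placement, fitted on data pooled across all conditions |
| `pseudocount` | 0.5 | count regularization for the Markov family and the marginal estimators |
| `emission_floor` | `1e-6` | post-fit floor on emission probabilities (renormalized) |
| `restarts`, `tol`, `max_iter` | 5, `1e-6`, 500 | Baum–Welch settings |
| optimizer `tol` | `1e-6` bits | simplex-ascent convergence threshold |
| `n_test` | 30 | held-out trajectories for the rescaled log-likelihood |

Choices the data do not dictate, and why the defaults are what they are:

* **Pooled quantile binning.** The bins are fitted on data pooled across all
  conditions so that every per-condition model shares one alphabet — otherwise
  the cross-condition probabilities in the unconditional entropy are not
  comparable. Quantile (equal-occupancy) bins keep all count-matrix columns
  populated; equal-width bins are available by flag. Bins are half-open
  `[a, b)`, ties go up, the last bin is closed, and out-of-range values clamp
  to the boundary bins (a model trained on one data split must be able to
  score the other split).
* **Emission floor.** When one condition's trajectories are scored under
  another condition's model, symbols never emitted by that model would
  otherwise produce $-\infty$ log-probabilities; flooring at $10^{-6}$ and
  renormalizing is the minimal intervention that keeps the mixture in the
  unconditional entropy finite. It also sets the effective per-step penalty
  (about 20 bits) that a completely foreign symbol incurs.
* **Negative-dMI clipping.** The sample-based estimate can dip below zero by
  finite-sample noise; values are clipped at 0 and a warning reports the raw
  value when it falls below $-10^{-9}$ bits.
* **Simplex optimizer.** The objective is concave in $q$, so projected-gradient
  ascent with backtracking converges to the global maximum; it is
  cross-validated in the tests against a $10^{-3}$-step grid search and a
  closed-form channel capacity ($\log_2(5/4)$ bits for the asymmetric binary
  channel with rows $(1,0)$ and $(0.5, 0.5)$). Log-sum-exp is used for all
  mixtures, and $q_k = 0$ terms are dropped exactly.

## Model-quality metrics and overfitting

Three metrics quantify training performance (`cmd_fit_evaluate` reports all
three per condition):

* **Relative KL-divergence** — per-timepoint KL between the data's and a
  model-sampled ensemble's symbol marginals, divided by the data marginal's
  entropy, pseudocounted on both sides; near 0 means the model reproduces the
  per-timepoint distributions.
* **False k-NN mixing probability** — after mixing data and sampled
  trajectories, the binomial-fitted probability that a trajectory's $k$
  nearest neighbors (Euclidean, full time vector, self excluded; $k \in \{1,
  5, 10\}$ by default) come from the other ensemble. The maximum-likelihood
  binomial fit is $\hat p = \overline{\text{count}}/k$; 0.5 indicates optimal
  mixing. Ties among equidistant neighbors (frequent for integer state
  vectors) are broken by fresh seeded jitter per query, keeping neighbor
  choices independent across trajectories.
* **Rescaled log-likelihood** — per-step log-likelihood ratio on held-out
  trajectories against the null of independent uniform emissions:
  $(1/n)(\log_2 p(y_{1:n}) + n \log_2 K_E)$. The rescaling counteracts the
  per-step decay of trajectory probabilities with alphabet size; the uniform
  null itself scores exactly 0 and a deterministic model scoring its own
  output scores $\log_2 K_E$.

**Split-half protocol.** Too many states let a model memorize sampling noise,
which inflates the dMI. `split_half_overfit_check` bipartitions each
condition's ensemble at random, fits one model per half, and computes the
maximum dMI between the halves as two pseudo-conditions: both halves obey the
same generative law, so the value should be near zero, and a clearly positive
value flags overfitting at that state count. The workflow flags configurations
above 0.1 bits. In the acceptance suite the well-sampled case (400
trajectories/condition, 4 hidden states) is run with the HMM family and the
starved case (40 trajectories, 16 symbols) with the time-inhomogeneous family,
whose per-timepoint parameterization overfits at far lower state counts — the
same contrast between the families that motivates preferring the HMM for
trajectory-level information estimates.

## Synthetic data: what it emulates, and what it does not

`generate_toy_hmm_ensembles` builds $M$ ground-truth HMMs over one shared
alphabet: a common random model blended with per-condition block emissions,
`E_i = (1 - s) E_shared + s E_block_i`. The `separation` dial $s$ interpolates
from identical conditions ($s = 0$, zero information) to disjoint emission
supports ($s = 1$, fully distinguishable). The limiting behavior pins down the
estimator's calibration: at $s = 1$ the maximum dMI must saturate at $\log_2 M$
bits (1 bit for two conditions, 2 bits for four), and at $s = 0$ it must stay
near 0. The defaults (200 trajectories x 60 timepoints per condition) are the
benchmark conditions used by the acceptance script.

`generate_dynamic_ensemble` emulates NF&kappa;B-like heterogeneity: per-cell
lognormal amplitude scales, a damped rectified sinusoid (period of order 1–2 h)
or a saturating pulse, optional per-cell phase jitter, additive Gaussian noise,
clipping at zero. It reproduces the qualitative features the models must cope
with — oscillatory vs non-oscillatory patterns, amplitude heterogeneity,
measurement noise — but it is *not* a mechanistic model of the pathway: real
data add receptor-level stochasticity, non-stationary baselines, segmentation
artifacts and day effects that the generator does not represent. Passing the
synthetic benchmarks therefore validates the estimator's calibration and
internal consistency, not the biology of any particular dataset.

**Permutation control.** Shuffling the timepoints (the same random column
permutation applied to every condition) destroys temporal ordering while
preserving per-column marginals; a drop in the dMI after shuffling shows that
the ordering itself carried stimulus information. The package's benchmark for
this control is `period_contrast_pair`: two oscillatory ensembles with
identical amplitude statistics and per-cell uniform random phase that differ
only in oscillation period, so the per-timepoint marginals are identical
across conditions and *only* the dynamics are informative. A pair differing
only by a deterministic phase shift (`phase_shifted_pair`) is provided for
construction-level tests, but it cannot serve as this control: a
time-homogeneous HMM is shift-invariant except through its initial
distribution, so both the shuffled and unshuffled runs are driven by
single-column marginals and neither direction of the comparison is forced —
whereas with matched marginals and contrasting periods the unshuffled run
saturates near 1 bit and the shuffled run collapses toward 0.

**False k-NN calibration.** Two independent ensembles drawn from one model are
exchangeable, so the fitted mixing probability must read 0.5. The benchmark
uses the package's fixed `benchmark_hmm()` (4 hidden states, 8 symbols,
sticky-but-mixing transitions) and queries each ensemble against the other,
averaging the two fits. A fixed, well-mixing reference model is used because
randomly drawn transition matrices can mix slowly, which clusters the
ensembles, correlates neighbor counts, and inflates the variance of the
one-sided estimate several-fold without changing its expectation.

## Problem sizes

The bundled benchmarks run at desk scale: toy saturation at 200 trajectories x
60 timepoints per condition with 8 (two conditions) or 16 (four conditions)
hidden states; parameter recovery at 500 trajectories x 150 timepoints with 2
hidden states; the false k-NN calibration at 2 x 300 trajectories x 100
timepoints; the permutation control at 2 x 200 x 60 with 8 hidden states over
five seeds. Enumeration-based oracles are checked on instances up to 3 hidden
states, 3 symbols and 6 timepoints, where brute force is exact and fast.
Analyses of real datasets (tens of conditions, 32 emission symbols, hundreds of
cells) use the same code paths with larger settings.

## Known limitations

* The dMI is a *plug-in* estimate under the fitted models: model mismatch
  biases it downward (the models waste probability off the data manifold) and
  overfitting biases it upward; the evaluation metrics and the split-half
  protocol are there to keep runs inside the regime where neither dominates.
* Finite condition sets only: the maximum dMI is the capacity of the supplied
  condition set, not of the pathway over all conceivable stimuli.
* All trajectories within one computation must share length and sampling
  interval; ragged designs need upstream alignment.
* The Markov family requires the scored trajectory length not to exceed the
  fitted length; both families require the shared discretization scheme, and
  mixing model families across conditions in one dMI computation is rejected.
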