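---
title: "Information transmission in noisy glioma differentiation signaling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information transmission in noisy glioma differentiation signaling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(gliacap)
```

`gliacap` treats a stochastic signaling pathway as a communication channel:
the *input* is one of 16 composite signals — a cholera toxin (CT) dose
combined with a noise setting — and the *output* is the single-cell GFAP
response, either a scalar summary of the trajectory or a d-dimensional
vector of time samples. The channel capacity, the maximum of the mutual
information over all input distributions, measures how many of those
composite signals the response can reliably resolve, in bits. This vignette
documents the models, the estimator, and the numerical and design choices
behind the package, including which features of the published system the
synthetic reconstruction does and does not reproduce.

## The signaling models

The network has 10 states: PKA, phospho-CREB, IL6, active JAK2,
phospho-STAT3, PI3K, phospho-AKT, phospho-GSK3-beta (the inactive form of the
kinase), cyclin D1, and GFAP, the astrocytic differentiation marker used as
the channel output. CT acts through two arms:

* a **PKA/CREB/IL6/JAK2/STAT3** arm that drives GFAP synthesis, and
* a **PI3K/AKT/GSK3-beta** arm: CT inhibits PI3K, which lowers phospho-AKT
  and thereby *activates* GSK3-beta, which degrades cyclin D1.

Cyclin D1 is the hub of the dose response. It carries an ultrasensitive
positive feedback loop on its own synthesis and represses GFAP synthesis
through a steep Hill gate, so differentiation requires collapsing cyclin D1.
Untreated cells rest at a proliferative high-cyclin-D1 state (the shared
initial condition, stored with the packaged parameters). At 5 ng/ml the
degradation pressure is insufficient and cells are caught by a residual high
attractor; at 7.5 and 10 ng/ml cyclin D1 falls to a low level that opens the
GFAP gate, with dose-graded kinetics and depth. The dimensionless rate
constants (41 of them, units per hour, CT in ng/ml) live in
`inst/extdata/glioma_params_synthetic.yaml`.

**Provenance.** The parameterisation is synthetic: it is the package's own
calibration, chosen once so that the deterministic and stochastic variants
reproduce the published *qualitative* behaviour of the system — the
dose-graded differentiation of the low-noise row, suppression of
differentiation under strong intrinsic noise, extrinsic-noise-dominated
fans, and the enhanced, noise-robust differentiation of the
feedback-inhibited variant. Absolute rates are not measurements, and
quantitative outputs (e.g. absolute bit values) should be read accordingly.

### Noise structure

Three Ito SDE variants share the drift above (Euler-Maruyama integration):

* **AN** (additive noise): each state receives a Brownian term with
  intensity `sigma_an` times the state's dynamic scale (1 for the unit-range
  states, 3 for cyclin D1). Intensities 0.1%, 1%, 5%, 10% form the noise
  axis of the AN signal grid.
* **CLE** (chemical Langevin): intrinsic noise enters each state as
  `sigma_int * w_s * sqrt(production + degradation)` white noise — the
  square-root-propensity scaling of the chemical Langevin equation — and
  extrinsic noise as a per-cell, trajectory-constant log-normal perturbation
  of all 41 rate constants with log-scale standard deviation `sigma_ext`.
  The four settings LL, HL, LH, HH combine `sigma_int, sigma_ext` in
  {0.001, 0.1}. The per-species weights `w_s` (1 for signaling states, 2
  for cyclin D1, 3 for GFAP) play the role of inverse square-root copy
  number scales: the two output species are treated as lower-copy, hence
  noisier, than the kinase pools. They were fixed during model calibration.
* **CLE-**: the CLE model with the cyclin D1 feedback synthesis term scaled
  by `feedback_scale` (default 0, i.e. removed). Without feedback the high
  attractor disappears and every signal, including dose 0, relaxes to the
  gate-open low-cyclin-D1 state — differentiation becomes efficient
  regardless of dose and noise, which is exactly the behaviour that makes
  CLE- informative through kinetics rather than endpoints.

Before treatment starts at t = 0, every cell is placed at the untreated
steady state of its *own* parameters (solved analytically: the dose-0
cascade is feed-forward, with a scalar fixed-point iteration for cyclin D1)
and then run for a 10 h stochastic settling period at dose 0 with feedback
intact. Baselines at t = 0 therefore fluctuate cell-to-cell, which matters
for the fold-change descriptor — dividing by a noiseless common baseline
would make fold change an exact rescaling of max response.

States are clamped to zero after every step (reflection is not used); the
integrator aborts with a diagnostic naming cell, state and time on any
non-finite value. The default step is 0.01 h with output saved every 0.1 h
(481 points over 48 h); a grid-refinement test holds the population mean to
within 2% sup-norm under dt halving. Each cell integrates from its own
counter-derived xoshiro256+ stream, so ensembles are bit-reproducible and
independent of scheduling.

```{r fig2, fig.height = 6}
cle <- glioma_model("CLE")
grid <- build_signal_grid("CLE")
ens <- purrr::map(seq_len(nrow(grid)), function(i) {
  simulate_ensemble(cle, grid[i, ], sim_config(n_cells = 60, seed = 100 + i))
})
plot_trajectory_fans(ens, max_cells = 15)
```

## The capacity estimator

For a response dataset of N vectors in d dimensions with signal labels, the
conditional density of vector *i* under signal *s* is estimated with
k-nearest neighbours:

$$ \hat f(x_i \mid s) = \frac{k}{m_s \, c_d \, r_{s,k}(x_i)^d}, $$

with $r_{s,k}(x_i)$ the Euclidean distance to the k-th nearest class-s
sample (leave-one-out inside the own class, so $m_s = n_s - 1$ there),
and $c_d$ the unit-ball volume. The plug-in mutual information at input
weights $w$ is the response-entropy difference

$$ \hat I(w) = \sum_s w_s \frac{1}{n_s} \sum_{i \in s}
   \log_2 \frac{\hat f(x_i \mid s)}{\sum_{s'} w_{s'} \hat f(x_i \mid s')},$$

and the capacity estimate maximizes $\hat I$ over the simplex.

Numerical choices, in the order they matter:

* **Optimizer.** A Blahut-Arimoto multiplicative fixed point
  ($w_s \propto w_s 2^{D_s(w)}$) from uniform weights, which for a true
  channel increases the objective monotonically. The *empirical* objective
  is only approximately a channel MI — its per-class averages are
  Monte-Carlo weighted — and the exact BA step can dip transiently and, on
  small samples, park marginally below the optimum. The iteration is
  therefore run undamped with the best iterate kept, followed by a softmax
  BFGS polish with the analytic gradient (plus a few biased restarts when
  S is small). Both routes agree with brute-force simplex search to
  within $10^{-3}$ bits on small instances, which is the correctness
  criterion the tests enforce; monotonicity is asserted only for the exact
  discrete-channel iteration used as the fixtures' truth engine.
* **Stopping.** Capacity-gap $\max_s D_s(w) - \hat I(w) < 10^{-4}$ bits
  (converged), a 100-iteration plateau of the best objective (reported as
  not converged), or 10000 iterations.
* **Distance floor.** Zero k-th-neighbour distances (exact duplicates, which
  arise at vanishing noise) are floored at $10^{-12}$ response units.
* **Defaults** k = 5 and d = 6 follow the tuning reported for this
  estimator family; both are plain arguments, and capacity is insensitive
  to moderate k changes on the fixture battery.
* **No extrapolation.** Raw plug-in estimates are reported; no
  infinite-sample-size extrapolation is attempted. Estimates are clipped to
  $[0, \log_2 S]$, with the raw value retained in diagnostics.

The estimator is validated against channels whose information content is
known independently of it: jittered-atom discrete channels (truth = exact
Blahut-Arimoto on the transition matrix), isotropic Gaussian mixtures
(truth = adaptive quadrature in d = 1, tensor Gauss-Hermite in d = 2,
seeded Monte Carlo with reported standard error above), and constructed
trajectory toys. At 500 samples per signal the estimator recovers the
noiseless 4-ary channel to within 0.02 bits of its exact 2 bits and
Gaussian-mixture truths to within 0.1 bits once class separations reach
about 1.5 sigma. Below that — heavily overlapping classes — it
*underestimates*, by about 0.13 bits at 0.5 sigma separation: the mixture
denominator of the likelihood ratio does not share the numerator's kNN
bias structure, so the corrections that cancel in well-separated regimes
no longer do. This is a property of the plug-in kNN-mixture construction
itself (a uniform digamma correction cancels in the ratio), and it is the
regime in which absolute bit values from this estimator family should be
trusted least.

```{r estimator}
fx <- make_discrete_channel(diag(4), n_per_signal = 300, seed = 1)
est <- estimate_capacity(fx$data, k = 5)
glance(est)
fx$true_capacity_bits
```

## Response representations and sampling plans

Scalar descriptors (max response, max fold change, trapezoidal AUC) and
d-dimensional vectors run through the same `response_dataset` container.
Vectors are sampled by one of three plans: `symmetric` (d indices uniformly
spaced around the middle time point, at interior fractions j/(d+1); a
full-span variant is available via `endpoints = TRUE`), `balanced`
(per-block argmax of the pooled per-time-point variance over d equal
blocks), and `greedy` (global top-d variance indices). Variance is pooled
across all cells of all signals — one profile, hence one plan, per dataset.
All ties break toward earlier time points, so plans are deterministic; no
minimum spacing is enforced between greedy picks.

Descriptors are computed on the saved 0.1 h grid, i.e. on what an observer
of the simulation records. Fold operations (fold transform, fold change)
require an initial level above `eps_init = 1e-8`; inadmissible cells are
excluded and counted, never given infinite values.

## Subpopulations

The terminally differentiated subpopulation keeps cells with GFAP at or
above 0.8 at the *final* time point (the any-time criterion is also
exposed for the differentiation-potential metric, but transient white-noise
excursions of the GFAP reporter inflate it, so noise-level comparisons in
the tests use the terminal form). Trajectory clustering runs k-means per
signal on the full saved time courses (cells as points in R^T): greedy
kmeans++-style seeding from a fixed stream, 20 restarts of Lloyd iteration
(via `stats::kmeans`), best inertia kept, and clusters rank-labelled C1-C3
by descending mean GFAP. Rank labels are the only cross-signal
correspondence; per-label datasets across all 16 signals feed
`estimate_capacity()`, with signals dropped (and logged) when a label's
block has k + 1 or fewer cells.

## The replicated experiment

`run_replicates()` re-simulates all 16 ensembles per model with a
replicate-specific derived seed (master seed -> replicate -> model ->
signal -> cell, a counter-based scheme), so replicate spread covers both
simulation and estimation noise; `resimulate = FALSE` switches to
estimator-only replication. Condition pairs are compared with Welch's
unequal-variance t test on the replicate capacities. The default problem
size — 10 replicates of 16 ensembles x 500 cells, d = 6, k = 5 — was chosen
to match the published experimental design and runs in about ten minutes on
one CPU; asymmetric-sampling and subpopulation analyses default to the CLE
model, the model those experiments were designed around.

## What the reconstruction does and does not reproduce

Reproduced (and asserted in the test suite):

* dose-monotone mean GFAP with a crisp low-noise row, suppression of the
  terminal differentiation potential when intrinsic noise rises from LL to
  HL, extrinsic-noise-dominated fans, and noise-robust CLE- enhancement;
* multivariate (d = 6) capacities above every scalar descriptor, for all
  three models;
* the CLE model transmitting the least in the vector representations and
  AUC; fold change carrying the least information among descriptors;
* estimator correctness on all known-truth fixtures, the bound
  $0 \le C \le \log_2 16 = 4$ bits everywhere, and capacity invariance to
  coordinate permutations.

Not reproduced — these reflect the synthetic parameterisation, are left as
failing expectations rather than weakened, and should be treated as caveats
on the corresponding claims:

* the CLE model is *not* strictly lowest for max response (statistical tie
  with CLE-) or max fold change (CLE- is lowest): the reconstructed CLE-
  differentiates fully at every signal, which compresses endpoint
  descriptors while enriching kinetic ones;
* balanced/greedy sampling do not beat symmetric sampling: the pooled
  variance of the reconstruction peaks in one contiguous transition band,
  so greedy picks near-duplicate adjacent points and the symmetric interior
  grid already covers the informative region;
* cluster capacities do not order C1 > C2 > C3: at crisp signals k-means
  splits near-identical cells arbitrarily, so rank labels lose cross-signal
  meaning, and the smaller per-class sample inflates all three estimates;
* the max-based descriptors' heatmap contrast at high noise is inflated by
  running-maximum excursions, so "most dose-sensitive at LL" is asserted
  for max response and AUC as dose contrasts, and not for fold change;
* known-MI recovery holds to 0.1 bits only from moderate class separation
  upward (see the estimator section); the sub-sigma-separation settings of
  the validation battery sit outside that envelope and their checks fail
  by construction of the estimator, not of the fixtures.

More generally, the generator emulates the statistical structure the
estimator assumes (i.i.d. cells within signal, shared time grid, no
cell-cell communication or measurement noise); conclusions about real
imaging data would additionally face segmentation error, photobleaching and
temporal correlation structures none of which are modelled here.
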