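# gliacap

Channel-capacity analysis of noisy glioma differentiation signaling.

Cholera toxin (CT) induces glioma cells to differentiate into glia-like
cells, read out by the marker GFAP. `gliacap` asks how much *information*
that noisy pathway transmits: it treats the pathway as a communication
channel whose input is one of 16 composite signals — a CT dose (0, 5, 7.5,
10 ng/ml) crossed with a noise setting — and whose output is the single-cell
GFAP response. The package is for computational biologists studying
information transmission in stochastic signaling models; it provides the
full pipeline from stochastic simulation to replicated capacity estimates.

Three Ito SDE variants of a 10-state network (PKA/CREB/IL6/JAK2/STAT3 and
PI3K/AKT/GSK3-beta arms converging on a bistable, ultrasensitive cyclin D1
switch that represses GFAP) generate 500-cell trajectory ensembles:

* **AN** — additive Brownian noise at 0.1–10% of each state's scale,
* **CLE** — chemical-Langevin intrinsic noise (square-root-propensity
  terms) plus per-cell log-normal extrinsic parameter noise, with the four
  settings LL/HL/LH/HH of Table-style (sigma_int, sigma_ext) in
  {0.001, 0.1}²,
* **CLE-** — the CLE model with the cyclin D1 positive feedback removed.

The parameterisation is a synthetic reconstruction calibrated to the
published qualitative behaviour (see the methods vignette); rate values are
not measurements.

Responses are reduced either to scalar descriptors (max response, max fold
change, AUC) or to d-dimensional vectors sampled symmetrically around the
trajectory midpoint, or at maximum-variance time points ("balanced" per
d blocks, "greedy" global top-d). The capacity of each representation is
estimated by k-nearest-neighbour conditional densities

    L[s, i] = k / (m_s · c_d · r_{s,k}(x_i)^d),

whose plug-in mutual information I(w) = H(response) − H(response | signal)
is maximized over input distributions w by a Blahut–Arimoto fixed point
with a gradient polish, giving the channel capacity in bits (0 ≤ C ≤
log2 16 = 4). Subpopulation decompositions (terminal-differentiation
filtering at GFAP ≥ 0.8 and per-signal k-means trajectory clusters C1–C3)
and synthetic fixture channels with exactly known information content
(discrete, Gaussian, trajectory toys) round out the pipeline.

## Worked example

```r
library(gliacap)

model <- glioma_model("CLE")
#> <glioma_model> variant CLE, 10 states, 41 drift parameters, feedback scale 1

ensembles <- simulate_signal_grid(model, sim_config(n_cells = 200, seed = 1))
ensembles[["s13"]]
#> <trajectory_ensemble> CLE, dose 10 ng/ml, noise LL: 200 cells x 481 time points

differentiation_potential(ensembles[["s13"]], criterion = "terminal")
#> [1] 1

plan <- symmetric_plan(ensembles[[1]]$time, d = 6)
plan
#> <sampling_plan> symmetric, d = 6: indices 70, 138, 207, 275, 344, 412

dataset <- assemble_response_dataset(ensembles, plan)
dataset
#> <response_dataset> 3200 vectors x 6 dims, 16 classes (n = 200-200)

est <- estimate_capacity(dataset, k = 5)
est
#> <capacity_estimate> 2.3435 bits (MI at uniform 1.3914), S = 16, k = 5, d = 6, converged after 420 iterations
```

The 2.34 bits say that the d = 6 GFAP response vectors of this CLE
simulation can reliably resolve about 2^2.34 ≈ 5 of the 16 composite
signals — far from the 4 bits a noiseless channel would achieve, because
high intrinsic noise suppresses differentiation and extrinsic noise smears
the dose response. The optimal input weights (`tidy(est)`) show which
signals carry that information. A scalar summary of the same data transmits
less:

```r
estimate_capacity(descriptor_dataset(ensembles, "max_response"), k = 5)$capacity_bits
#> [1] 2.245512
```

`run_replicates()` scales this to the full replicated experiment (all
models, representations, sampling strategies and subpopulations, 10
re-simulated replicates), `compare_conditions()` runs Welch tests between
conditions, and `plot_trajectory_fans()` / `plot_descriptor_heatmap()` /
`plot_capacity_bars()` draw the standard figures. A thin CLI wrapper with
the same verbs lives in `exec/gliacap`.

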