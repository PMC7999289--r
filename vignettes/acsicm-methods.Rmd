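---
title: "Spatiotemporal mixture modelling of combined EEG/MEG data: model, optimizers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal mixture modelling of combined EEG/MEG data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

The electromagnetic inverse problem asks for the cortical current sources
$S(t) = (S_1(t), \dots, S_P(t))'$ underlying sensor measurements. `acsicm`
models two modalities jointly,

$$
M(t) = X_M S(t) + \epsilon_M(t), \qquad
E(t) = X_E S(t) + \epsilon_E(t), \qquad t = 1, \dots, T,
$$

with known forward operators $X_M$ ($n_M \times P$), $X_E$ ($n_E \times P$)
and Gaussian sensor noise
$\epsilon_M(t) \sim \mathrm{N}(0, \sigma_M^2 H_M)$,
$\epsilon_E(t) \sim \mathrm{N}(0, \sigma_E^2 H_E)$, where $H_M$, $H_E$ carry
the known noise correlation structure (identity by default). The problem is
ill-posed — infinitely many source configurations reproduce the data — so the
sources receive a structured prior. The $P$ cortical locations are embedded
in a regular $N_v$-voxel grid via a map $v(\cdot)$, and each voxel carries a
one-hot latent label $Z_v$ over $K$ states. Sources follow a Gaussian
mixture at the level of voxels,

$$
S_j(t) \mid Z_{v(j)} = l \;\sim\; \mathrm{N}(\mu_l(t), \alpha_l),
$$

with state 1 *inactive* ($\mu_1 \equiv 0$) and the active mean time courses
$\mu_A(t) = (\mu_2(t), \dots, \mu_K(t))'$ evolving as a first-order vector
autoregression $\mu_A(t) = A\,\mu_A(t-1) + a(t)$,
$a(t) \sim \mathrm{N}(0, \sigma_a^2 I)$, with
$\mu_A(1) \sim \mathrm{N}(0, \sigma_{\mu 1}^2 I)$. The labels follow a Potts
prior on the first-order (6-connected) voxel lattice,
$P(Z \mid \beta) \propto \exp\{\beta \sum_{h \sim j} \delta(Z_j, Z_h)\}$
with $\delta = 2 Z_j' Z_h - 1$, which rewards spatially coherent labelings;
$\beta \ge 0$ is fixed. Inverse-gamma priors sit on all variances and a
Gaussian prior on the entries of $A$.

`log_joint()` evaluates the log of the joint density of data and parameters
— the objective both optimizers maximize. Because $\beta$ is fixed, the
intractable Potts normalizing constant $G(\beta)$ shifts every configuration
equally and is omitted; reported objective values are therefore defined up
to that constant, and only comparisons at equal $\beta$ are meaningful.

# MAP estimation

## Iterated Conditional Modes

`icm_run()` is deterministic coordinate ascent: each sweep replaces every
parameter block with the mode of its full conditional, in the order
$\sigma_M^2, \sigma_E^2, \sigma_a^2, A, \alpha, \mu, S$, labels. All
conditional modes are available in closed form:

* every variance has an inverse-gamma conditional whose mode is
  `ig_conditional_mode()`, $(b + \tfrac12\mathrm{SSQ})/(a + n/2 + 1)$;
* $A$ solves a ridge-penalized regression of $\mu_A(t)$ on $\mu_A(t-1)$
  (`update_ar_matrix()`);
* each $\mu_A(t)$ solves a small $(K-1)$-dimensional linear system with
  endpoint corrections, swept in time order so each update sees
  already-updated earlier time points (Gauss–Seidel; monotonicity holds for
  any sweep order, this one matches the sequential description of the
  update equations);
* sources are updated cluster-by-cluster (see below), each cluster's shared
  time course having a Gaussian conditional;
* labels are updated by the chequerboard scheme: voxels of one lattice
  parity are conditionally independent given the other, so a whole colour
  is re-labelled simultaneously by per-voxel argmax of the log conditional
  score, computed in the log domain with ties broken to the lowest
  component index. Voxels containing no cortical location are labelled by
  the neighbour term alone.

Because every update is an exact conditional maximizer, the objective trace
is non-decreasing; the tests assert this per block update to $10^{-8}$.
Convergence is monitored by the relative Frobenius change of $S$ between
sweeps (`tol`, default $10^{-4}$; `max_sweeps` 100). Variance floors
(`jitter`, default $10^{-10}$) guard against a component collapsing onto a
perfectly fitted location; empty components revert to their prior modes.

## Dimension reduction and model selection

`cluster_locations()` groups the $P$ locations into $J \le P$ spatial
clusters (Lloyd's k-means on the 3-D coordinates, deterministic greedy
farthest-point seeding) whose members share one source time course; the
source update then works with summed forward columns per cluster. With
$J = P$ the constraint disappears. Clustering on coordinates is the most
literal reading of spatial parcellation; the feature choice is deliberately
kept out of the optimizer itself.

Running the optimizer with a deliberately generous upper bound $K$ leaves
redundant components empty; `estimate_K()` counts components holding at
least one voxel, giving a one-run estimate $\hat K \le K$ of the number of
latent states.

## Ant Colony System with ICM local search

ICM converges to the nearest local mode and is well known to be sensitive to
its starting value. `acs_icm_run()` wraps it in a population-based label
search. A pheromone matrix $\tau$ ($N_v \times K$, initialized at
$\tau_0$) encodes the learned desirability of voxel–label pairs. Each outer
iteration, every ant visits the voxels in a fresh random permutation and
assigns labels by the Ant Colony System transition rule: with probability
$q_0$ the label maximizing $\tau(s, \cdot)$ (exploitation, ties to the
lowest index), otherwise a draw proportional to $\tau(s, \cdot)$
(exploration). After each assignment the *local* rule
$\tau(s,\ell) \leftarrow (1-\rho)\tau(s,\ell) + \rho\tau_0$ is applied to
the chosen pair while the other labels at that voxel evaporate by
$(1-\rho)$, discouraging immediate re-use and sustaining exploration. Each
ant grafts its constructed labeling onto the continuous parameters carried
over from its previous solution and runs ICM to convergence; ants are
scored by `log_joint()`. After all ants finish, the *global* rule applies
the same evaporate-and-deposit arithmetic toward the best labeling (by
default the all-time incumbent; a switch selects the iteration best).

Two design details make the comparison with plain ICM sharp. First, one
designated ant re-starts each iteration from the incumbent labeling
(iteration 1: from the unmodified initial value), so the final objective is
never below a plain `icm_run()` from the same initialization — an invariant
the tests assert. Second, all randomness flows through deterministic
substreams of one master seed (`substream_seed()`), so runs are exactly
reproducible and per-ant results do not depend on execution order.
Pheromone entries are floored at the smallest positive double so that long
evaporation sequences cannot underflow to zero, preserving the strict
positivity the transition rule requires.

The outer loop stops when the incumbent's improvement over one iteration
falls below `outer_tol` (default $10^{-3}$) or after `max_outer`
iterations. Tuning defaults $(q_0, \tau_0, \rho, N_{\mathrm{ants}}) =
(0.43, 0.05, 0.64, 10)$ are the Nelder–Mead-selected values from the
evoked-response analysis this methodology was developed for; `tune_acs()`
re-optimizes $(q_0, \tau_0, \rho)$ for new data by Nelder–Mead on an
unconstrained scale (logit, log, logit), scoring each candidate by a seeded
ACS-ICM run and returning the best-evaluated point.

# Uncertainty quantification

`bootstrap_fit()` implements a nonparametric bootstrap over trials: each
replicate resamples the trial-specific time series with replacement
(independently per modality, since EEG and MEG sessions have distinct trial
sets), averages them into an evoked response and re-runs ACS-ICM.
`tmap()` divides the point estimate of per-location total power
$\sum_t \hat S_j(t)^2$ by its bootstrap standard deviation, flagging
zero-SD locations rather than emitting infinities; `ci_timecourse()` gives
pointwise percentile intervals for a location's time course. The percentile
method was chosen over BCa/normal intervals for its transparency at
moderate $B$; the method is a configuration point, not a commitment.

# The synthetic-data generator

`simulate_study()` (and its parts `make_lead_fields()`,
`make_ground_truth()`, `simulate_sensors()`, `make_trials()`) generates the
conditions under which the estimators are evaluated:

* seeded random unit-norm lead fields in place of head-model operators;
* $K_{\mathrm{true}} - 1$ disjoint contiguous active voxel blocks grown by
  breadth-first search from farthest-point seeds, the rest inactive;
* smooth Gaussian-bump or sinusoidal active mean time courses with peak
  amplitude `separation` (1 = well separated, 0.35 mimics poorly separated
  signals);
* per-location sources drawn about their component mean with variance
  `alpha_true`. The default 0.01 — deviations with SD one tenth of the unit
  peak amplitude — encodes coherent regional activity and defines the
  package's high-signal-to-noise regime. (With much larger `alpha_true`
  most of the truth's variance is location-level noise that no estimator
  could recover from a few dozen sensors, so recovery benchmarks would
  measure the generator, not the optimizer.)
* sensor noise that is independent Gaussian per sensor with variance equal
  to `noise_frac` (default 5%) of that sensor's noiseless temporal
  variance; trial-level data adds independent noise per trial so that
  averaging $n$ trials scales the noise variance by $1/n$.

What the generator does **not** emulate: realistic head geometry and
lead-field correlation structure, spatially correlated or non-Gaussian
noise, inter-trial amplitude/latency variability, and cortical-surface
(rather than lattice) adjacency. Passing tests therefore demonstrate
correctness of the machinery and ordinal behaviour of the optimizers under
clean conditions, not performance on real recordings.

# Study designs used by the tests and the acceptance script

Problem sizes were chosen so each study exercises the full pipeline at
desk scale:

* **Optimizer comparison** (20 replicates): $P = 100$ locations on a
  $3^3$ grid, $T = 30$, 20 MEG + 20 EEG sensors, $K_{\mathrm{true}} = 3$,
  5% noise, fit with $K = 3$, $\beta = 0.3$, $J = P$, ACS with 5 ants and
  5 outer iterations. One ground truth is fixed and only sensor noise is
  redrawn, so the TMSE bias–variance decomposition is with respect to a
  common truth. Both algorithms share a *neutral random-label*
  initialization (`initial_state(method = "random")`): ICM's sensitivity
  to starting values is precisely what the population search addresses,
  and from the package's data-driven k-means initialization ICM already
  reaches the mode, collapsing the comparison to ties.
* **Model selection** (30 replicates per scenario): $P = 48$, $T = 20$,
  16+16 sensors, upper bound $K = 6$, $K_{\mathrm{true}} \in \{2, 3\}$,
  compact 5-voxel active blocks, $\beta = 2$. At this scale a voxel holds
  about 2 cortical locations versus roughly 15 in a full-resolution
  analysis, so the per-voxel data term is an order of magnitude weaker
  relative to the fixed label prior; $\beta$ is raised accordingly so the
  prior's relative cohesion is comparable, and active regions occupy a
  realistic minority of the volume.
* **Bootstrap calibration**: $P = 16$ with 12+12 sensors — an identified
  regime in which the point estimator is nearly unbiased, so interval
  coverage genuinely measures the bootstrap rather than MAP shrinkage —
  50 trials with single-trial noise variance equal to the signal variance
  (realistic evoked-response trials; averaging 50 yields a clean evoked
  response), $B = 100$. The noise priors are set to $b_M = b_E = 0.01$:
  weakly informative priors must match the scale of the data, and the
  generic $b = 1$ would dominate the tiny evoked-response residual sum at
  this size, inflating the noise scale and over-shrinking the sources.

# Numerical choices and edge cases

* All densities are evaluated in the log domain; sensor quadratic forms use
  one Cholesky factorization of $H_M$, $H_E$ per fit.
* Voxel cells are half-open $[lo, hi)$ with the last cell closed along each
  axis; degenerate axes (zero coordinate spread) collapse to one slab.
  Location and voxel ids are contiguous integers from 1 in all formats.
* Label score ties break to the lowest component index everywhere
  (chequerboard update and ant construction alike), making both optimizers
  deterministic given their seeds.
* Hyperprior defaults $a_\cdot = 2$, $b_\cdot = 1$,
  $\sigma_{\mu 1}^2 = 10$, $\sigma_A^2 = 1$ are weakly informative and
  configurable; as noted above, $b_M, b_E$ should be scaled to the data's
  units when residual sums are far from unity.
* On-disk formats are delimited-text bundles (one CSV per matrix at
  `%.17g` precision, which round-trips IEEE doubles exactly, plus a JSON
  manifest) written and read by `write_dataset()` / `read_dataset()`;
  every load re-validates the container invariants.

# Limitations

The estimators are MAP point estimates: posterior uncertainty comes only
from the bootstrap, and the Potts constant's absence means objective values
are comparable only at fixed $\beta$. ACS-ICM costs roughly
$N_{\mathrm{ants}} \times$ outer-iterations ICM runs per fit; the bootstrap
multiplies that by $B$ (its replicates are seed-deterministic and safely
parallelizable). Estimating $\beta$, computing lead fields from head
geometry, structured-noise error models and random-field-theory
thresholding of T-maps are out of scope.
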