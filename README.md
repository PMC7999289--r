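# acsicm

Bayesian spatial mixture modelling of combined EEG and MEG data, with MAP
estimation by Iterated Conditional Modes (ICM) and by an Ant Colony System
metaheuristic coupled with ICM local search (ACS-ICM).

## The problem

Electromagnetic source localization estimates the cortical current sources
S(t) (P locations × T time points) that underlie the measurements observed
at an MEG array M(t) and an EEG array E(t), linked by known forward
operators: M(t) = X_M S(t) + ε_M(t), E(t) = X_E S(t) + ε_E(t). The problem
is ill-posed — many source configurations reproduce the data — so `acsicm`
regularizes it with a spatial finite mixture: the cortical locations sit in
a regular voxel grid, each voxel carries a latent label among K states
(state 1 "inactive" with mean zero), labels follow a Potts prior with fixed
inverse temperature β on the 6-connected lattice, sources are Gaussian
about their state's mean time course μ_l(t) with variance α_l, and the
active means follow a VAR(1) process μ_A(t) = A μ_A(t−1) + a(t).
Inverse-gamma priors complete the model.

Everything is estimated by maximizing the log joint posterior. ICM is fast,
deterministic coordinate ascent over closed-form full-conditional modes
(with a chequerboard scheme updating half of the labels simultaneously),
but lands in the local mode nearest its starting value. ACS-ICM wraps ICM
in a population search over labelings: artificial ants construct candidate
voxel labelings from a pheromone matrix, refine them with ICM, and
reinforce the best solution found. Running with a generous K and counting
the non-empty components afterwards (K̂) gives simultaneous model
selection. A nonparametric trial-resampling bootstrap supplies standard
errors, T-maps (point power over bootstrap SD) and percentile confidence
intervals.

The package is aimed at methodologists working on the EEG/MEG inverse
problem who need a reproducible reference implementation of this model
family, its two optimizers and its simulation benchmarks. Forward operators
are inputs; computing them from head geometry is out of scope.

## Worked example

```r
library(acsicm)

# simulate a two-modality study: 60 cortical locations in a 3x3x3 voxel
# grid, 16 MEG + 16 EEG sensors, 3 latent states, 5% sensor noise
study    <- simulate_study(P = 60, dims = c(3, 3, 3), n_M = 16, n_E = 16,
                           K_true = 3, T = 24, seed = 42)
hyper    <- hyperparameters(K = 3, beta = 0.3)
clusters <- cluster_locations(study$coords, J = 60)   # J = P: no tying
init     <- initial_state(study$dataset, study$grid, hyper, clusters,
                          seed = 1, method = "random")

icm <- icm_run(study$dataset, init, hyper, study$grid, clusters)
acs <- acs_icm_run(study$dataset, init, hyper, study$grid, clusters,
                   acs_tuning(n_ants = 4, max_outer = 4, seed = 1))
icm
#> <acsicm_fit>  iterations: 48  converged: TRUE  K-hat: 3  final log-joint: 2176.69
acs
#> <acsicm_fit>  iterations: 3  converged: TRUE  K-hat: 3  final log-joint: 2347.598

source_correlation(study$truth$S_true, icm$sources)
#> 0.953
source_correlation(study$truth$S_true, acs$sources)
#> 0.967
```

Both optimizers recover the true number of latent states (`K-hat: 3`).
From the same neutral initialization the ant-system run reaches a higher
posterior mode (2347.6 vs 2176.7) and a higher correlation with the true
sources (0.967 vs 0.953) — the ordinal behaviour the method is designed
for. `sensor_residuals()` and `residual_summary()` provide the
goodness-of-fit diagnostics; `bootstrap_fit()`, `tmap()` and
`ci_timecourse()` quantify uncertainty from trial-level data.

A command-line surface mirrors the R API
(`inst/cli/acsicm simulate|fit-icm|fit-acs|tune|bootstrap|evaluate`); every
run writes a manifest recording the resolved options and seeds.

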