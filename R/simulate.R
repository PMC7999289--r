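#' Random unit-norm lead fields
#'
#' Generates seeded surrogate forward operators with independent
#' standard-normal entries and columns scaled to unit Euclidean norm. These
#' stand in for head-model operators (which are inputs computed upstream of
#' this package) in simulation studies; the filename-free, synthetic nature
#' of these operators means simulation results are qualitative mirrors of
#' sensor-array behaviour, not reproductions of any particular montage.
#'
#' @param n_M,n_E,P Positive dimensions.
#' @param seed Integer seed.
#' @return A list with matrices `X_M` (`n_M x P`) and `X_E` (`n_E x P`).
#' @export
make_lead_fields <- function(n_M, n_E, P, seed = 1) {
  if (n_M < 1 || n_E < 1 || P < 1) stop_input("dimensions must be positive")
  with_seed(seed, {
    X_M <- matrix(stats::rnorm(n_M * P), n_M, P)
    X_E <- matrix(stats::rnorm(n_E * P), n_E, P)
    X_M <- sweep(X_M, 2, sqrt(colSums(X_M^2)), "/")
    X_E <- sweep(X_E, 2, sqrt(colSums(X_E^2)), "/")
    list(X_M = X_M, X_E = X_E)
  })
}

#' Ground-truth model instance
#'
#' Places `K_true - 1` disjoint contiguous blocks of active voxels on the
#' grid (grown by breadth-first search from well-separated seed voxels; the
#' remaining voxels are inactive), assigns each active component a smooth
#' mean time course (a Gaussian bump or a sinusoid, with peak amplitude set
#' by `separation`), and draws per-location sources independently about the
#' component means with variance `alpha_true`. `separation = 1` is the
#' well-separated regime; `0.35` mimics poorly separated signals.
#'
#' @param grid A [build_grid()] voxel grid (supplies the location map).
#' @param K_true True number of latent states, `>= 2` (one inactive).
#' @param T Number of time points.
#' @param signal_kind `"gaussian"` bumps or `"sinusoid"` waves.
#' @param separation Peak amplitude scale of the active means.
#' @param alpha_true Variance of sources about their component mean (default
#'   0.01, i.e. per-location deviations with SD one tenth of the unit peak
#'   amplitude: coherent regional activity).
#' @param block_size Voxels per active block; default
#'   `floor(N_v / (2 (K_true - 1)))`, at least 1.
#' @param seed Integer seed (source draws).
#' @return An object of class `ground_truth`: `Z_true` (`N_v x K_true`
#'   one-hot), `mu_true` (`K_true x T`, row 1 zero), `S_true` (`P x T`),
#'   `active_mask` (length-P logical), `K_true`.
#' @export
make_ground_truth <- function(grid, K_true, T, signal_kind = c("gaussian", "sinusoid"),
                              separation = 1, alpha_true = 0.01,
                              block_size = NULL, seed = 1) {
  signal_kind <- match.arg(signal_kind)
  if (K_true < 2) stop_input("K_true must be >= 2")
  Tt <- as.integer(T)
  n_blocks <- K_true - 1
  Nv <- grid$N_v
  if (n_blocks > Nv) stop_input("cannot place ", n_blocks, " blocks on ",
                                Nv, " voxels")
  block_size <- block_size %||% max(1L, Nv %/% (2L * n_blocks))

  # deterministic farthest-point block seeds on the voxel lattice
  vc <- grid$vox_coords
  seeds <- 1L
  if (n_blocks > 1) {
    mind <- rowSums(sweep(vc, 2, vc[1, ])^2)
    while (length(seeds) < n_blocks) {
      nxt <- which.max(mind)
      seeds <- c(seeds, nxt)
      mind <- pmin(mind, rowSums(sweep(vc, 2, vc[nxt, ])^2))
    }
  }
  lab_vox <- rep(1L, Nv)
  taken <- rep(FALSE, Nv)
  for (b in seq_len(n_blocks)) {
    if (taken[seeds[b]]) stop_input("cannot place ", n_blocks,
                                    " disjoint blocks on this grid")
    block <- seeds[b]
    taken[seeds[b]] <- TRUE
    frontier <- seeds[b]
    while (length(block) < block_size && length(frontier)) {
      nb <- setdiff(unique(unlist(grid$nbr[frontier])), which(taken))
      if (!length(nb)) break
      nb <- nb[seq_len(min(length(nb), block_size - length(block)))]
      taken[nb] <- TRUE
      block <- c(block, nb)
      frontier <- nb
    }
    lab_vox[block] <- b + 1L
  }

  tgrid <- seq_len(Tt)
  mu_true <- matrix(0, K_true, Tt)
  for (b in seq_len(n_blocks)) {
    l <- b + 1L
    sgn <- if (b %% 2 == 0) -1 else 1
    if (signal_kind == "gaussian") {
      ctr <- (0.25 + 0.5 * (b - 1) / max(1, n_blocks - 1)) * Tt
      wid <- Tt / 8
      mu_true[l, ] <- sgn * separation * exp(-(tgrid - ctr)^2 / (2 * wid^2))
    } else {
      mu_true[l, ] <- sgn * separation * sin(2 * pi * b * tgrid / Tt)
    }
  }

  lab_loc <- lab_vox[grid$v]
  S_true <- mu_true[lab_loc, , drop = FALSE] +
    with_seed(seed, matrix(stats::rnorm(grid$P * Tt, sd = sqrt(alpha_true)),
                           grid$P, Tt))
  Z_true <- matrix(0, Nv, K_true)
  Z_true[cbind(seq_len(Nv), lab_vox)] <- 1
  structure(list(Z_true = Z_true, mu_true = mu_true, S_true = S_true,
                 active_mask = lab_loc != 1L, K_true = as.integer(K_true),
                 lab_vox = lab_vox),
            class = "ground_truth")
}

#' Project a ground truth onto the sensor arrays
#'
#' Forms the noiseless projections `X_M S_true` and `X_E S_true` and adds
#' independent Gaussian noise at each sensor with variance equal to
#' `noise_frac` times the temporal variance of that sensor's noiseless
#' signal (default 5%); sensors with zero signal variance receive the
#' configured floor instead.
#'
#' @param truth A [make_ground_truth()] object.
#' @param X_M,X_E Forward operators.
#' @param noise_frac Nonnegative noise-variance fraction. Default 0.05.
#' @param seed Integer seed.
#' @param var_floor Noise variance used for zero-signal sensors.
#' @param coords Optional coordinates to carry into the dataset.
#' @return A [sensor_dataset()] with identity `H_M`, `H_E`.
#' @export
simulate_sensors <- function(truth, X_M, X_E, noise_frac = 0.05, seed = 1,
                             var_floor = 1e-8, coords = NULL) {
  if (noise_frac < 0) stop_input("noise_frac must be nonnegative")
  sigM <- X_M %*% truth$S_true
  sigE <- X_E %*% truth$S_true
  noise_var <- function(sig) {
    v <- noise_frac * apply(sig, 1, stats::var)
    v[v <= 0] <- if (noise_frac > 0) var_floor else 0
    v
  }
  vM <- noise_var(sigM); vE <- noise_var(sigE)
  with_seed(seed, {
    M <- sigM + matrix(stats::rnorm(length(sigM), sd = sqrt(vM)),
                       nrow(sigM))   # sd recycles per column
    E <- sigE + matrix(stats::rnorm(length(sigE), sd = sqrt(vE)),
                       nrow(sigE))
    sensor_dataset(M, E, X_M, X_E, coords = coords)
  })
}

#' Simulate trial-level sensor data
#'
#' Each trial is the noiseless projection of the truth plus an independent
#' noise draw at the single-trial noise level, so averaging `n` trials
#' reproduces the statistics of [simulate_sensors()] with noise variance
#' scaled by `1/n`.
#'
#' @inheritParams simulate_sensors
#' @param n_trials Number of trials per modality.
#' @return A [trial_data()] object.
#' @export
make_trials <- function(truth, X_M, X_E, n_trials, noise_frac = 0.05,
                        seed = 1, var_floor = 1e-8, coords = NULL) {
  if (n_trials < 1) stop_input("n_trials must be >= 1")
  sigM <- X_M %*% truth$S_true
  sigE <- X_E %*% truth$S_true
  nv <- function(sig) {
    v <- noise_frac * apply(sig, 1, stats::var)
    v[v <= 0] <- if (noise_frac > 0) var_floor else 0
    v
  }
  vM <- nv(sigM); vE <- nv(sigE)
  Tt <- ncol(sigM)
  with_seed(seed, {
    meg <- array(0, c(n_trials, nrow(sigM), Tt))
    eeg <- array(0, c(n_trials, nrow(sigE), Tt))
    for (r in seq_len(n_trials)) {
      meg[r, , ] <- sigM + matrix(stats::rnorm(length(sigM), sd = sqrt(vM)),
                                  nrow(sigM))
      eeg[r, , ] <- sigE + matrix(stats::rnorm(length(sigE), sd = sqrt(vE)),
                                  nrow(sigE))
    }
    trial_data(meg, eeg, X_M, X_E, coords = coords)
  })
}

#' Simulate a complete study instance
#'
#' Convenience wrapper bundling the full simulation pipeline under one seed:
#' uniform random cortical coordinates in the unit cube, a voxel grid, seeded
#' unit-norm lead fields, a ground truth and a noisy two-modality dataset.
#' Defaults follow the simulation design the estimators are evaluated under:
#' 5% sensor noise and well-separated Gaussian signals.
#'
#' @param P Number of cortical locations.
#' @param dims Voxel grid dimensions.
#' @param n_M,n_E Sensor counts.
#' @param K_true True number of latent states.
#' @param T Time points.
#' @param noise_frac Sensor noise fraction (default 0.05).
#' @param separation Signal separation scale (default 1).
#' @param alpha_true Source variance about component means.
#' @param signal_kind Mean time-course family.
#' @param seed Master seed; coordinates, lead fields, truth and noise use
#'   deterministic substreams of it.
#' @param truth Optional pre-built truth to reuse (so replicates can share
#'   one truth and redraw only sensor noise); must match `grid`.
#' @return A list with `dataset`, `truth`, `grid`, `coords`, `lead`.
#' @export
simulate_study <- function(P = 100, dims = c(3, 3, 3), n_M = 20, n_E = 20,
                           K_true = 3, T = 30, noise_frac = 0.05,
                           separation = 1, alpha_true = 0.01,
                           signal_kind = "gaussian", seed = 1, truth = NULL) {
  coords <- with_seed(substream_seed(seed, 1),
                      matrix(stats::runif(P * 3), P, 3))
  grid <- build_grid(coords, dims)
  lead <- make_lead_fields(n_M, n_E, P, seed = substream_seed(seed, 2))
  if (is.null(truth)) {
    truth <- make_ground_truth(grid, K_true, T, signal_kind = signal_kind,
                               separation = separation,
                               alpha_true = alpha_true,
                               seed = substream_seed(seed, 3))
  }
  dataset <- simulate_sensors(truth, lead$X_M, lead$X_E,
                              noise_frac = noise_frac,
                              seed = substream_seed(seed, 4),
                              coords = coords)
  list(dataset = dataset, truth = truth, grid = grid, coords = coords,
       lead = lead)
}
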