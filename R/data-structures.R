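#' Two-modality sensor dataset
#'
#' Bundles averaged (evoked-response) MEG and EEG sensor readings with their
#' forward operators and sensor-noise covariance structure. The forward
#' operators (lead fields) map the P cortical source amplitudes to the sensor
#' arrays; they are inputs to the inverse problem, never computed here.
#'
#' @param M Numeric matrix, `n_M x T`, MEG sensor readings.
#' @param E Numeric matrix, `n_E x T`, EEG sensor readings.
#' @param X_M Numeric matrix, `n_M x P`, MEG forward operator.
#' @param X_E Numeric matrix, `n_E x P`, EEG forward operator.
#' @param H_M,H_E Known symmetric positive-definite sensor-noise covariance
#'   structure matrices (e.g. estimated from baseline data). Default identity.
#' @param coords Optional `P x 3` matrix of cortical location coordinates.
#' @return An object of class `sensor_dataset` with elements `M`, `E`, `X_M`,
#'   `X_E`, `H_M`, `H_E`, `coords`, `n_M`, `n_E`, `P`, `T`.
#' @export
sensor_dataset <- function(M, E, X_M, X_E, H_M = NULL, H_E = NULL,
                           coords = NULL) {
  M <- as.matrix(M); E <- as.matrix(E)
  X_M <- as.matrix(X_M); X_E <- as.matrix(X_E)
  n_M <- nrow(M); n_E <- nrow(E); Tt <- ncol(M); P <- ncol(X_M)
  if (Tt < 2) stop_input("T must be at least 2 (got T = ", Tt, ")")
  check_matrix(M, "M"); check_matrix(E, "E", ncol = Tt)
  check_matrix(X_M, "X_M", nrow = n_M)
  check_matrix(X_E, "X_E", nrow = n_E, ncol = P)
  H_M <- if (is.null(H_M)) diag(n_M) else as.matrix(H_M)
  H_E <- if (is.null(H_E)) diag(n_E) else as.matrix(H_E)
  check_matrix(H_M, "H_M", nrow = n_M, ncol = n_M)
  check_matrix(H_E, "H_E", nrow = n_E, ncol = n_E)
  chol_spd(H_M, "H_M"); chol_spd(H_E, "H_E")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    check_matrix(coords, "coords", nrow = P, ncol = 3)
  }
  structure(list(M = M, E = E, X_M = X_M, X_E = X_E, H_M = H_M, H_E = H_E,
                 coords = coords, n_M = n_M, n_E = n_E, P = P, T = Tt),
            class = "sensor_dataset")
}

#' @export
print.sensor_dataset <- function(x, ...) {
  cat("<sensor_dataset>  MEG:", x$n_M, "sensors  EEG:", x$n_E,
      "sensors  P =", x$P, " T =", x$T, "\n")
  invisible(x)
}

#' Mixture model parameter state
#'
#' All model parameters except the sources: the voxel-level one-hot mixture
#' allocations `Z`, component mean time courses `mu` (row 1 is the inactive
#' component and is identically zero), component variances `alpha`, the
#' VAR(1) coefficient matrix `A` driving the active means, and the three
#' variance scalars.
#'
#' @param Z `N_v x K` one-hot allocation matrix.
#' @param mu `K x T` component means; `mu[1, ] == 0`.
#' @param alpha Length-`K` positive component variances.
#' @param A `(K-1) x (K-1)` VAR coefficient matrix for the active means.
#' @param sigma2_a,sigma2_E,sigma2_M Positive variance scalars (VAR innovation
#'   variance and the two sensor-noise scale factors).
#' @return An object of class `mixture_state`.
#' @export
mixture_state <- function(Z, mu, alpha, A, sigma2_a, sigma2_E, sigma2_M) {
  Z <- as.matrix(Z); mu <- as.matrix(mu); A <- as.matrix(A)
  check_one_hot(Z)
  K <- ncol(Z)
  if (nrow(mu) != K) stop_input("mu must have K = ", K, " rows")
  if (any(mu[1, ] != 0)) stop_input("mu[1, ] must be identically zero")
  if (length(alpha) != K || any(alpha <= 0))
    stop_input("alpha must be K positive values")
  check_matrix(A, "A", nrow = K - 1, ncol = K - 1)
  for (nm in c("sigma2_a", "sigma2_E", "sigma2_M")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0)
      stop_input(nm, " must be a positive scalar")
  }
  structure(list(Z = Z, mu = mu, alpha = as.numeric(alpha), A = A,
                 sigma2_a = sigma2_a, sigma2_E = sigma2_E,
                 sigma2_M = sigma2_M),
            class = "mixture_state")
}

#' Model hyperparameters
#'
#' Fixed quantities of the prior: the component-count upper bound `K`, the
#' Potts inverse temperature `beta` (larger values enforce spatially smoother
#' labelings), inverse-gamma prior parameters for all variance parameters, the
#' (fixed) prior variance of the initial active mean, and the prior variance
#' of the VAR coefficients. The inverse-gamma defaults `a = 2, b = 1` are
#' weakly informative (prior mean 1, infinite variance).
#'
#' @param K Integer upper bound on the number of mixture components, `>= 2`.
#'   Model selection runs with `K` deliberately large and counts the non-empty
#'   components afterwards (see [estimate_K()]).
#' @param beta Nonnegative Potts inverse temperature. Default 0.3.
#' @param a_E,b_E,a_M,b_M,a_alpha,b_alpha,a_a,b_a Positive inverse-gamma prior
#'   parameters for `sigma2_E`, `sigma2_M`, the `alpha_l`, and `sigma2_a`.
#' @param sigma2_mu1 Positive prior variance of the initial active means.
#' @param sigma2_A Positive prior variance of each VAR coefficient.
#' @return An object of class `acsicm_hyper`.
#' @export
hyperparameters <- function(K, beta = 0.3, a_E = 2, b_E = 1, a_M = 2, b_M = 1,
                            a_alpha = 2, b_alpha = 1, a_a = 2, b_a = 1,
                            sigma2_mu1 = 10, sigma2_A = 1) {
  if (K < 2 || K != round(K)) stop_input("K must be an integer >= 2")
  if (beta < 0) stop_input("beta must be nonnegative")
  pos <- c(a_E = a_E, b_E = b_E, a_M = a_M, b_M = b_M, a_alpha = a_alpha,
           b_alpha = b_alpha, a_a = a_a, b_a = b_a,
           sigma2_mu1 = sigma2_mu1, sigma2_A = sigma2_A)
  if (any(pos <= 0))
    stop_input("hyperparameter(s) ", paste(names(pos)[pos <= 0], collapse = ", "),
               " must be strictly positive")
  structure(c(list(K = as.integer(K), beta = beta), as.list(pos)),
            class = "acsicm_hyper")
}

#' ICM convergence settings
#'
#' @param tol Positive relative-change threshold on the Frobenius norm of the
#'   source matrix between consecutive sweeps (the convergence monitor).
#' @param max_sweeps Maximum number of full ICM sweeps.
#' @param jitter Numerical floor applied to updated variances, preventing
#'   degeneracy when a component fits its locations perfectly.
#' @return An object of class `icm_settings`.
#' @export
icm_settings <- function(tol = 1e-4, max_sweeps = 100, jitter = 1e-10) {
  if (tol <= 0) stop_input("tol must be positive")
  if (max_sweeps < 1) stop_input("max_sweeps must be >= 1")
  if (jitter <= 0) stop_input("jitter must be positive")
  structure(list(tol = tol, max_sweeps = as.integer(max_sweeps),
                 jitter = jitter),
            class = "icm_settings")
}

#' Ant Colony System tuning parameters
#'
#' Defaults are the Nelder-Mead-selected values reported for the
#' face-perception evoked-response analysis: `(q0, tau0, rho, n_ants) =
#' (0.43, 0.05, 0.64, 10)`.
#'
#' @param q0 Exploitation probability in (0,1): with probability `q0` an ant
#'   picks the label maximizing the pheromone, otherwise it samples
#'   proportionally to pheromone.
#' @param tau0 Positive initial/deposit pheromone level.
#' @param rho Evaporation rate in (0,1).
#' @param n_ants Positive integer number of ants per outer iteration.
#' @param max_outer Maximum outer (colony) iterations.
#' @param outer_tol Positive absolute improvement threshold on the incumbent
#'   objective below which the outer loop stops.
#' @param seed Integer master seed for all ant randomness.
#' @param global_best Which labeling receives the global pheromone deposit:
#'   the all-time `"incumbent"` (default) or the current `"iteration"` best.
#' @return An object of class `acs_tuning`.
#' @export
acs_tuning <- function(q0 = 0.43, tau0 = 0.05, rho = 0.64, n_ants = 10,
                       max_outer = 10, outer_tol = 1e-3, seed = 1,
                       global_best = c("incumbent", "iteration")) {
  if (q0 <= 0 || q0 >= 1) stop_input("q0 must lie in (0, 1)")
  if (tau0 <= 0) stop_input("tau0 must be positive")
  if (rho <= 0 || rho >= 1) stop_input("rho must lie in (0, 1)")
  if (n_ants < 1) stop_input("n_ants must be >= 1")
  if (max_outer < 1) stop_input("max_outer must be >= 1")
  if (outer_tol <= 0) stop_input("outer_tol must be positive")
  structure(list(q0 = q0, tau0 = tau0, rho = rho, n_ants = as.integer(n_ants),
                 max_outer = as.integer(max_outer), outer_tol = outer_tol,
                 seed = as.integer(seed),
                 global_best = match.arg(global_best)),
            class = "acs_tuning")
}

#' Trial-level two-modality data
#'
#' Per-trial sensor time series prior to averaging, as used by the
#' nonparametric bootstrap. The MEG and EEG trial sets may have different
#' numbers of trials (the modalities are typically recorded in separate
#' sessions).
#'
#' @param meg_trials Array `n_trials_M x n_M x T`.
#' @param eeg_trials Array `n_trials_E x n_E x T`.
#' @param X_M,X_E Forward operators as in [sensor_dataset()].
#' @param H_M,H_E Optional noise structure matrices (default identity).
#' @param coords Optional `P x 3` coordinates.
#' @return An object of class `trial_data`.
#' @export
trial_data <- function(meg_trials, eeg_trials, X_M, X_E,
                       H_M = NULL, H_E = NULL, coords = NULL) {
  if (length(dim(meg_trials)) != 3 || length(dim(eeg_trials)) != 3)
    stop_input("meg_trials and eeg_trials must be 3-d arrays (trial, sensor, time)")
  if (dim(meg_trials)[1] < 1 || dim(eeg_trials)[1] < 1)
    stop_input("need at least one trial per modality")
  if (dim(meg_trials)[3] != dim(eeg_trials)[3])
    stop_input("trial arrays disagree on T")
  X_M <- as.matrix(X_M); X_E <- as.matrix(X_E)
  if (dim(meg_trials)[2] != nrow(X_M))
    stop_input("meg_trials sensor dimension does not match X_M")
  if (dim(eeg_trials)[2] != nrow(X_E))
    stop_input("eeg_trials sensor dimension does not match X_E")
  structure(list(meg_trials = meg_trials, eeg_trials = eeg_trials,
                 X_M = X_M, X_E = X_E, H_M = H_M, H_E = H_E, coords = coords,
                 n_M = nrow(X_M), n_E = nrow(X_E), P = ncol(X_M),
                 T = dim(meg_trials)[3],
                 n_trials_M = dim(meg_trials)[1],
                 n_trials_E = dim(eeg_trials)[1]),
            class = "trial_data")
}

# internal fit-result constructor
new_fit_result <- function(state, sources, objective_trace, k_hat, converged,
                           iterations, seed = NA_integer_) {
  structure(list(state = state, sources = sources,
                 objective_trace = objective_trace, k_hat = k_hat,
                 converged = converged, iterations = iterations, seed = seed),
            class = "acsicm_fit")
}

#' @export
print.acsicm_fit <- function(x, ...) {
  cat("<acsicm_fit>  iterations:", x$iterations,
      " converged:", x$converged,
      " K-hat:", x$k_hat,
      " final log-joint:", format(utils::tail(x$objective_trace, 1)), "\n")
  invisible(x)
}
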