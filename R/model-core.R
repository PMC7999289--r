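# log inverse-gamma density
ig_logpdf <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

#' Log kernel of the Potts prior
#'
#' Evaluates `beta * sum over neighbour pairs of delta(Z_j, Z_h)` where
#' `delta = +1` when the two voxels carry the same label and `-1` otherwise
#' (equivalently `2 Z_j' Z_h - 1` for one-hot rows). The normalizing constant
#' `G(beta)` is omitted: `beta` is held fixed throughout, so the constant
#' shifts every configuration's objective equally.
#'
#' @param Z `N_v x K` one-hot label matrix.
#' @param beta Nonnegative inverse temperature.
#' @param grid A [build_grid()] voxel grid supplying the neighbour pairs.
#' @return A scalar, the log kernel.
#' @export
potts_log_kernel <- function(Z, beta, grid) {
  check_one_hot(Z)
  if (nrow(Z) != grid$N_v)
    stop_input("Z has ", nrow(Z), " rows; grid has N_v = ", grid$N_v)
  pairs <- grid$pairs
  if (nrow(pairs) == 0L) return(0)
  lab <- max.col(Z, ties.method = "first")
  n_eq <- sum(lab[pairs[, 1]] == lab[pairs[, 2]])
  beta * (2 * n_eq - nrow(pairs))
}

#' Sensor-space residuals
#'
#' Exact differences between the observed sensor data and the forward
#' projection of a source estimate: `eps_M(t) = M(t) - X_M S(t)` and
#' `eps_E(t) = E(t) - X_E S(t)`, with no scaling. Under the model these
#' should look like draws from mean-zero Gaussians if the fit is adequate.
#'
#' @param dataset A [sensor_dataset()].
#' @param sources `P x T` source matrix.
#' @return A list with elements `eps_E` (`n_E x T`) and `eps_M` (`n_M x T`).
#' @export
sensor_residuals <- function(dataset, sources) {
  sources <- as.matrix(sources)
  check_matrix(sources, "sources", nrow = dataset$P, ncol = dataset$T)
  list(eps_E = dataset$E - dataset$X_E %*% sources,
       eps_M = dataset$M - dataset$X_M %*% sources)
}

#' Log joint posterior objective
#'
#' Evaluates the log of the unnormalized joint density of data and parameters
#' under the spatiotemporal mixture model: the two Gaussian sensor
#' likelihoods, the inverse-gamma priors on the noise scales, the voxel-level
#' Gaussian mixture over sources, the VAR(1) prior on the active means plus
#' its initial-state term, the Potts log kernel (normalizing constant
#' omitted; see [potts_log_kernel()]), the inverse-gamma priors on the
#' component variances and on the VAR innovation variance, and the Gaussian
#' prior on the VAR coefficients. This is the objective maximized by both
#' [icm_run()] and [acs_icm_run()]; reported values are defined up to the
#' constant `-log G(beta)`.
#'
#' @param dataset A [sensor_dataset()].
#' @param state A [mixture_state()].
#' @param sources `P x T` source matrix.
#' @param grid A [build_grid()] voxel grid consistent with the dataset.
#' @param hyper A [hyperparameters()] object.
#' @param terms If `TRUE`, return the named vector of additive terms instead
#'   of their sum.
#' @return A finite scalar (or named vector when `terms = TRUE`).
#' @export
log_joint <- function(dataset, state, sources, grid, hyper, terms = FALSE) {
  sources <- as.matrix(sources)
  P <- dataset$P; Tt <- dataset$T; K <- hyper$K
  check_matrix(sources, "sources", nrow = P, ncol = Tt)
  if (ncol(state$Z) != K) stop_input("state has ", ncol(state$Z),
                                     " components; hyper$K = ", K)
  if (nrow(state$Z) != grid$N_v) stop_input("state$Z rows != grid N_v")
  if (length(grid$v) != P) stop_input("grid maps ", length(grid$v),
                                      " locations; dataset has P = ", P)
  if (ncol(state$mu) != Tt) stop_input("state$mu must have T columns")

  cholM <- chol_spd(dataset$H_M, "H_M")
  cholE <- chol_spd(dataset$H_E, "H_E")
  ldHM <- 2 * sum(log(diag(cholM)))
  ldHE <- 2 * sum(log(diag(cholE)))

  RM <- dataset$M - dataset$X_M %*% sources
  RE <- dataset$E - dataset$X_E %*% sources
  qM <- sum(quad_forms(cholM, RM))
  qE <- sum(quad_forms(cholE, RE))
  lik_M <- -Tt * dataset$n_M / 2 * log(2 * pi * state$sigma2_M) -
    Tt / 2 * ldHM - qM / (2 * state$sigma2_M)
  lik_E <- -Tt * dataset$n_E / 2 * log(2 * pi * state$sigma2_E) -
    Tt / 2 * ldHE - qE / (2 * state$sigma2_E)

  prior_sigma_M <- ig_logpdf(state$sigma2_M, hyper$a_M, hyper$b_M)
  prior_sigma_E <- ig_logpdf(state$sigma2_E, hyper$a_E, hyper$b_E)

  # mixture term: each location contributes the Gaussian density of its
  # voxel's assigned component
  lab <- max.col(state$Z, ties.method = "first")[grid$v]
  al <- state$alpha[lab]
  dev2 <- rowSums((sources - state$mu[lab, , drop = FALSE])^2)
  mixture <- sum(-Tt / 2 * log(2 * pi * al) - dev2 / (2 * al))

  muA <- state$mu[-1, , drop = FALSE]
  innov <- muA[, -1, drop = FALSE] -
    state$A %*% muA[, -Tt, drop = FALSE]
  var_term <- -(Tt - 1) * (K - 1) / 2 * log(2 * pi * state$sigma2_a) -
    sum(innov^2) / (2 * state$sigma2_a)
  init_term <- -(K - 1) / 2 * log(2 * pi * hyper$sigma2_mu1) -
    sum(muA[, 1]^2) / (2 * hyper$sigma2_mu1)

  potts <- potts_log_kernel(state$Z, hyper$beta, grid)
  prior_alpha <- sum(ig_logpdf(state$alpha, hyper$a_alpha, hyper$b_alpha))
  prior_A <- -(K - 1)^2 / 2 * log(2 * pi * hyper$sigma2_A) -
    sum(state$A^2) / (2 * hyper$sigma2_A)
  prior_sigma_a <- ig_logpdf(state$sigma2_a, hyper$a_a, hyper$b_a)

  out <- c(lik_M = lik_M, lik_E = lik_E,
           prior_sigma_M = prior_sigma_M, prior_sigma_E = prior_sigma_E,
           mixture = mixture, var_term = var_term, init_term = init_term,
           potts = potts, prior_alpha = prior_alpha, prior_A = prior_A,
           prior_sigma_a = prior_sigma_a)
  if (!all(is.finite(out)))
    stop_input("log_joint is non-finite in term(s): ",
               paste(names(out)[!is.finite(out)], collapse = ", "))
  if (terms) out else sum(out)
}
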