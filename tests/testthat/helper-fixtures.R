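# Shared fixture builders and the independent log-joint oracle. The oracle
# deliberately takes different numerical routes from the package (solve/det
# instead of Cholesky backsolves, dgamma on the reciprocal instead of a
# hand-written inverse-gamma density, explicit loops instead of vectorized
# aggregation) so agreement is evidence, not tautology.

random_spd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(n)
}

# random one-hot matrix
random_onehot <- function(Nv, K) {
  Z <- matrix(0, Nv, K)
  Z[cbind(seq_len(Nv), sample.int(K, Nv, replace = TRUE))] <- 1
  Z
}

# a small random model instance on a 2 x 2 x 2 grid
tiny_instance <- function(seed, n_M = 4, n_E = 4, P = 10, T = 5, K = 3,
                          dims = c(2, 2, 2), spd_H = TRUE, beta = 0.3) {
  set.seed(seed)
  coords <- matrix(runif(P * 3), P, 3)
  grid <- build_grid(coords, dims)
  X_M <- matrix(rnorm(n_M * P), n_M, P)
  X_E <- matrix(rnorm(n_E * P), n_E, P)
  H_M <- if (spd_H) random_spd(n_M) else diag(n_M)
  H_E <- if (spd_H) random_spd(n_E) else diag(n_E)
  M <- matrix(rnorm(n_M * T), n_M, T)
  E <- matrix(rnorm(n_E * T), n_E, T)
  dataset <- sensor_dataset(M, E, X_M, X_E, H_M, H_E, coords = coords)
  state <- mixture_state(
    Z = random_onehot(grid$N_v, K),
    mu = rbind(0, matrix(rnorm((K - 1) * T), K - 1, T)),
    alpha = runif(K, 0.3, 2),
    A = matrix(rnorm((K - 1)^2, sd = 0.4), K - 1, K - 1),
    sigma2_a = runif(1, 0.3, 2),
    sigma2_E = runif(1, 0.3, 2),
    sigma2_M = runif(1, 0.3, 2))
  sources <- matrix(rnorm(P * T), P, T)
  hyper <- hyperparameters(K = K, beta = beta, a_E = 2.5, b_E = 1.2,
                           a_M = 2.2, b_M = 0.8, a_alpha = 2, b_alpha = 1,
                           a_a = 3, b_a = 1.5, sigma2_mu1 = 5, sigma2_A = 2)
  list(dataset = dataset, state = state, sources = sources, grid = grid,
       hyper = hyper, coords = coords)
}

# independent multivariate normal log density
oracle_mvn <- function(x, mean, Sigma) {
  d <- length(x)
  r <- x - mean
  -d / 2 * log(2 * pi) - 0.5 * log(det(Sigma)) -
    0.5 * drop(t(r) %*% solve(Sigma) %*% r)
}

# independent inverse-gamma log density via the gamma density of 1/x
oracle_ig <- function(x, a, b) {
  stats::dgamma(1 / x, shape = a, rate = b, log = TRUE) - 2 * log(x)
}

# term-by-term evaluation of the log joint objective
oracle_log_joint <- function(dataset, state, sources, grid, hyper) {
  Tt <- dataset$T; K <- hyper$K; P <- dataset$P
  total <- 0
  for (t in seq_len(Tt)) {
    total <- total + oracle_mvn(dataset$M[, t], dataset$X_M %*% sources[, t],
                                state$sigma2_M * dataset$H_M)
    total <- total + oracle_mvn(dataset$E[, t], dataset$X_E %*% sources[, t],
                                state$sigma2_E * dataset$H_E)
  }
  total <- total + oracle_ig(state$sigma2_M, hyper$a_M, hyper$b_M)
  total <- total + oracle_ig(state$sigma2_E, hyper$a_E, hyper$b_E)
  for (j in seq_len(P)) {
    vj <- grid$v[j]
    for (t in seq_len(Tt)) {
      for (l in seq_len(K)) {
        if (state$Z[vj, l] == 1)
          total <- total + stats::dnorm(sources[j, t], state$mu[l, t],
                                        sqrt(state$alpha[l]), log = TRUE)
      }
    }
  }
  muA <- state$mu[-1, , drop = FALSE]
  for (t in 2:Tt) {
    total <- total + oracle_mvn(muA[, t], state$A %*% muA[, t - 1],
                                state$sigma2_a * diag(K - 1))
  }
  total <- total + oracle_mvn(muA[, 1], rep(0, K - 1),
                              hyper$sigma2_mu1 * diag(K - 1))
  for (p in seq_len(nrow(grid$pairs))) {
    zi <- state$Z[grid$pairs[p, 1], ]
    zh <- state$Z[grid$pairs[p, 2], ]
    total <- total + hyper$beta * (2 * sum(zi * zh) - 1)
  }
  for (l in seq_len(K))
    total <- total + oracle_ig(state$alpha[l], hyper$a_alpha, hyper$b_alpha)
  total <- total + sum(stats::dnorm(state$A, 0, sqrt(hyper$sigma2_A),
                                    log = TRUE))
  total <- total + oracle_ig(state$sigma2_a, hyper$a_a, hyper$b_a)
  total
}

# shared replicate experiment for the ordinal optimizer comparison
# (built lazily, reused across acceptance blocks)
.acsicm_test_cache <- new.env(parent = emptyenv())

comparison_experiment <- function(n_rep = 20) {
  key <- paste0("cmp", n_rep)
  if (!is.null(.acsicm_test_cache[[key]])) return(.acsicm_test_cache[[key]])
  base <- simulate_study(P = 100, dims = c(3, 3, 3), n_M = 20, n_E = 20,
                         K_true = 3, T = 30, noise_frac = 0.05, seed = 9001)
  hy <- hyperparameters(K = 3, beta = 0.3)
  cl <- cluster_locations(base$coords, 100)
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    ds <- simulate_sensors(base$truth, base$lead$X_M, base$lead$X_E,
                           noise_frac = 0.05,
                           seed = substream_seed(9001, 100, r),
                           coords = base$coords)
    init <- initial_state(ds, base$grid, hy, cl,
                          seed = substream_seed(9001, 200, r),
                          method = "random")
    icm <- icm_run(ds, init, hy, base$grid, cl)
    acs <- acs_icm_run(ds, init, hy, base$grid, cl,
                       acs_tuning(n_ants = 5, max_outer = 5,
                                  seed = substream_seed(9001, 300, r)))
    out[[r]] <- list(icm = icm, acs = acs)
  }
  res <- list(base = base, fits = out)
  .acsicm_test_cache[[key]] <- res
  res
}
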