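test_that("log joint matches the closed-form hand sum at the zero configuration", {
  # single voxel, 1+1 sensors, T = 2, K = 2, everything zero, unit variances
  coords <- matrix(0.5, 1, 3)
  grid <- build_grid(coords, c(1, 1, 1))
  dataset <- sensor_dataset(M = matrix(0, 1, 2), E = matrix(0, 1, 2),
                            X_M = matrix(1, 1, 1), X_E = matrix(1, 1, 1),
                            coords = coords)
  state <- mixture_state(Z = matrix(c(1, 0), 1, 2), mu = matrix(0, 2, 2),
                         alpha = c(1, 1), A = matrix(0, 1, 1),
                         sigma2_a = 1, sigma2_E = 1, sigma2_M = 1)
  hyper <- hyperparameters(K = 2, beta = 0.3, sigma2_mu1 = 10, sigma2_A = 1)
  # every Gaussian contributes -(dim/2) log 2*pi*var, every IG(2,1) density
  # at 1 contributes 2*log(1) - lgamma(2) - 3*log(1) - 1 = -1
  expected <- -log(2 * pi) +                 # MEG likelihood, two time points
    -log(2 * pi) +                           # EEG likelihood
    -log(2 * pi) +                           # mixture term, one location
    -0.5 * log(2 * pi) +                     # VAR innovation at t = 2
    -0.5 * log(2 * pi * 10) +                # initial active mean
    -0.5 * log(2 * pi) +                     # prior on the single A entry
    -5                                       # five IG(2,1) densities at 1
  expect_equal(log_joint(dataset, state, matrix(0, 1, 2), grid, hyper),
               expected, tolerance = 1e-12)
})

test_that("log joint agrees with the independent term-by-term oracle", {
  for (seed in 1:20) {
    inst <- tiny_instance(seed)
    got <- log_joint(inst$dataset, inst$state, inst$sources, inst$grid,
                     inst$hyper)
    want <- oracle_log_joint(inst$dataset, inst$state, inst$sources,
                             inst$grid, inst$hyper)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("perturbing one source entry moves only the likelihood and mixture terms", {
  inst <- tiny_instance(31)
  t0 <- log_joint(inst$dataset, inst$state, inst$sources, inst$grid,
                  inst$hyper, terms = TRUE)
  S2 <- inst$sources
  S2[3, 2] <- S2[3, 2] + 0.7
  t1 <- log_joint(inst$dataset, inst$state, S2, inst$grid, inst$hyper,
                  terms = TRUE)
  moved <- c("lik_M", "lik_E", "mixture")
  fixed <- setdiff(names(t0), moved)
  expect_identical(t1[fixed], t0[fixed])
  expect_equal(sum(t1) - sum(t0), sum(t1[moved]) - sum(t0[moved]))
  # and the moved-term delta matches the oracle's delta exactly
  d_oracle <- oracle_log_joint(inst$dataset, inst$state, S2, inst$grid,
                               inst$hyper) -
    oracle_log_joint(inst$dataset, inst$state, inst$sources, inst$grid,
                     inst$hyper)
  expect_equal(sum(t1) - sum(t0), d_oracle, tolerance = 1e-9)
})

test_that("Potts log kernel handles the pairwise fixtures", {
  coords <- rbind(c(0.25, 0.5, 0.5), c(0.75, 0.5, 0.5))
  grid <- build_grid(coords, c(2, 1, 1))
  same <- rbind(c(1, 0), c(1, 0))
  diff <- rbind(c(1, 0), c(0, 1))
  expect_equal(potts_log_kernel(same, 0.3, grid), 0.3)
  expect_equal(potts_log_kernel(diff, 0.3, grid), -0.3)
})

test_that("Potts kernel on a uniform 3x3x3 grid counts all 54 neighbour pairs", {
  set.seed(4)
  coords <- matrix(runif(60), 20, 3)
  grid <- build_grid(coords, c(3, 3, 3))
  expect_equal(nrow(grid$pairs), 54)
  Z <- matrix(0, 27, 3); Z[, 1] <- 1
  expect_equal(potts_log_kernel(Z, 0.1, grid), 5.4)
})

test_that("Potts kernel is invariant under global label permutations", {
  set.seed(11)
  coords <- matrix(runif(90), 30, 3)
  grid <- build_grid(coords, c(3, 3, 3))
  for (i in 1:10) {
    Z <- random_onehot(27, 4)
    perm <- sample(4)
    expect_equal(potts_log_kernel(Z[, perm], 0.7, grid),
                 potts_log_kernel(Z, 0.7, grid))
  }
  expect_error(potts_log_kernel(matrix(1, 27, 2), 0.3, grid), "one-hot")
})

test_that("sensor residuals are exact differences and linear", {
  inst <- tiny_instance(5)
  r0 <- sensor_residuals(inst$dataset, matrix(0, 10, 5))
  expect_identical(r0$eps_M, inst$dataset$M)
  expect_identical(r0$eps_E, inst$dataset$E)

  S <- inst$sources
  exact <- sensor_dataset(inst$dataset$X_M %*% S, inst$dataset$X_E %*% S,
                          inst$dataset$X_M, inst$dataset$X_E)
  rz <- sensor_residuals(exact, S)
  expect_equal(rz$eps_M, matrix(0, 4, 5), ignore_attr = TRUE)
  expect_equal(rz$eps_E, matrix(0, 4, 5), ignore_attr = TRUE)

  # linearity: residuals at S1 + S2 plus the projection of S2 recovers
  # residuals at S1
  S2 <- matrix(rnorm(50), 10, 5)
  r12 <- sensor_residuals(inst$dataset, S + S2)
  r1 <- sensor_residuals(inst$dataset, S)
  expect_equal(r12$eps_M + inst$dataset$X_M %*% S2, r1$eps_M)
  expect_equal(r12$eps_E + inst$dataset$X_E %*% S2, r1$eps_E)

  expect_error(sensor_residuals(inst$dataset, matrix(0, 9, 5)), "rows")
})

test_that("log joint is invariant to location order and empty-component relabeling", {
  inst <- tiny_instance(77, K = 4)
  # make components 3 and 4 empty, then swap them (with mu, alpha and the
  # VAR matrix permuted consistently)
  st <- inst$state
  lab <- max.col(st$Z)
  lab[lab > 2] <- 1
  st$Z <- matrix(0, nrow(st$Z), 4)
  st$Z[cbind(seq_along(lab), lab)] <- 1
  base <- log_joint(inst$dataset, st, inst$sources, inst$grid, inst$hyper)

  perm <- c(1, 2, 4, 3)
  permA <- c(1, 3, 2)      # active-component permutation for mu_A rows and A
  st2 <- st
  st2$Z <- st$Z[, perm]
  st2$mu <- st$mu[perm, ]
  st2$alpha <- st$alpha[perm]
  st2$A <- st$A[permA, permA]
  expect_equal(log_joint(inst$dataset, st2, inst$sources, inst$grid,
                         inst$hyper), base)

  # permuting the cortical locations consistently leaves the value unchanged
  p <- sample(10)
  ds2 <- sensor_dataset(inst$dataset$M, inst$dataset$E,
                        inst$dataset$X_M[, p], inst$dataset$X_E[, p],
                        inst$dataset$H_M, inst$dataset$H_E,
                        coords = inst$coords[p, ])
  grid2 <- build_grid(inst$coords[p, ], c(2, 2, 2))
  expect_equal(log_joint(ds2, st, inst$sources[p, ], grid2, inst$hyper),
               base)
})

test_that("log joint rejects inconsistent input", {
  inst <- tiny_instance(8)
  expect_error(log_joint(inst$dataset, inst$state, inst$sources[, 1:4],
                         inst$grid, inst$hyper), "columns")
  bad <- inst$dataset
  bad$H_M <- -diag(4)
  expect_error(log_joint(bad, inst$state, inst$sources, inst$grid,
                         inst$hyper), "positive definite")
  expect_error(mixture_state(inst$state$Z, inst$state$mu,
                             c(-1, 1, 1), inst$state$A, 1, 1, 1),
               "alpha")
})
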