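test_that("pheromone initialization and transition start uniform", {
  ph <- initialize_pheromone(8, 3, 0.05)
  expect_equal(ph, matrix(0.05, 8, 3))
  expect_error(initialize_pheromone(8, 3, 0), "positive")
  expect_equal(ph[1, ] / sum(ph[1, ]), rep(1 / 3, 3))
})

test_that("local and global updates reproduce the evaporate-and-deposit arithmetic", {
  tn <- acs_tuning(q0 = 0.43, tau0 = 0.05, rho = 0.64)
  ph <- matrix(0.4, 2, 3)
  up <- local_pheromone_update(ph, 1, 2, tn)
  expect_equal(up[1, 2], 0.36 * 0.4 + 0.64 * 0.05)   # 0.176
  expect_equal(up[1, 1], 0.36 * 0.4)                 # 0.144
  expect_equal(up[2, ], ph[2, ])                     # other voxels untouched

  # rho -> 1 drives the chosen entry to tau0 exactly
  tn1 <- acs_tuning(rho = 1 - 1e-12, tau0 = 0.05)
  up1 <- local_pheromone_update(ph, 1, 2, tn1)
  expect_equal(up1[1, 2], 0.05, tolerance = 1e-9)

  Zb <- rbind(c(0, 1, 0), c(1, 0, 0))
  gl <- global_pheromone_update(ph, Zb, tn)
  expect_equal(gl[1, ], c(0.144, 0.176, 0.144))
  expect_equal(gl[2, ], c(0.176, 0.144, 0.144))
})

test_that("repeated global updates converge to tau0 on the best labels, keeping positivity", {
  tn <- acs_tuning(rho = 0.64, tau0 = 0.05)
  ph <- matrix(runif(12, 0.01, 1), 4, 3)
  cap <- max(tn$tau0, max(ph))
  Zb <- random_onehot(4, 3)
  lab <- max.col(Zb)
  for (i in 1:10000) ph <- global_pheromone_update(ph, Zb, tn)
  expect_true(all(ph > 0))
  expect_true(all(ph <= cap + 1e-12))
  expect_equal(ph[cbind(1:4, lab)], rep(0.05, 4), tolerance = 1e-10)
  expect_true(all(ph[cbind(1:4, max.col(1 - Zb))] < 1e-10))
})

test_that("construction exploits the argmax and breaks ties to the lowest label", {
  ph <- matrix(rep(c(0.2, 0.5, 0.3), each = 6), 6, 3)
  tn <- acs_tuning(q0 = 1 - 1e-9)
  out <- construct_labeling(ph, tn, seed = 1)
  expect_equal(max.col(out$Z), rep(2, 6))
  # constant field: argmax ties resolve to component 1 everywhere
  flat <- initialize_pheromone(6, 3, 0.05)
  out2 <- construct_labeling(flat, tn, seed = 2)
  expect_equal(max.col(out2$Z), rep(1, 6))
  # local updates were applied while constructing
  expect_false(identical(out$pheromone, ph))
})

test_that("exploration samples labels proportionally to pheromone", {
  n <- 1e5
  ph <- matrix(rep(c(0.2, 0.5, 0.3), each = n), n, 3)
  tn <- acs_tuning(q0 = 1e-12)
  out <- construct_labeling(ph, tn, seed = 3)
  freq <- colMeans(out$Z)
  for (l in 1:3) {
    p <- c(0.2, 0.5, 0.3)[l]
    expect_lt(abs(freq[l] - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("a single incumbent-seeded ant reduces ACS-ICM to plain ICM", {
  st <- simulate_study(P = 30, dims = c(2, 2, 2), n_M = 10, n_E = 10,
                       K_true = 2, T = 10, seed = 3003)
  hy <- hyperparameters(K = 2)
  cl <- cluster_locations(st$coords, 30)
  init <- initial_state(st$dataset, st$grid, hy, cl, seed = 4)
  icm <- icm_run(st$dataset, init, hy, st$grid, cl)
  acs <- acs_icm_run(st$dataset, init, hy, st$grid, cl,
                     acs_tuning(n_ants = 1, max_outer = 1, seed = 9))
  expect_equal(acs$sources, icm$sources)
  expect_equal(utils::tail(acs$objective_trace, 1),
               utils::tail(icm$objective_trace, 1))
})

test_that("ACS-ICM is reproducible and never falls below ICM from the same start", {
  st <- simulate_study(P = 36, dims = c(2, 2, 2), n_M = 12, n_E = 12,
                       K_true = 3, T = 12, seed = 3004)
  hy <- hyperparameters(K = 3)
  cl <- cluster_locations(st$coords, 36)
  init <- initial_state(st$dataset, st$grid, hy, cl, seed = 4,
                        method = "random")
  tn <- acs_tuning(n_ants = 3, max_outer = 3, seed = 17)
  a1 <- acs_icm_run(st$dataset, init, hy, st$grid, cl, tn)
  a2 <- acs_icm_run(st$dataset, init, hy, st$grid, cl, tn)
  expect_identical(a1$sources, a2$sources)
  expect_identical(a1$objective_trace, a2$objective_trace)
  # incumbent trace is non-decreasing
  expect_true(all(diff(a1$objective_trace) >= 0))
  icm <- icm_run(st$dataset, init, hy, st$grid, cl)
  expect_gte(utils::tail(a1$objective_trace, 1),
             utils::tail(icm$objective_trace, 1))
})

test_that("outer tuning honours its budget and recovers a surrogate optimum", {
  surrogate <- function(q0, tau0, rho)
    -((q0 - 0.5)^2 + (rho - 0.5)^2 + log(tau0)^2)
  # budget 1 returns the starting tuple
  t1 <- tune_acs(NULL, NULL, NULL, NULL, NULL, budget = 1,
                 tuning = acs_tuning(q0 = 0.43, tau0 = 0.05, rho = 0.64),
                 objective = surrogate)
  expect_equal(c(t1$q0, t1$tau0, t1$rho), c(0.43, 0.05, 0.64))

  tt <- suppressWarnings(
    tune_acs(NULL, NULL, NULL, NULL, NULL, budget = 2000,
             tuning = acs_tuning(q0 = 0.43, tau0 = 0.05, rho = 0.64),
             objective = surrogate))
  expect_equal(tt$q0, 0.5, tolerance = 1e-3)
  expect_equal(tt$tau0, 1, tolerance = 1e-3)
  expect_equal(tt$rho, 0.5, tolerance = 1e-3)
  # returned tuple always satisfies the range invariants
  expect_s3_class(tt, "acs_tuning")
  expect_true(tt$q0 > 0 && tt$q0 < 1 && tt$rho > 0 && tt$rho < 1 &&
                tt$tau0 > 0)
})
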