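#' Initialize a pheromone field
#'
#' @param N_v Number of voxels.
#' @param K Number of components.
#' @param tau0 Positive initial pheromone level.
#' @return An `N_v x K` matrix filled with `tau0`.
#' @export
initialize_pheromone <- function(N_v, K, tau0) {
  if (tau0 <= 0) stop_input("tau0 must be positive")
  matrix(tau0, N_v, K)
}

#' Local pheromone update for one (voxel, label) choice
#'
#' The chosen entry moves toward the deposit level,
#' `tau(s,l) <- (1 - rho) tau(s,l) + rho tau0`, while every other label at
#' that voxel purely evaporates, `tau(s,k) <- (1 - rho) tau(s,k)`. Applied
#' immediately after each construction step, this makes just-visited
#' components less desirable to subsequent ants and sustains exploration.
#'
#' @param pher Pheromone matrix.
#' @param voxel Voxel index `s`.
#' @param label Chosen label `l`.
#' @param tuning An [acs_tuning()] object (supplies `rho`, `tau0`).
#' @return The updated pheromone matrix (all entries remain positive).
#' @export
local_pheromone_update <- function(pher, voxel, label, tuning) {
  if (voxel < 1 || voxel > nrow(pher) || label < 1 || label > ncol(pher))
    stop_input("voxel/label index out of range")
  row <- (1 - tuning$rho) * pher[voxel, ]
  row[label] <- row[label] + tuning$rho * tuning$tau0
  # floor at the smallest positive double: long evaporation sequences decay
  # geometrically and must not underflow to exactly zero
  pher[voxel, ] <- pmax(row, .Machine$double.xmin)
  pher
}

#' Global pheromone update toward a best labeling
#'
#' Applies the same evaporate-and-deposit arithmetic as the local rule,
#' voxel-wise, on the best solution found: at every voxel the best label's
#' entry becomes `(1 - rho) tau + rho tau0` and all other labels evaporate
#' to `(1 - rho) tau`. Repeated application with the same labeling drives the
#' chosen entries geometrically to `tau0` and the rest toward zero while
#' keeping all entries strictly positive.
#'
#' @param pher Pheromone matrix.
#' @param Z_best One-hot labeling of the best solution.
#' @param tuning An [acs_tuning()] object.
#' @return The updated pheromone matrix.
#' @export
global_pheromone_update <- function(pher, Z_best, tuning) {
  check_one_hot(Z_best, "Z_best")
  if (nrow(Z_best) != nrow(pher) || ncol(Z_best) != ncol(pher))
    stop_input("Z_best dimensions do not match the pheromone field")
  lab <- max.col(Z_best, ties.method = "first")
  pher <- (1 - tuning$rho) * pher
  idx <- cbind(seq_len(nrow(pher)), lab)
  pher[idx] <- pher[idx] + tuning$rho * tuning$tau0
  pmax(pher, .Machine$double.xmin)
}

#' Construct one ant's candidate labeling
#'
#' Visits the voxels in a fresh random permutation. At each voxel a uniform
#' draw `q` decides between exploitation (`q <= q0`: take the label with
#' maximal pheromone, ties to the lowest index) and biased exploration
#' (sample label `l` with probability `tau(s,l) / sum_u tau(s,u)`). The local
#' pheromone update is applied immediately after each assignment, so the
#' returned field differs from the input.
#'
#' @param pher Pheromone matrix.
#' @param tuning An [acs_tuning()] object.
#' @param seed Integer seed for this ant's randomness.
#' @return A list with elements `Z` (one-hot labeling) and `pheromone`
#'   (the field after the per-step local updates).
#' @export
construct_labeling <- function(pher, tuning, seed = NULL) {
  Nv <- nrow(pher); K <- ncol(pher)
  with_seed(seed, {
    ord <- sample.int(Nv)
    lab <- integer(Nv)
    rho <- tuning$rho; dep <- tuning$rho * tuning$tau0
    for (s in ord) {
      row <- pher[s, ]
      l <- if (stats::runif(1) <= tuning$q0) which.max(row)
           else sample.int(K, 1L, prob = row)
      lab[s] <- l
      row <- (1 - rho) * row
      row[l] <- row[l] + dep
      pher[s, ] <- pmax(row, .Machine$double.xmin)
    }
    Z <- matrix(0, Nv, K)
    Z[cbind(seq_len(Nv), lab)] <- 1
    list(Z = Z, pheromone = pher)
  })
}

#' Ant Colony System coupled with ICM local search
#'
#' Population-based stochastic search over voxel labelings wrapped around the
#' deterministic ICM coordinate ascent. Each outer iteration, every ant
#' constructs a candidate labeling from the pheromone field (applying local
#' pheromone updates while constructing), grafts it onto the continuous
#' parameters it carried over from its previous solution, runs ICM to
#' convergence, and is scored by the log joint objective. The all-time best
#' solution (incumbent) is tracked and never lost; after each iteration the
#' global pheromone rule reinforces the best labeling. One designated ant
#' re-starts each iteration from the incumbent labeling (iteration 1: from
#' the unmodified `init`), which guarantees the final objective is at least
#' that of a plain [icm_run()] from the same initialization. The run is fully
#' reproducible given `tuning$seed`.
#'
#' @inheritParams icm_run
#' @param tuning An [acs_tuning()] object.
#' @param icm An [icm_settings()] object for the inner local search.
#' @return An object of class `acsicm_fit` for the incumbent; its
#'   `objective_trace` holds the incumbent objective per outer iteration, and
#'   attribute `"ant_log"` a per-iteration, per-ant objective table.
#' @export
acs_icm_run <- function(dataset, init, hyper, grid, clusters,
                        tuning = acs_tuning(), icm = icm_settings()) {
  seed <- tuning$seed
  pher <- initialize_pheromone(grid$N_v, hyper$K, tuning$tau0)
  ants <- replicate(tuning$n_ants, init, simplify = FALSE)
  incumbent <- NULL
  inc_obj <- -Inf
  trace <- numeric(0)
  ant_log <- list()
  for (it in seq_len(tuning$max_outer)) {
    it_best_obj <- -Inf
    it_best_Z <- NULL
    for (a in seq_len(tuning$n_ants)) {
      if (a == 1L) {
        # incumbent-seeded ant: plain ICM from init on iteration 1,
        # from the best labeling found so far on later iterations
        Za <- if (it == 1L) init$state$Z else incumbent$state$Z
      } else {
        built <- construct_labeling(pher, tuning,
                                    seed = substream_seed(seed, it, a))
        pher <- built$pheromone
        Za <- built$Z
      }
      st <- ants[[a]]$state
      st$Z <- Za
      fit <- tryCatch(
        icm_run(dataset, list(state = st, sources = ants[[a]]$sources),
                hyper, grid, clusters, icm),
        error = function(e) {
          warning("ant ", a, " failed in iteration ", it, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(fit)) next
      ants[[a]] <- list(state = fit$state, sources = fit$sources)
      obj <- utils::tail(fit$objective_trace, 1)
      ant_log[[length(ant_log) + 1]] <-
        data.frame(iteration = it, ant = a, objective = obj)
      if (obj > it_best_obj) { it_best_obj <- obj; it_best_Z <- fit$state$Z }
      if (obj > inc_obj) { inc_obj <- obj; incumbent <- fit }
    }
    if (is.null(incumbent))
      stop("all ants failed in iteration ", it)
    trace <- c(trace, inc_obj)
    Zdep <- if (tuning$global_best == "incumbent") incumbent$state$Z
            else it_best_Z
    if (!is.null(Zdep)) pher <- global_pheromone_update(pher, Zdep, tuning)
    if (it >= 2 && (trace[it] - trace[it - 1]) < tuning$outer_tol) break
  }
  out <- new_fit_result(incumbent$state, incumbent$sources, trace,
                        incumbent$k_hat,
                        converged = length(trace) < tuning$max_outer ||
                          (length(trace) >= 2 &&
                           diff(utils::tail(trace, 2)) < tuning$outer_tol),
                        iterations = length(trace), seed = seed)
  attr(out, "ant_log") <- do.call(rbind, ant_log)
  out
}

#' Nelder-Mead outer tuning of the ant system
#'
#' Optimizes the tuning triple `(q0, tau0, rho)` by running a seeded
#' [acs_icm_run()] at each candidate and maximizing its final objective.
#' The search runs on an unconstrained scale (logit for `q0` and `rho`, log
#' for `tau0`) via [stats::optim()]'s Nelder-Mead method, and the
#' best-evaluated point is returned, so the result always respects the
#' parameter ranges. The number of ants is held fixed.
#'
#' @inheritParams acs_icm_run
#' @param budget Maximum number of objective evaluations (each a full
#'   ACS-ICM run unless `objective` overrides it). With `budget = 1` the
#'   starting tuple is returned after a single evaluation.
#' @param seed Seed passed to each inner run so the objective is
#'   deterministic in the candidate point.
#' @param objective Optional replacement objective `function(q0, tau0, rho)`
#'   returning a scalar to maximize (used for testing or surrogate tuning).
#' @return An [acs_tuning()] object at the best-evaluated point, with
#'   attributes `"objective"` (its value) and `"budget_exhausted"`.
#' @export
tune_acs <- function(dataset, init, hyper, grid, clusters, budget = 20,
                     seed = 1, tuning = acs_tuning(),
                     icm = icm_settings(), objective = NULL) {
  if (budget < 1) stop_input("budget must be >= 1")
  obj_fn <- objective %||% function(q0, tau0, rho) {
    tn <- tuning
    tn$q0 <- q0; tn$tau0 <- tau0; tn$rho <- rho; tn$seed <- seed
    utils::tail(acs_icm_run(dataset, init, hyper, grid, clusters, tn,
                            icm)$objective_trace, 1)
  }
  best <- list(val = -Inf, par = c(tuning$q0, tuning$tau0, tuning$rho))
  n_eval <- 0L
  exhausted <- FALSE
  fn <- function(theta) {
    if (n_eval >= budget)
      stop(structure(class = c("acsicm_budget", "error", "condition"),
                     list(message = "budget exhausted", call = NULL)))
    n_eval <<- n_eval + 1L
    q0 <- stats::plogis(theta[1])
    tau0 <- exp(theta[2])
    rho <- stats::plogis(theta[3])
    v <- obj_fn(q0, tau0, rho)
    if (v > best$val) best <<- list(val = v, par = c(q0, tau0, rho))
    -v
  }
  start <- c(stats::qlogis(tuning$q0), log(tuning$tau0),
             stats::qlogis(tuning$rho))
  if (budget == 1) {
    fn(start)
  } else {
    tryCatch(
      stats::optim(start, fn, method = "Nelder-Mead",
                   control = list(maxit = 10 * budget,
                                  reltol = 1e-10)),
      acsicm_budget = function(e) {
        exhausted <<- TRUE
        warning("tuning budget exhausted; returning best point so far")
      })
  }
  out <- acs_tuning(q0 = best$par[1], tau0 = best$par[2], rho = best$par[3],
                    n_ants = tuning$n_ants, max_outer = tuning$max_outer,
                    outer_tol = tuning$outer_tol, seed = seed,
                    global_best = tuning$global_best)
  attr(out, "objective") <- best$val
  attr(out, "budget_exhausted") <- exhausted
  out
}
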