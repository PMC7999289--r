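# Precomputations shared by all ICM block updates for one (dataset, grid,
# clusters) triple: Cholesky factors of the noise structure matrices,
# cluster-effective forward columns (sum of member columns), H^{-1}-projected
# columns and their quadratic norms.
icm_ctx <- function(dataset, grid, clusters) {
  P <- dataset$P
  if (length(clusters$assignment) != P)
    stop_input("clusters cover ", length(clusters$assignment),
               " locations; dataset has P = ", P)
  cl <- clusters$assignment
  J <- clusters$J
  ind <- matrix(0, P, J)
  ind[cbind(seq_len(P), cl)] <- 1
  XcM <- dataset$X_M %*% ind
  XcE <- dataset$X_E %*% ind
  cholM <- chol_spd(dataset$H_M, "H_M")
  cholE <- chol_spd(dataset$H_E, "H_E")
  HinvM <- chol2inv(cholM)
  HinvE <- chol2inv(cholE)
  AM <- HinvM %*% XcM
  AE <- HinvE %*% XcE
  list(cl = cl, J = J, XcM = XcM, XcE = XcE,
       cholM = cholM, cholE = cholE, AM = AM, AE = AE,
       gM = colSums(XcM * AM), gE = colSums(XcE * AE),
       first_member = match(seq_len(J), cl))
}

#' Mode of an inverse-gamma full conditional
#'
#' All variance parameters of the model (`sigma2_M`, `sigma2_E`, `sigma2_a`
#' and each `alpha_l`) have inverse-gamma full conditionals with shape
#' `a + n_terms/2` and scale `b + half_ssq`; the conditional mode used by the
#' ICM update is `(b + half_ssq) / (a + n_terms/2 + 1)`. With no data
#' (`n_terms = half_ssq = 0`) this falls back to the prior mode `b/(a+1)`.
#'
#' @param a,b Positive inverse-gamma prior parameters.
#' @param n_terms Nonnegative number of Gaussian observations informing the
#'   variance (e.g. `T * n_M` for `sigma2_M`).
#' @param half_ssq Nonnegative half sum of squares (the quadratic form
#'   divided by 2).
#' @return The positive conditional mode.
#' @export
#' @examples
#' ig_conditional_mode(2, 1, 0, 0)      # prior mode 1/3
#' ig_conditional_mode(2, 1, 1, 2)      # 3/3.5
ig_conditional_mode <- function(a, b, n_terms, half_ssq) {
  if (a <= 0 || b <= 0) stop_input("a and b must be positive")
  if (n_terms < 0 || half_ssq < 0)
    stop_input("n_terms and half_ssq must be nonnegative")
  (b + half_ssq) / (a + n_terms / 2 + 1)
}

#' Conditional-mode update of the VAR coefficient matrix
#'
#' The full conditional of the VAR(1) coefficient matrix `A` given the active
#' mean trajectories is Gaussian; its mode is the ridge-penalized
#' least-squares regression of `mu_A(t)` on `mu_A(t-1)`:
#' `A = C (G + (sigma2_a / sigma2_A) I)^{-1}` with
#' `C = sum_{t=2}^T mu_A(t) mu_A(t-1)'` and
#' `G = sum_{t=2}^T mu_A(t-1) mu_A(t-1)'`. The ridge term from the Gaussian
#' prior keeps the system nonsingular.
#'
#' @param mu_A `(K-1) x T` active component means.
#' @param sigma2_a VAR innovation variance.
#' @param sigma2_A Prior variance of the coefficients.
#' @return The updated `(K-1) x (K-1)` matrix.
#' @export
update_ar_matrix <- function(mu_A, sigma2_a, sigma2_A) {
  mu_A <- as.matrix(mu_A)
  if (!all(is.finite(mu_A))) stop_input("mu_A contains non-finite entries")
  Tt <- ncol(mu_A)
  if (Tt < 2) stop_input("T must be >= 2")
  Km1 <- nrow(mu_A)
  lagged <- mu_A[, -Tt, drop = FALSE]
  lead <- mu_A[, -1, drop = FALSE]
  C <- tcrossprod(lead, lagged)
  G <- tcrossprod(lagged)
  t(solve(G + (sigma2_a / sigma2_A) * diag(Km1), t(C)))
}

#' Conditional-mode update of the component mean time courses
#'
#' Updates the active component means `mu_A(t)` one time point at a time in
#' time order (Gauss-Seidel: each update sees already-updated earlier time
#' points), solving the small `(K-1)`-dimensional linear system given by the
#' mixture data term and the VAR coupling to the neighbouring time points.
#' The endpoint systems differ from the interior one: `t = 1` couples to the
#' initial-state prior, `t = T` only to its predecessor. Row 1 of the
#' returned matrix (the inactive component) stays identically zero.
#'
#' @param sources `P x T` current source matrix.
#' @param state Current [mixture_state()].
#' @param grid Voxel grid.
#' @param hyper Hyperparameters.
#' @return The updated `K x T` mean matrix.
#' @export
update_component_means <- function(sources, state, grid, hyper) {
  sources <- as.matrix(sources)
  K <- hyper$K; Tt <- ncol(sources); Km1 <- K - 1
  lab <- max.col(state$Z, ties.method = "first")[grid$v]
  cnt <- tabulate(lab, K)
  al <- state$alpha
  d <- cnt[-1] / al[-1]
  SL <- rowsum_full(sources, lab, K)          # K x T per-component sums
  Cdat <- SL[-1, , drop = FALSE] / al[-1]
  A <- state$A; sa <- state$sigma2_a
  AtA <- crossprod(A)
  I1 <- diag(Km1)
  B1 <- diag(d, Km1) + AtA / sa + I1 / hyper$sigma2_mu1
  B2 <- diag(d, Km1) + (AtA + I1) / sa
  B3 <- diag(d, Km1) + I1 / sa
  muA <- state$mu[-1, , drop = FALSE]
  for (t in seq_len(Tt)) {
    if (t == 1) {
      rhs <- Cdat[, 1] + crossprod(A, muA[, 2]) / sa
      muA[, 1] <- solve(B1, rhs)
    } else if (t < Tt) {
      rhs <- Cdat[, t] + (crossprod(A, muA[, t + 1]) + A %*% muA[, t - 1]) / sa
      muA[, t] <- solve(B2, rhs)
    } else {
      rhs <- Cdat[, Tt] + A %*% muA[, Tt - 1] / sa
      muA[, Tt] <- solve(B3, rhs)
    }
  }
  rbind(0, muA)
}

#' Conditional-mode update of the source time courses
#'
#' Updates the shared time course of each location cluster to the mode of its
#' Gaussian full conditional, sweeping clusters sequentially so each update
#' uses the current values of all other clusters (Gauss-Seidel). For a
#' cluster `c` the effective forward column is the sum of its members'
#' columns, the precision is
#' `W1 = g_M/sigma2_M + g_E/sigma2_E + sum_{j in c} 1/alpha_{label(j)}`, and
#' the mode at time `t` combines the two modality pulls with the mixture
#' prior pull toward the assigned component means. With `J = P` (singleton
#' clusters) this reduces to the per-location update.
#'
#' @param dataset A [sensor_dataset()].
#' @param state Current [mixture_state()].
#' @param sources `P x T` current source matrix (needed for the
#'   Gauss-Seidel sweep).
#' @param clusters A [cluster_locations()] map.
#' @param grid Voxel grid.
#' @param ctx Optional precomputation from a previous call (internal reuse).
#' @param jitter Numerical floor on the per-cluster precision.
#' @return The updated `P x T` source matrix (constant within clusters).
#' @export
update_sources <- function(dataset, state, sources, clusters, grid,
                           ctx = NULL, jitter = 1e-10) {
  ctx <- ctx %||% icm_ctx(dataset, grid, clusters)
  sources <- as.matrix(sources)
  J <- ctx$J
  Sc <- sources[ctx$first_member, , drop = FALSE]   # J x T cluster courses
  RM <- dataset$M - ctx$XcM %*% Sc
  RE <- dataset$E - ctx$XcE %*% Sc
  lab <- max.col(state$Z, ties.method = "first")[grid$v]
  invai <- 1 / state$alpha[lab]
  wgt <- as.numeric(rowsum_full(invai, ctx$cl, J))
  prior_pull <- rowsum_full(state$mu[lab, , drop = FALSE] * invai, ctx$cl, J)
  sM <- state$sigma2_M; sE <- state$sigma2_E
  for (c in seq_len(J)) {
    sc_old <- Sc[c, ]
    num <- (crossprod(RM, ctx$AM[, c])[, 1] + ctx$gM[c] * sc_old) / sM +
      (crossprod(RE, ctx$AE[, c])[, 1] + ctx$gE[c] * sc_old) / sE +
      prior_pull[c, ]
    W1 <- max(ctx$gM[c] / sM + ctx$gE[c] / sE + wgt[c], jitter)
    sc_new <- num / W1
    delta <- sc_new - sc_old
    if (any(delta != 0)) {
      RM <- RM - tcrossprod(ctx$XcM[, c], delta)
      RE <- RE - tcrossprod(ctx$XcE[, c], delta)
      Sc[c, ] <- sc_new
    }
  }
  Sc[ctx$cl, , drop = FALSE]
}

#' Chequerboard update of the voxel labels
#'
#' Re-labels all voxels of one parity colour simultaneously (they are
#' conditionally independent given the other colour under the first-order
#' Potts prior), then the other colour. Each voxel takes the component `h`
#' maximizing the log full-conditional score
#' `-(T N_kappa / 2) log alpha_h - (1/(2 alpha_h)) sum_{j in kappa} sum_t
#' (S_j(t) - mu_h(t))^2 + 2 beta (number of neighbours labelled h)`,
#' computed in the log domain; ties break to the lowest component index.
#' Voxels containing no cortical location are labelled by the neighbour term
#' alone.
#'
#' @param sources `P x T` source matrix.
#' @param state Current [mixture_state()].
#' @param grid Voxel grid.
#' @param hyper Hyperparameters.
#' @param colours Which colours to update, in order. Default both
#'   (black then white).
#' @return The updated one-hot `N_v x K` matrix.
#' @export
update_labels_chequerboard <- function(sources, state, grid, hyper,
                                       colours = c("black", "white")) {
  sources <- as.matrix(sources)
  K <- hyper$K; Tt <- ncol(sources); Nv <- grid$N_v
  al <- state$alpha
  # per-location, per-component sums of squared deviations
  SSQ <- matrix(rowSums(sources^2), nrow(sources), K) -
    2 * sources %*% t(state$mu) +
    matrix(rowSums(state$mu^2), nrow(sources), K, byrow = TRUE)
  Vssq <- rowsum_full(SSQ, grid$v, Nv)
  datterm <- -outer(Tt * grid$N_loc / 2, log(al)) -
    sweep(Vssq, 2, 2 * al, "/")
  part <- chequerboard_partition(grid)
  Z <- state$Z
  p1 <- grid$pairs[, 1]; p2 <- grid$pairs[, 2]
  for (colour in colours) {
    set <- part[[colour]]
    if (!length(set)) next
    lab <- max.col(Z, ties.method = "first")
    # neighbour label counts via the pair list (both directions)
    idx <- (lab[c(p2, p1)] - 1L) * Nv + c(p1, p2)
    NBC <- matrix(tabulate(idx, nbins = Nv * K), Nv, K)
    score <- datterm[set, , drop = FALSE] +
      2 * hyper$beta * NBC[set, , drop = FALSE]
    q <- max.col(score, ties.method = "first")
    Z[set, ] <- 0
    Z[cbind(set, q)] <- 1
  }
  Z
}

#' Iterated Conditional Modes
#'
#' Coordinate ascent on the log joint objective: each sweep replaces every
#' parameter block by the mode of its full conditional, in the order
#' `sigma2_M`, `sigma2_E`, `sigma2_a`, `A`, `alpha`, `mu`, sources,
#' black labels, white labels. Every block update is an exact conditional
#' maximizer, so the objective trace is non-decreasing; the algorithm is
#' fully deterministic and converges to a local posterior mode. Convergence
#' is monitored by the relative change of the Frobenius norm of the source
#' matrix between consecutive sweeps.
#'
#' @param dataset A [sensor_dataset()].
#' @param init List with elements `state` (a [mixture_state()]) and `sources`
#'   (`P x T` matrix); see [initial_state()].
#' @param hyper A [hyperparameters()] object.
#' @param grid A [build_grid()] voxel grid.
#' @param clusters A [cluster_locations()] map (use `J = P` for unconstrained
#'   per-location sources).
#' @param settings An [icm_settings()] object.
#' @param trace_blocks If `TRUE`, additionally record the objective after
#'   every individual block update (slower; used for monotonicity audits).
#' @return An object of class `acsicm_fit`: elements `state`, `sources`,
#'   `objective_trace` (per sweep), `k_hat`, `converged`, `iterations`,
#'   `seed`, and (if requested) attribute `"block_trace"`.
#' @export
icm_run <- function(dataset, init, hyper, grid, clusters,
                    settings = icm_settings(), trace_blocks = FALSE) {
  state <- init$state
  S <- as.matrix(init$sources)
  check_matrix(S, "init$sources", nrow = dataset$P, ncol = dataset$T)
  ctx <- icm_ctx(dataset, grid, clusters)
  K <- hyper$K; Tt <- dataset$T
  jit <- settings$jitter
  trace <- numeric(0)
  block_trace <- if (trace_blocks) numeric(0) else NULL
  note <- function() {
    if (trace_blocks)
      block_trace <<- c(block_trace, log_joint(dataset, state, S, grid, hyper))
  }
  converged <- FALSE
  sweep_i <- 0L
  for (sweep_i in seq_len(settings$max_sweeps)) {
    S_old <- S

    RM <- dataset$M - dataset$X_M %*% S
    state$sigma2_M <- max(ig_conditional_mode(
      hyper$a_M, hyper$b_M, Tt * dataset$n_M,
      0.5 * sum(quad_forms(ctx$cholM, RM))), jit)
    note()
    RE <- dataset$E - dataset$X_E %*% S
    state$sigma2_E <- max(ig_conditional_mode(
      hyper$a_E, hyper$b_E, Tt * dataset$n_E,
      0.5 * sum(quad_forms(ctx$cholE, RE))), jit)
    note()

    muA <- state$mu[-1, , drop = FALSE]
    innov <- muA[, -1, drop = FALSE] - state$A %*% muA[, -Tt, drop = FALSE]
    state$sigma2_a <- max(ig_conditional_mode(
      hyper$a_a, hyper$b_a, (Tt - 1) * (K - 1), 0.5 * sum(innov^2)), jit)
    note()

    state$A <- update_ar_matrix(muA, state$sigma2_a, hyper$sigma2_A)
    note()

    lab <- max.col(state$Z, ties.method = "first")[grid$v]
    cnt <- tabulate(lab, K)
    dev2 <- rowSums((S - state$mu[lab, , drop = FALSE])^2)
    ssq <- as.numeric(rowsum_full(dev2, lab, K))
    for (l in seq_len(K)) {
      state$alpha[l] <- max(ig_conditional_mode(
        hyper$a_alpha, hyper$b_alpha, Tt * cnt[l], 0.5 * ssq[l]), jit)
    }
    note()

    state$mu <- update_component_means(S, state, grid, hyper)
    note()

    S <- update_sources(dataset, state, S, clusters, grid, ctx, jitter = jit)
    note()

    state$Z <- update_labels_chequerboard(S, state, grid, hyper,
                                          colours = "black")
    note()
    state$Z <- update_labels_chequerboard(S, state, grid, hyper,
                                          colours = "white")
    note()

    lj <- log_joint(dataset, state, S, grid, hyper)
    if (!is.finite(lj))
      stop("ICM objective became non-finite at sweep ", sweep_i)
    trace <- c(trace, lj)
    rel <- norm(S - S_old, "F") / max(norm(S_old, "F"), 1e-12)
    if (rel < settings$tol) { converged <- TRUE; break }
  }
  fit <- new_fit_result(state, S, trace, estimate_K(state$Z), converged,
                        sweep_i)
  if (trace_blocks) attr(fit, "block_trace") <- block_trace
  fit
}

#' Data-driven initial state
#'
#' Builds a starting value for the optimizers: sources from a ridge-penalized
#' minimum-norm inverse of the stacked two-modality forward problem, voxel
#' labels and component means from k-means on the voxel-averaged source time
#' courses (the lowest-power cluster becomes the inactive component),
#' component variances from the within-cluster spread, and unit noise scales
#' with a zero VAR matrix.
#'
#' With `method = "random"` the labels are instead drawn uniformly at random
#' and the means, variances and VAR matrix start at neutral values; this is
#' the kind of uninformative shared starting value under which ICM's
#' sensitivity to initialization shows, and from which the ant-system search
#' earns its advantage.
#'
#' @param dataset A [sensor_dataset()].
#' @param grid Voxel grid.
#' @param hyper Hyperparameters (supplies `K`).
#' @param clusters Optional cluster map; if given, the initial sources are
#'   averaged within clusters so they satisfy the equality constraint.
#' @param seed Integer seed for the k-means restarts (or the random labels).
#' @param ridge Optional ridge penalty for the minimum-norm step; default
#'   `0.1 * mean(colSums(X^2))` of the stacked operator.
#' @param method `"kmeans"` (data-driven, default) or `"random"` (neutral).
#' @return A list with elements `state` and `sources`, suitable as `init`
#'   for [icm_run()] and [acs_icm_run()].
#' @export
initial_state <- function(dataset, grid, hyper, clusters = NULL, seed = 1,
                          ridge = NULL, method = c("kmeans", "random")) {
  method <- match.arg(method)
  X <- rbind(dataset$X_M, dataset$X_E)
  Y <- rbind(dataset$M, dataset$E)
  lam <- ridge %||% (0.1 * mean(colSums(X^2)))
  Gm <- tcrossprod(X)
  diag(Gm) <- diag(Gm) + lam
  S0 <- crossprod(X, solve(Gm, Y))
  if (!is.null(clusters)) {
    cl <- clusters$assignment
    csum <- rowsum_full(S0, cl, clusters$J)
    S0 <- (csum / tabulate(cl, clusters$J))[cl, , drop = FALSE]
  }
  K <- hyper$K; Nv <- grid$N_v
  if (method == "random") {
    lab_vox <- with_seed(seed, sample.int(K, Nv, replace = TRUE))
    Z <- matrix(0, Nv, K)
    Z[cbind(seq_len(Nv), lab_vox)] <- 1
    state <- mixture_state(Z, matrix(0, K, dataset$T), rep(1, K),
                           matrix(0, K - 1, K - 1), 1, 1, 1)
    return(list(state = state, sources = S0))
  }
  Fv <- rowsum_full(S0, grid$v, Nv)
  occ <- pmax(grid$N_loc, 1)
  Fv <- Fv / occ
  k <- min(K, Nv)
  km <- with_seed(seed, {
    # tiny jitter keeps duplicate (e.g. all-zero empty-voxel) rows from
    # producing coincident centers
    Fj <- Fv + matrix(stats::rnorm(length(Fv), sd = 1e-8), nrow(Fv))
    stats::kmeans(Fj, centers = k, nstart = 5, iter.max = 100)
  })
  pow <- rowSums(km$centers^2)
  ord <- order(pow)                       # ascending power; first = inactive
  relab <- match(seq_len(k), ord)         # km cluster id -> component id
  comp <- relab[km$cluster]
  Z <- matrix(0, Nv, K)
  Z[cbind(seq_len(Nv), comp)] <- 1
  mu <- matrix(0, K, dataset$T)
  for (c in seq_len(k)[-1]) mu[c, ] <- km$centers[ord[c], ]
  lab_loc <- comp[grid$v]
  resid2 <- rowSums((S0 - mu[lab_loc, , drop = FALSE])^2) / dataset$T
  alpha <- rep(1, K)
  for (c in seq_len(K)) {
    sel <- lab_loc == c
    if (any(sel)) alpha[c] <- max(mean(resid2[sel]), 1e-3)
  }
  state <- mixture_state(Z, mu, alpha, matrix(0, K - 1, K - 1), 1, 1, 1)
  list(state = state, sources = S0)
}
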