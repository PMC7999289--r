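#' Correlation between true and estimated sources
#'
#' Pearson correlation of the two source matrices flattened over locations
#' and time, the agreement measure used to compare optimizers in the
#' simulation studies.
#'
#' @param S_true,S_hat `P x T` matrices of identical shape.
#' @return A scalar in `[-1, 1]`.
#' @export
source_correlation <- function(S_true, S_hat) {
  S_true <- as.matrix(S_true); S_hat <- as.matrix(S_hat)
  if (!all(dim(S_true) == dim(S_hat)))
    stop_input("S_true and S_hat must have identical dimensions")
  if (stats::sd(S_true) == 0 || stats::sd(S_hat) == 0)
    stop_input("source correlation undefined: zero variance input")
  stats::cor(as.vector(S_true), as.vector(S_hat))
}

#' Total MSE report with bias-variance decomposition
#'
#' For each location-time cell, the mean squared error over the R replicate
#' estimates is decomposed (with `1/R` normalization, so the identity
#' `MSE = bias^2 + variance` is exact) and totalled separately over the true
#' active region (locations whose true label is not the inactive component)
#' and the inactive region.
#'
#' @param S_hats List of `R >= 2` estimated `P x T` source matrices, one per
#'   replicate.
#' @param truth A [make_ground_truth()] object shared by the replicates
#'   (supplies `S_true` and `active_mask`). Alternatively a list of R truths
#'   if the truth varied by replicate; the decomposition is then applied to
#'   the per-replicate estimation errors.
#' @return A data frame with rows `active` and `inactive` and columns
#'   `tmse`, `total_bias2`, `total_var`.
#' @export
tmse_report <- function(S_hats, truth) {
  R <- length(S_hats)
  if (R < 2) stop_input("need at least R = 2 replicates")
  truths <- if (inherits(truth, "ground_truth")) replicate(R, truth,
                                                           simplify = FALSE)
            else truth
  if (length(truths) != R) stop_input("truth list length must equal R")
  mask <- truths[[1]]$active_mask
  dims <- dim(truths[[1]]$S_true)
  errs <- lapply(seq_len(R), function(r) {
    e <- as.matrix(S_hats[[r]]) - truths[[r]]$S_true
    if (!all(dim(e) == dims)) stop_input("replicate ", r, " has wrong shape")
    e
  })
  mean_err <- Reduce(`+`, errs) / R
  mse <- Reduce(`+`, lapply(errs, function(e) e^2)) / R
  bias2 <- mean_err^2
  vr <- mse - bias2
  region_totals <- function(sel) {
    c(tmse = sum(mse[sel, ]), total_bias2 = sum(bias2[sel, ]),
      total_var = sum(vr[sel, ]))
  }
  out <- rbind(active = region_totals(mask), inactive = region_totals(!mask))
  as.data.frame(out)
}

#' Relative percentage improvement in TMSE
#'
#' `100 * (tmse_ref - tmse_new) / tmse_ref`, the percentage by which a new
#' estimator improves on a reference (negative when it degrades).
#'
#' @param tmse_ref Positive reference TMSE (e.g. ICM).
#' @param tmse_new TMSE of the comparison estimator (e.g. ACS-ICM).
#' @return A percentage.
#' @export
relative_improvement <- function(tmse_ref, tmse_new) {
  if (tmse_ref <= 0) stop_input("tmse_ref must be positive")
  100 * (tmse_ref - tmse_new) / tmse_ref
}

#' Sampling metrics for the component-count estimator
#'
#' @param khats Integer vector of `K-hat` estimates over replicates.
#' @param K_true True number of latent states.
#' @return A list with `bias` (`mean(khats) - K_true`), `mse`
#'   (`mean((khats - K_true)^2)`) and `histogram` (a table over observed
#'   values).
#' @export
khat_metrics <- function(khats, K_true) {
  if (!length(khats)) stop_input("khats is empty")
  list(bias = mean(khats) - K_true,
       mse = mean((khats - K_true)^2),
       histogram = table(khats))
}

#' Total power of estimated sources
#'
#' Per-location sum of squared amplitudes over time,
#' `sum_t S_j(t)^2`, the quantity mapped onto the cortex in activation maps.
#'
#' @param sources `P x T` source matrix.
#' @return Length-P numeric vector.
#' @export
total_power <- function(sources) {
  rowSums(as.matrix(sources)^2)
}

#' Residual diagnostics summary
#'
#' Per-sensor means and variances, pooled standardized residuals paired with
#' standard-normal quantiles (normal quantile-quantile data), and, when
#' fitted values are supplied, residual-versus-fitted pairs. The tables are
#' plot-ready; plotting itself is left to the caller.
#'
#' @param eps `n_sensors x T` residual matrix (see [sensor_residuals()]).
#' @param fitted Optional matrix of the same shape with fitted values.
#' @return A list with `per_sensor` (data frame of means/variances and a
#'   `zero_variance` flag), `qq` (data frame `theoretical`, `sample`), and
#'   `vs_fitted` (data frame or `NULL`).
#' @export
residual_summary <- function(eps, fitted = NULL) {
  eps <- as.matrix(eps)
  per_sensor <- data.frame(sensor = seq_len(nrow(eps)),
                           mean = rowMeans(eps),
                           var = apply(eps, 1, stats::var))
  per_sensor$zero_variance <- per_sensor$var == 0
  x <- as.vector(eps)
  s <- stats::sd(x)
  z <- if (s > 0) (x - mean(x)) / s else x * 0
  qq <- data.frame(theoretical = stats::qnorm(stats::ppoints(length(z))),
                   sample = sort(z))
  vs_fitted <- NULL
  if (!is.null(fitted)) {
    fitted <- as.matrix(fitted)
    if (!all(dim(fitted) == dim(eps)))
      stop_input("fitted must match the residual matrix shape")
    vs_fitted <- data.frame(fitted = as.vector(fitted),
                            residual = as.vector(eps))
  }
  list(per_sensor = per_sensor, qq = qq, vs_fitted = vs_fitted)
}
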