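#' Resample trials and average into an evoked response
#'
#' Draws trial indices with replacement, independently for the MEG and EEG
#' trial sets (the modalities are typically recorded in separate sessions
#' with different trial counts), and averages the selected trials into a
#' single evoked-response [sensor_dataset()].
#'
#' @param trials A [trial_data()] object.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param indices Optional list with integer vectors `meg` and `eeg`
#'   overriding the random draw (e.g. to force the identity resample).
#' @return A [sensor_dataset()].
#' @export
resample_average <- function(trials, seed = NULL, indices = NULL) {
  idx <- indices %||% with_seed(seed, list(
    meg = sample.int(trials$n_trials_M, replace = TRUE),
    eeg = sample.int(trials$n_trials_E, replace = TRUE)))
  M <- colMeans(trials$meg_trials[idx$meg, , , drop = FALSE], dims = 1)
  E <- colMeans(trials$eeg_trials[idx$eeg, , , drop = FALSE], dims = 1)
  sensor_dataset(M, E, trials$X_M, trials$X_E, trials$H_M, trials$H_E,
                 coords = trials$coords)
}

#' Nonparametric bootstrap of the ACS-ICM fit
#'
#' Runs `B` independent resample-average / fit pipelines. Each replicate
#' resamples the trials with replacement, averages them into an evoked
#' response, and fits the model with [acs_icm_run()]; per-replicate seeds are
#' deterministic substreams of the master seed, so replicates are
#' reproducible and order-independent. Individual replicate failures are
#' logged and excluded.
#'
#' @param trials A [trial_data()] object.
#' @param B Number of bootstrap replicates, `>= 2`.
#' @param fit_config List with components `hyper`, `grid`, `clusters`, and
#'   optionally `tuning` ([acs_tuning()]), `icm` ([icm_settings()]), and
#'   `init` (a fixed initial value; if absent each replicate initializes
#'   itself with [initial_state()]).
#' @param seed Master seed.
#' @return A list of `acsicm_fit` objects (successful replicates), with
#'   attributes `"n_failed"` and `"boot_sources"` (a `B_ok x P x T` array of
#'   replicate source estimates).
#' @export
bootstrap_fit <- function(trials, B, fit_config, seed = 1) {
  if (B < 2) stop_input("B must be >= 2")
  for (nm in c("hyper", "grid", "clusters"))
    if (is.null(fit_config[[nm]])) stop_input("fit_config$", nm, " is required")
  tuning <- fit_config$tuning %||% acs_tuning()
  icm <- fit_config$icm %||% icm_settings()
  fits <- vector("list", B)
  failed <- 0L
  for (b in seq_len(B)) {
    fits[[b]] <- tryCatch({
      ds <- resample_average(trials, seed = substream_seed(seed, b, 1))
      init <- fit_config$init %||%
        initial_state(ds, fit_config$grid, fit_config$hyper,
                      fit_config$clusters,
                      seed = substream_seed(seed, b, 2))
      tn <- tuning
      tn$seed <- substream_seed(seed, b, 3)
      acs_icm_run(ds, init, fit_config$hyper, fit_config$grid,
                  fit_config$clusters, tn, icm)
    }, error = function(e) {
      warning("bootstrap replicate ", b, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(fits[[b]])) failed <- failed + 1L
  }
  ok <- !vapply(fits, is.null, logical(1))
  fits <- fits[ok]
  boot_sources <- if (length(fits)) {
    arr <- array(0, c(length(fits), nrow(fits[[1]]$sources),
                      ncol(fits[[1]]$sources)))
    for (i in seq_along(fits)) arr[i, , ] <- fits[[i]]$sources
    arr
  } else NULL
  attr(fits, "n_failed") <- failed
  attr(fits, "boot_sources") <- boot_sources
  fits
}

#' Bootstrap T-map
#'
#' Per-location ratio of the point estimate of total source power to its
#' bootstrap standard deviation (sample SD over replicates, `1/(B-1)`
#' denominator). Locations with zero bootstrap SD are returned as `NA` and
#' flagged, never as infinities. The map is invariant under a common
#' positive rescaling of all inputs.
#'
#' @param point_power Length-P vector of point-estimate total power
#'   (see [total_power()]).
#' @param boot_powers `B x P` matrix of replicate total powers.
#' @return Length-P vector with attribute `"undefined"` (logical vector
#'   marking zero-SD locations).
#' @export
tmap <- function(point_power, boot_powers) {
  boot_powers <- as.matrix(boot_powers)
  if (nrow(boot_powers) < 2) stop_input("need B >= 2 bootstrap replicates")
  if (ncol(boot_powers) != length(point_power))
    stop_input("boot_powers columns must match length(point_power)")
  sds <- apply(boot_powers, 2, stats::sd)
  undefined <- sds == 0
  out <- point_power / sds
  out[undefined] <- NA_real_
  attr(out, "undefined") <- undefined
  out
}

#' Pointwise bootstrap confidence band for a source time course
#'
#' Percentile interval at each time point for the source amplitude at one
#' location, across bootstrap replicates.
#'
#' @param boot_sources `B x P x T` array of replicate source estimates.
#' @param location Location index `j`.
#' @param level Coverage level in (0, 1); default 0.95.
#' @return A list with length-T vectors `lower` and `upper` and the logical
#'   `small_B` flag (set when `B < 20`, too few replicates for stable tail
#'   quantiles at the default level).
#' @export
ci_timecourse <- function(boot_sources, location, level = 0.95) {
  if (level <= 0 || level >= 1) stop_input("level must lie in (0, 1)")
  if (length(dim(boot_sources)) != 3)
    stop_input("boot_sources must be a B x P x T array")
  B <- dim(boot_sources)[1]
  small_B <- B < 20
  if (small_B) warning("only B = ", B,
                       " replicates; percentile interval is unstable")
  x <- boot_sources[, location, , drop = FALSE]
  dim(x) <- dim(boot_sources)[c(1, 3)]
  a <- (1 - level) / 2
  list(lower = apply(x, 2, stats::quantile, probs = a, names = FALSE),
       upper = apply(x, 2, stats::quantile, probs = 1 - a, names = FALSE),
       small_B = small_B)
}
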