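# Matrices are stored as comma-separated text with %.17g formatting, which
# round-trips IEEE doubles exactly; a JSON manifest records dimensions and
# layout so every load can re-validate the container invariants.

write_matrix_txt <- function(x, path) {
  x <- as.matrix(x)
  lines <- vapply(seq_len(nrow(x)), function(i)
    paste(sprintf("%.17g", x[i, ]), collapse = ","), character(1))
  writeLines(lines, path)
  invisible(path)
}

read_matrix_txt <- function(path, name = path) {
  if (!file.exists(path)) stop_input("missing matrix file for ", name)
  m <- as.matrix(data.table::fread(path, header = FALSE, sep = ","))
  dimnames(m) <- NULL
  m
}

#' Write a dataset to a delimited-text bundle
#'
#' Serializes a [sensor_dataset()] or [trial_data()] object as a directory of
#' full-precision CSV matrices plus a JSON manifest recording the layout and
#' dimensions. The bundle round-trips exactly through [read_dataset()].
#' Trial arrays are stored as row-blocks of trials in one file per modality.
#'
#' @param x A `sensor_dataset` or `trial_data` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  if (inherits(x, "sensor_dataset")) {
    manifest <- list(type = "averaged", n_M = x$n_M, n_E = x$n_E, P = x$P,
                     T = x$T, has_coords = !is.null(x$coords))
    write_matrix_txt(x$M, p("M.csv"))
    write_matrix_txt(x$E, p("E.csv"))
    write_matrix_txt(x$X_M, p("X_M.csv"))
    write_matrix_txt(x$X_E, p("X_E.csv"))
    write_matrix_txt(x$H_M, p("H_M.csv"))
    write_matrix_txt(x$H_E, p("H_E.csv"))
    if (!is.null(x$coords)) write_matrix_txt(x$coords, p("coords.csv"))
  } else if (inherits(x, "trial_data")) {
    manifest <- list(type = "trials", n_M = x$n_M, n_E = x$n_E, P = x$P,
                     T = x$T, n_trials_M = x$n_trials_M,
                     n_trials_E = x$n_trials_E,
                     has_coords = !is.null(x$coords))
    flat <- function(a) do.call(rbind, lapply(seq_len(dim(a)[1]),
                                              function(r) a[r, , ]))
    write_matrix_txt(flat(x$meg_trials), p("meg_trials.csv"))
    write_matrix_txt(flat(x$eeg_trials), p("eeg_trials.csv"))
    write_matrix_txt(x$X_M, p("X_M.csv"))
    write_matrix_txt(x$X_E, p("X_E.csv"))
    if (!is.null(x$H_M)) write_matrix_txt(x$H_M, p("H_M.csv"))
    if (!is.null(x$H_E)) write_matrix_txt(x$H_E, p("H_E.csv"))
    if (!is.null(x$coords)) write_matrix_txt(x$coords, p("coords.csv"))
  } else {
    stop_input("x must be a sensor_dataset or trial_data object")
  }
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a dataset bundle
#'
#' Loads a directory written by [write_dataset()], auto-detecting the
#' averaged versus trial-level layout from the manifest, and re-validates
#' every container invariant (consistent dimensions, positive-definite noise
#' structure) before returning. Load errors name the offending field.
#'
#' @param dir Bundle directory.
#' @return A [sensor_dataset()] or [trial_data()] object.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop_input("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  p <- function(f) file.path(dir, f)
  X_M <- read_matrix_txt(p("X_M.csv"), "X_M")
  X_E <- read_matrix_txt(p("X_E.csv"), "X_E")
  coords <- if (isTRUE(manifest$has_coords))
    read_matrix_txt(p("coords.csv"), "coords") else NULL
  if (identical(manifest$type, "averaged")) {
    M <- read_matrix_txt(p("M.csv"), "M")
    E <- read_matrix_txt(p("E.csv"), "E")
    if (nrow(M) != manifest$n_M)
      stop_input("field M: ", nrow(M), " rows but manifest n_M = ",
                 manifest$n_M)
    if (nrow(X_M) != manifest$n_M)
      stop_input("field X_M: ", nrow(X_M), " rows but manifest n_M = ",
                 manifest$n_M)
    sensor_dataset(M, E, X_M, X_E,
                   read_matrix_txt(p("H_M.csv"), "H_M"),
                   read_matrix_txt(p("H_E.csv"), "H_E"),
                   coords = coords)
  } else if (identical(manifest$type, "trials")) {
    unflat <- function(m, n_tr, n_s) {
      a <- array(0, c(n_tr, n_s, ncol(m)))
      for (r in seq_len(n_tr)) a[r, , ] <- m[(r - 1) * n_s + seq_len(n_s), ]
      a
    }
    meg <- unflat(read_matrix_txt(p("meg_trials.csv"), "meg_trials"),
                  manifest$n_trials_M, manifest$n_M)
    eeg <- unflat(read_matrix_txt(p("eeg_trials.csv"), "eeg_trials"),
                  manifest$n_trials_E, manifest$n_E)
    H_M <- if (file.exists(p("H_M.csv"))) read_matrix_txt(p("H_M.csv")) else NULL
    H_E <- if (file.exists(p("H_E.csv"))) read_matrix_txt(p("H_E.csv")) else NULL
    trial_data(meg, eeg, X_M, X_E, H_M, H_E, coords = coords)
  } else {
    stop_input("unknown dataset type in manifest: ", manifest$type)
  }
}

#' Write a fit result
#'
#' Stores the estimated sources, allocations, component means, variances and
#' VAR matrix as full-precision CSV matrices, plus a JSON file holding the
#' scalar parameters, objective trace and run metadata.
#'
#' @param fit An `acsicm_fit` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_matrix_txt(fit$sources, p("S.csv"))
  write_matrix_txt(fit$state$Z, p("Z.csv"))
  write_matrix_txt(fit$state$mu, p("mu.csv"))
  write_matrix_txt(matrix(fit$state$alpha, ncol = 1), p("alpha.csv"))
  write_matrix_txt(fit$state$A, p("A.csv"))
  meta <- list(sigma2_a = fit$state$sigma2_a, sigma2_E = fit$state$sigma2_E,
               sigma2_M = fit$state$sigma2_M,
               objective_trace = fit$objective_trace, k_hat = fit$k_hat,
               converged = fit$converged, iterations = fit$iterations,
               seed = fit$seed)
  jsonlite::write_json(meta, p("fit.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fit result
#'
#' @param dir Directory written by [write_fit()].
#' @return An `acsicm_fit` object.
#' @export
read_fit <- function(dir) {
  p <- function(f) file.path(dir, f)
  meta <- jsonlite::read_json(p("fit.json"), simplifyVector = TRUE)
  state <- mixture_state(read_matrix_txt(p("Z.csv"), "Z"),
                         read_matrix_txt(p("mu.csv"), "mu"),
                         as.numeric(read_matrix_txt(p("alpha.csv"), "alpha")),
                         read_matrix_txt(p("A.csv"), "A"),
                         meta$sigma2_a, meta$sigma2_E, meta$sigma2_M)
  new_fit_result(state, read_matrix_txt(p("S.csv"), "S"),
                 meta$objective_trace, meta$k_hat, meta$converged,
                 meta$iterations, meta$seed %||% NA_integer_)
}

#' Serialize a voxel grid or cluster map to JSON
#'
#' @param x A `voxel_grid` or `cluster_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spatial_json <- function(x, path) {
  if (inherits(x, "voxel_grid")) {
    jsonlite::write_json(list(kind = "voxel_grid", dims = x$dims, v = x$v),
                         path, auto_unbox = TRUE)
  } else if (inherits(x, "cluster_map")) {
    jsonlite::write_json(list(kind = "cluster_map", J = x$J,
                              assignment = x$assignment),
                         path, auto_unbox = TRUE)
  } else stop_input("x must be a voxel_grid or cluster_map")
  invisible(path)
}
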