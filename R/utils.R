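`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`, then
#' restores the previous RNG state so callers' randomness is undisturbed.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Derive a deterministic sub-seed from a master seed
#'
#' Maps a master seed plus an index path (e.g. iteration, ant, replicate) to a
#' reproducible 32-bit seed, so that nested stochastic components (ants,
#' bootstrap replicates) each consume an independent, order-insensitive
#' substream.
#'
#' @param master Integer master seed.
#' @param ... Integer indices identifying the substream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, 2, 3)
substream_seed <- function(master, ...) {
  ids <- c(...)
  x <- as.double(master) %% 2147483647
  for (i in seq_along(ids)) {
    # multiplicative-congruential mixing; all intermediates < 2^53
    x <- (x * 48271 + 104729 * (as.double(ids[[i]]) %% 65536) + i) %% 2147483647
  }
  as.integer(x)
}

stop_input <- function(...) {
  stop(structure(class = c("acsicm_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_matrix <- function(x, name, nrow = NULL, ncol = NULL, finite = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_input(name, " must be a numeric matrix")
  if (!is.null(nrow) && nrow(x) != nrow)
    stop_input(name, " has ", nrow(x), " rows; expected ", nrow)
  if (!is.null(ncol) && ncol(x) != ncol)
    stop_input(name, " has ", ncol(x), " columns; expected ", ncol)
  if (finite && !all(is.finite(x)))
    stop_input(name, " contains non-finite entries")
  invisible(x)
}

# one-hot check for an allocation matrix
check_one_hot <- function(Z, name = "Z") {
  if (!is.matrix(Z)) stop_input(name, " must be a matrix")
  if (!all(Z %in% c(0, 1)) || !all(rowSums(Z) == 1))
    stop_input(name, " rows must be one-hot (exactly one 1 per row)")
  invisible(Z)
}

# upper-triangular Cholesky factor, with an informative error for non-SPD input
chol_spd <- function(H, name) {
  if (!isSymmetric(unname(H), tol = 1e-8))
    stop_input(name, " must be symmetric")
  out <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(out)) stop_input(name, " is not positive definite")
  out
}

# column-wise quadratic forms r' H^{-1} r given the upper Cholesky factor of H
quad_forms <- function(cholH, R) {
  z <- backsolve(cholH, R, transpose = TRUE)
  colSums(z^2)
}

# aggregate rows of `x` by integer group in 1..n, returning an n x ncol matrix
# (zero rows for absent groups)
rowsum_full <- function(x, group, n) {
  x <- as.matrix(x)
  out <- matrix(0, n, ncol(x))
  tmp <- rowsum(x, group)
  out[as.integer(rownames(tmp)), ] <- tmp
  out
}
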