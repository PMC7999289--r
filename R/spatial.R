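#' Build a regular voxel grid over cortical locations
#'
#' Splits the axis-aligned bounding box of the coordinates into
#' `nx x ny x nz` equal-size cells, assigns every location to the voxel whose
#' half-open cell `[lo, hi)` contains it (the last cell along each axis is
#' closed), and constructs the first-order (6-connectivity) neighbourhood
#' structure and the black/white chequerboard parity needed for simultaneous
#' conditionally-independent label updates.
#'
#' @param coords `P x 3` numeric matrix of location coordinates.
#' @param dims Integer triple `(nx, ny, nz)`.
#' @return An object of class `voxel_grid` with elements `dims`, `N_v`,
#'   `v` (location to voxel index map), `pairs` (two-column matrix of
#'   unordered neighbour pairs), `nbr` (per-voxel adjacency list), `parity`
#'   (0/1 per voxel, adjacent voxels always differ), `N_loc` (cortical
#'   locations per voxel) and `P`.
#' @export
build_grid <- function(coords, dims) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop_input("coords is empty")
  check_matrix(coords, "coords", ncol = 3)
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1)) stop_input("dims must be 3 positive integers")
  P <- nrow(coords)
  idx3 <- matrix(0L, P, 3)
  for (d in 1:3) {
    lo <- min(coords[, d]); hi <- max(coords[, d])
    if (hi <= lo) hi <- lo + 1  # degenerate axis: single occupied slab
    edges <- seq(lo, hi, length.out = dims[d] + 1)
    idx3[, d] <- pmin.int(pmax.int(
      findInterval(coords[, d], edges, rightmost.closed = TRUE), 1L), dims[d])
  }
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  N_v <- nx * ny * nz
  v <- idx3[, 1] + (idx3[, 2] - 1L) * nx + (idx3[, 3] - 1L) * nx * ny

  # voxel integer coordinates (column-major unravel of 1..N_v)
  ix <- ((seq_len(N_v) - 1L) %% nx) + 1L
  iy <- (((seq_len(N_v) - 1L) %/% nx) %% ny) + 1L
  iz <- ((seq_len(N_v) - 1L) %/% (nx * ny)) + 1L
  parity <- (ix + iy + iz) %% 2L

  pair_list <- list()
  vox_id <- seq_len(N_v)
  if (nx > 1) {
    from <- vox_id[ix < nx]; pair_list[[length(pair_list) + 1]] <- cbind(from, from + 1L)
  }
  if (ny > 1) {
    from <- vox_id[iy < ny]; pair_list[[length(pair_list) + 1]] <- cbind(from, from + nx)
  }
  if (nz > 1) {
    from <- vox_id[iz < nz]; pair_list[[length(pair_list) + 1]] <- cbind(from, from + nx * ny)
  }
  pairs <- if (length(pair_list)) do.call(rbind, pair_list) else
    matrix(integer(0), 0, 2)
  colnames(pairs) <- NULL

  nbr <- vector("list", N_v)
  if (nrow(pairs)) {
    ends <- c(pairs[, 2], pairs[, 1])
    starts <- c(pairs[, 1], pairs[, 2])
    nbr <- unname(split(ends, factor(starts, levels = vox_id)))
  } else {
    nbr <- replicate(N_v, integer(0), simplify = FALSE)
  }

  structure(list(dims = dims, N_v = N_v, v = v, pairs = pairs, nbr = nbr,
                 parity = parity, N_loc = tabulate(v, N_v), P = P,
                 vox_coords = cbind(ix, iy, iz)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$dims, collapse = " x "), " (N_v =", x$N_v,
      ") holding", x$P, "locations;", nrow(x$pairs), "neighbour pairs\n")
  invisible(x)
}

#' Chequerboard partition of a voxel grid
#'
#' Splits the voxels into "black" and "white" sets by coordinate parity.
#' Under the first-order neighbourhood structure no two voxels in the same
#' set are adjacent, so all labels of one colour can be updated
#' simultaneously from their full conditionals given the other colour.
#'
#' @param grid A [build_grid()] object.
#' @return A list with integer vectors `black` and `white`.
#' @export
chequerboard_partition <- function(grid) {
  list(black = which(grid$parity == 0L), white = which(grid$parity == 1L))
}

#' Cluster cortical locations
#'
#' Groups the P locations into `J <= P` spatial clusters whose members are
#' constrained to share one source time course, reducing the dimension of the
#' source update. Clustering is Lloyd's k-means on the 3-D coordinates with
#' deterministic greedy farthest-point seeding, so the result is reproducible
#' and equivariant under permutations of the input rows.
#'
#' @param coords `P x 3` coordinate matrix.
#' @param J Number of clusters, `1 <= J <= P`.
#' @param seed Unused (the seeding is deterministic); kept so callers can
#'   treat all stochastic-looking constructors uniformly.
#' @return An object of class `cluster_map` with elements `J`,
#'   `assignment` (length-P integer vector) and `members` (list of index
#'   vectors).
#' @export
cluster_locations <- function(coords, J, seed = NULL) {
  coords <- as.matrix(coords)
  P <- nrow(coords)
  if (J > P) stop_input("J = ", J, " exceeds P = ", P)
  if (J < 1) stop_input("J must be >= 1")
  if (J == P) {
    assignment <- seq_len(P)
  } else if (J == 1) {
    assignment <- rep(1L, P)
  } else {
    # greedy farthest-point seeding: start at the point farthest from the
    # centroid, then repeatedly add the point maximizing the minimum
    # distance to the chosen seeds
    ctr <- colMeans(coords)
    d0 <- rowSums(sweep(coords, 2, ctr)^2)
    chosen <- which.max(d0)
    mind <- rowSums(sweep(coords, 2, coords[chosen, ])^2)
    while (length(chosen) < J) {
      nxt <- which.max(mind)
      chosen <- c(chosen, nxt)
      mind <- pmin(mind, rowSums(sweep(coords, 2, coords[nxt, ])^2))
    }
    centers <- coords[chosen, , drop = FALSE]
    if (anyDuplicated(centers))
      stop_input("coords contain too few distinct points for J = ", J)
    km <- stats::kmeans(coords, centers = centers, algorithm = "Lloyd",
                        iter.max = 200)
    assignment <- km$cluster
  }
  structure(list(J = as.integer(J), assignment = as.integer(assignment),
                 members = unname(split(seq_len(P),
                                        factor(assignment, levels = seq_len(J))))),
            class = "cluster_map")
}

#' Estimate the number of mixture components
#'
#' Counts the non-empty mixture components of an allocation matrix. Running
#' the optimizer with a deliberately large upper bound `K` leaves redundant
#' components empty, so the count of components holding at least one voxel
#' estimates the true number of latent states; it is always `<= K`.
#'
#' @param Z One-hot allocation matrix.
#' @return Integer estimate `K-hat`.
#' @export
estimate_K <- function(Z) {
  check_one_hot(Z)
  sum(colSums(Z) > 0)
}
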