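#' Build a homogeneous random system at prescribed density and polymer
#' fraction
#'
#' Fills a periodic box with beads at the target number density: chains are
#' placed as random walks (step length drawn near 0.7 rc, the typical
#' equilibrium bond distance for the soft potentials used here) and the
#' remaining beads become solvent, scattered uniformly.  The total bead count
#' is `N = round(density * V)` and the chain count is the nearest integer to
#' `phi * N / chain_length`, so the achieved polymer bead fraction lies
#' within one chain of the request.  DPD potentials are soft, so overlapping
#' initial placements are harmless and no minimisation is performed.
#'
#' @param box Length-3 box edges (or one number for a cubic box); each edge
#'   must be at least `2 * rc`.
#' @param phi Target polymer volume (bead-count) fraction in `(0, 1]`.
#' @param topology A [chain_topology()].
#' @param seed Integer RNG seed; the same spec and seed give an identical
#'   frame.
#' @param params A [dpd_params()].
#' @return A `dpd_frame` with attribute `achieved_phi`.
#' @examples
#' fr <- build_system(10, 0.10, chain_topology(3, 3, 6), seed = 1)
#' attr(fr, "achieved_phi")
#' @export
build_system <- function(box, phi, topology, seed, params = dpd_params()) {
  box <- as.numeric(box)
  if (length(box) == 1) box <- rep(box, 3)
  if (length(box) != 3 || any(box < 2 * params$rc))
    stop("box edges must all be at least 2*rc")
  if (!is.numeric(phi) || length(phi) != 1 || phi <= 0 || phi > 1)
    stop("'phi' must lie in (0, 1]")
  if (!inherits(topology, "chain_topology"))
    stop("'topology' must be a chain_topology object")
  V <- prod(box)
  N <- round(params$density * V)
  len <- topology$length
  if (N < len) stop("box too small to hold a single chain at this density")
  n_chains <- round(phi * N / len)
  if (phi > 0 && n_chains < 1) n_chains <- 1L
  n_poly <- n_chains * len
  if (n_poly > N)
    stop("box too small: requested polymer beads exceed the total bead count")
  n_solv <- N - n_poly

  set.seed(as.integer(seed %% .Machine$integer.max))
  pos <- matrix(0, N, 3)
  species <- character(N)
  bonds <- matrix(integer(), 0, 2)
  at <- 0L
  if (n_chains > 0) {
    bonds <- matrix(0L, n_chains * (len - 1L), 2)
    brow <- 0L
    for (ch in seq_len(n_chains)) {
      start <- runif(3) * box
      steps <- matrix(rnorm(3 * (len - 1L)), ncol = 3)
      steps <- steps / sqrt(rowSums(steps^2)) *
        (0.7 * params$rc * (1 + runif(len - 1L, -0.1, 0.1)))
      walk <- rbind(start, sweep(apply(steps, 2, cumsum), 2, start, `+`))
      if (len == 2) walk <- rbind(start, start + steps)  # cumsum drops dims
      pos[at + seq_len(len), ] <- walk
      species[at + seq_len(len)] <- topology$sequence
      idx <- at + seq_len(len - 1L)
      bonds[brow + seq_len(len - 1L), ] <- cbind(idx, idx + 1L)
      brow <- brow + len - 1L
      at <- at + len
    }
  }
  if (n_solv > 0) {
    pos[at + seq_len(n_solv), ] <- matrix(runif(3 * n_solv), ncol = 3) %*%
      diag(box)
    species[at + seq_len(n_solv)] <- "S"
  }
  fr <- dpd_frame(pos, species = species, box = box, bonds = bonds)
  attr(fr, "achieved_phi") <- n_poly / N
  attr(fr, "n_chains") <- n_chains
  fr
}

#' Build a pure-solvent box
#'
#' Uniform random solvent beads at the target density; the standard starting
#' state for thermostat and transport checks.
#'
#' @inheritParams build_system
#' @return A `dpd_frame` containing only S beads.
#' @export
solvent_system <- function(box, seed, params = dpd_params()) {
  box <- as.numeric(box)
  if (length(box) == 1) box <- rep(box, 3)
  if (length(box) != 3 || any(box < 2 * params$rc))
    stop("box edges must all be at least 2*rc")
  N <- round(params$density * prod(box))
  set.seed(as.integer(seed %% .Machine$integer.max))
  pos <- matrix(runif(3 * N), ncol = 3) %*% diag(box)
  dpd_frame(pos, species = rep("S", N), box = box)
}

#' Draw Maxwell-Boltzmann velocities at an exact kinetic temperature
#'
#' Gaussian velocities with the net momentum subtracted exactly and the
#' magnitudes rescaled so that the measured kinetic temperature
#' `sum(v^2)/(3N-3)` equals `kBT` exactly at t = 0.
#'
#' @param frame A `dpd_frame` with at least two beads.
#' @param kBT Target temperature (default 1).
#' @param seed Integer RNG seed.
#' @return The frame with velocities replaced.
#' @export
init_velocities <- function(frame, kBT = 1, seed) {
  n <- n_beads(frame)
  if (n < 2)
    stop("cannot zero momentum and set a temperature with fewer than 2 beads")
  if (kBT < 0) stop("'kBT' must be non-negative")
  set.seed(as.integer(seed %% .Machine$integer.max))
  v <- matrix(rnorm(3 * n), n, 3)
  v <- sweep(v, 2, colMeans(v))
  if (kBT == 0) {
    frame$velocities <- matrix(0, n, 3)
    return(frame)
  }
  scale <- sqrt((3 * n - 3) * kBT / sum(v^2))
  frame$velocities <- v * scale
  frame
}
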