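#' DPD pair force laws
#'
#' Reference implementations of the four force terms acting between beads,
#' evaluated for a single pair.  `r_vec` is the minimum-image displacement
#' `r_i - r_j`; all forces are the force ON bead i (bead j receives the exact
#' negative).  Beyond the cutoff every pair force vanishes; at exact
#' coincidence (zero separation) the direction is undefined and the soft
#' potential is
#' finite, so a zero vector is returned.
#'
#' * conservative: `a * (1 - r/rc) * e`, soft repulsion
#' * dissipative: `-gamma * (1 - r/rc)^2 * (v_ij . e) * e`, opposes relative
#'   radial motion (weight `omega_D = omega_R^2`)
#' * random: `sigma * (1 - r/rc) * xi * dt^(-1/2) * e`, with one symmetric
#'   zero-mean unit-variance draw `xi` per pair per step
#' * bond: `-C * (r - r_eq) * e`, harmonic; with `r_eq = 0` a linear
#'   attraction of magnitude `C * r`
#'
#' @param a Conservative repulsion amplitude for the species pair.
#' @param r_vec Displacement vector `r_i - r_j` (length 3).
#' @param rc Cutoff radius (default 1).
#' @param gamma Friction coefficient.
#' @param v_vec Relative velocity `v_i - v_j` (length 3).
#' @param sigma Random-force amplitude.
#' @param xi Zero-mean unit-variance random draw for the pair.
#' @param dt Timestep (the random force scales as `dt^(-1/2)`).
#' @param C Bond spring constant.
#' @param r_eq Equilibrium bond length.
#' @return Numeric length-3 force vector on bead i.
#' @examples
#' conservative_force(25, c(0.5, 0, 0))       # magnitude 12.5 along +x
#' dissipative_force(4.5, c(0.5, 0, 0), c(-1, 0, 0))
#' bond_force(8, c(0.5, 0, 0))                # magnitude 4 toward j
#' @export
conservative_force <- function(a, r_vec, rc = 1) {
  r <- sqrt(sum(r_vec^2))
  if (r >= rc || r == 0) return(c(0, 0, 0))
  a * (1 - r / rc) * r_vec / r
}

#' @rdname conservative_force
#' @export
dissipative_force <- function(gamma, r_vec, v_vec, rc = 1) {
  r <- sqrt(sum(r_vec^2))
  if (r >= rc || r == 0) return(c(0, 0, 0))
  e <- r_vec / r
  -gamma * omega_D(r, rc) * sum(v_vec * e) * e
}

#' @rdname conservative_force
#' @export
random_force <- function(sigma, r_vec, xi, dt, rc = 1) {
  if (dt <= 0) stop("'dt' must be positive")
  r <- sqrt(sum(r_vec^2))
  if (r >= rc || r == 0) return(c(0, 0, 0))
  sigma * omega_R(r, rc) * xi / sqrt(dt) * r_vec / r
}

#' @rdname conservative_force
#' @export
bond_force <- function(C, r_vec, r_eq = 0) {
  r <- sqrt(sum(r_vec^2))
  if (r == 0) return(c(0, 0, 0))
  -C * (r - r_eq) * r_vec / r
}

#' Thermostat weight functions
#'
#' The random-force weight is `omega_R(r) = 1 - r/rc` below the cutoff and
#' zero beyond; the fluctuation-dissipation theorem fixes the dissipative
#' weight to its square, `omega_D = omega_R^2`.
#'
#' @param r Pair distance(s).
#' @param rc Cutoff radius (default 1).
#' @return Weight value(s) in `[0, 1]`.
#' @export
omega_R <- function(r, rc = 1) ifelse(r < rc, 1 - r / rc, 0)

#' @rdname omega_R
#' @export
omega_D <- function(r, rc = 1) omega_R(r, rc)^2

#' Evaluate total forces on every bead of a frame
#'
#' One-shot evaluation of conservative + bond + dissipative + random forces
#' for a frame, through the engine core.  `use_cells = FALSE` switches to the
#' all-pairs O(N^2) path; both paths consume the identical per-pair random
#' stream, so they must agree to round-off.
#'
#' @param frame A `dpd_frame`.
#' @param interactions Matrix from [interaction_matrix()].
#' @param params Parameters from [dpd_params()].
#' @param seed Integer seed for the pairwise random stream.
#' @param step Absolute step index keying the random stream (default the
#'   frame's step).
#' @param shear_rate Applied strain rate (affects moving-image velocities).
#' @param use_cells Use the cell-list path (default TRUE).
#' @param gaussian Use Gaussian instead of uniform random draws.
#' @return List with `forces` (N x 3), `epot` (conservative + bond potential
#'   energy) and `n_pairs`.
#' @export
compute_forces <- function(frame, interactions, params, seed = 0,
                           step = frame$step, shear_rate = 0,
                           use_cells = TRUE, gaussian = FALSE) {
  a <- interactions[DPD_SPECIES, DPD_SPECIES]
  res <- cpp_forces(frame$positions, frame$velocities,
                    species_index(frame$species), a,
                    frame$bonds - 1L, frame$box, frame$tilt, 0L, 2L,
                    params$rc, params$gamma, params$sigma, params$dt,
                    params$spring_C, params$r_eq, seed, step, gaussian,
                    shear_rate, use_cells)
  if (res$n_zero_dist > 0)
    warning(sprintf("%d coincident pair(s) at zero distance: force direction undefined, zero force applied", res$n_zero_dist))
  res
}

#' Conservative + kinetic energy of a frame
#'
#' Total conservative energy: soft pair potential `a*rc/2*(1 - r/rc)^2`
#' summed over pairs within the cutoff, plus harmonic bond energy, plus
#' kinetic energy.  Useful for checking energy conservation with the
#' thermostat switched off.
#'
#' @inheritParams compute_forces
#' @return List with `potential`, `kinetic` and `total`.
#' @export
system_energy <- function(frame, interactions, params) {
  quiet <- dpd_params(rc = params$rc, density = params$density,
                      kBT = params$kBT, sigma = 0, dt = params$dt,
                      spring_C = params$spring_C, r_eq = params$r_eq,
                      a_ii = params$a_ii)
  quiet$gamma <- 0
  res <- compute_forces(frame, interactions, quiet)
  kin <- 0.5 * sum(frame$velocities^2)
  list(potential = res$epot, kinetic = kin, total = res$epot + kin)
}
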