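#' Simulation parameters in reduced DPD units
#'
#' Collects the constants of the DPD model.  Lengths are in units of the
#' cutoff radius `rc`, energies in `kBT`, and bead mass is 1, so times are in
#' `rc * sqrt(m / kBT)`.  The friction coefficient `gamma` is always derived
#' from the noise amplitude through the fluctuation-dissipation relation
#' `sigma^2 = 2 * gamma * kBT`; it cannot be set independently, so the
#' thermostat is consistent by construction.
#'
#' @param rc Pair-interaction cutoff radius (default 1, the length unit).
#' @param density Target bead number density rho (default 3).
#' @param kBT Thermostat temperature (default 1, the energy unit).
#' @param sigma Random-force amplitude (default 3).
#' @param dt Integration timestep (default 0.04).
#' @param spring_C Harmonic bond spring constant (default 8).
#' @param r_eq Equilibrium bond length (default 0).
#' @param a_ii Like-species repulsion amplitude (default 25, appropriate for
#'   density 3).
#'
#' @return An object of class `dpd_params`: a list with the above fields plus
#'   the derived friction `gamma = sigma^2 / (2 * kBT)`.
#' @examples
#' p <- dpd_params()
#' p$gamma  # 4.5
#' @export
dpd_params <- function(rc = 1, density = 3, kBT = 1, sigma = 3, dt = 0.04,
                       spring_C = 8, r_eq = 0, a_ii = 25) {
  for (nm in c("rc", "density", "kBT", "dt")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  }
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (spring_C < 0) stop("'spring_C' must be non-negative")
  if (r_eq < 0) stop("'r_eq' must be non-negative")
  structure(
    list(rc = rc, density = density, kBT = kBT, sigma = sigma,
         gamma = sigma^2 / (2 * kBT), dt = dt, spring_C = spring_C,
         r_eq = r_eq, a_ii = a_ii),
    class = "dpd_params")
}

#' @export
print.dpd_params <- function(x, ...) {
  cat("DPD parameters (reduced units):\n")
  cat(sprintf("  rc = %g, density = %g, kBT = %g, dt = %g\n",
              x$rc, x$density, x$kBT, x$dt))
  cat(sprintf("  sigma = %g, gamma = sigma^2/(2 kBT) = %g\n",
              x$sigma, x$gamma))
  cat(sprintf("  bonds: C = %g, r_eq = %g; a_ii = %g\n",
              x$spring_C, x$r_eq, x$a_ii))
  invisible(x)
}

#' Species labels used throughout the package
#'
#' The three polymer species of the pentablock chain plus solvent, in the
#' canonical order used by interaction matrices and frames.
#' @export
DPD_SPECIES <- c("A", "B", "C", "S")

#' Build the species interaction matrix
#'
#' Constructs the symmetric matrix of maximum conservative repulsion
#' amplitudes `a_ij` over species A, B, C (polymer blocks) and S (solvent).
#' All polymer-polymer cross pairs share one amplitude `aAB` (weak segregation
#' among blocks); the diagonal is the like-species value `a_ii`; the
#' block-solvent amplitudes `aAS`, `aBS`, `aCS` set the solvent selectivity
#' and are the control parameters of the self-assembly state diagram.
#'
#' @param aAS A-solvent repulsion amplitude.
#' @param aCS C-solvent repulsion amplitude.
#' @param aAB Polymer-polymer cross amplitude (A-B, B-C, A-C; default 40).
#' @param aBS B-solvent amplitude (default 45).
#' @param a_ii Like-species amplitude (default 25).
#' @return A 4x4 symmetric numeric matrix with dimnames `A, B, C, S`, of
#'   class `dpd_interactions`.
#' @examples
#' interaction_matrix(aAS = 65, aCS = 26)
#' @export
interaction_matrix <- function(aAS, aCS, aAB = 40, aBS = 45, a_ii = 25) {
  vals <- c(aAS = aAS, aCS = aCS, aAB = aAB, aBS = aBS, a_ii = a_ii)
  bad <- names(vals)[!is.finite(vals) | vals < 0]
  if (length(bad))
    stop("repulsion amplitude must be a non-negative number: ",
         paste(bad, collapse = ", "))
  a <- matrix(a_ii, 4, 4, dimnames = list(DPD_SPECIES, DPD_SPECIES))
  a["A", "B"] <- a["B", "A"] <- aAB
  a["B", "C"] <- a["C", "B"] <- aAB
  a["A", "C"] <- a["C", "A"] <- aAB
  a["A", "S"] <- a["S", "A"] <- aAS
  a["B", "S"] <- a["S", "B"] <- aBS
  a["C", "S"] <- a["S", "C"] <- aCS
  class(a) <- c("dpd_interactions", class(a))
  a
}

#' @export
print.dpd_interactions <- function(x, ...) {
  cat("DPD repulsion amplitudes a_ij (kBT/rc):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Map between repulsion amplitude and Flory-Huggins chi
#'
#' For bead density 3 the conservative amplitude is linear in the
#' Flory-Huggins incompatibility: `a_ij = a_ii + 3.27 * chi_ij`.  The two
#' functions are exact inverses of each other.
#'
#' @param a,chi Numeric vectors of amplitudes / chi parameters.
#' @param a_ii Like-species amplitude (default 25).
#' @return The mapped value(s).
#' @examples
#' a_to_chi(40)          # (40 - 25) / 3.27
#' chi_to_a(a_to_chi(40))
#' @export
a_to_chi <- function(a, a_ii = 25) (a - a_ii) / 3.27

#' @rdname a_to_chi
#' @export
chi_to_a <- function(chi, a_ii = 25) a_ii + 3.27 * chi
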