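#' Simulation frame
#'
#' One simulation state: bead positions and velocities, species labels, cargo
#' tags, the bond list and the (possibly tilted) periodic box.  The box is
#' orthorhombic with edge lengths `box`, optionally sheared in the `xz` plane:
#' the image one box length up in z is displaced by `tilt` in x
#' (Lees-Edwards convention).  `strain` is the cumulative applied strain; it
#' keeps growing even when `tilt` is re-wrapped into `(-Lx/2, Lx/2]`.
#'
#' Cargo (`S0`) is a bookkeeping tag on solvent beads only: it never enters
#' any force, which depends on species alone.
#'
#' @param positions N x 3 numeric matrix of bead positions.
#' @param velocities N x 3 numeric matrix (defaults to zeros).
#' @param species Character vector of per-bead labels among `A,B,C,S`.
#' @param box Numeric length-3 box edge lengths.
#' @param bonds Two-column integer matrix of 1-based bonded pairs (may have
#'   zero rows).
#' @param cargo Logical per-bead cargo tag (solvent beads only).
#' @param tilt Lees-Edwards x-offset of the +z image (default 0).
#' @param step Integer timestep index.
#' @param strain Cumulative shear strain.
#' @param wrap Wrap positions into the primary cell (default TRUE).
#' @return An object of class `dpd_frame`.
#' @export
dpd_frame <- function(positions, velocities = NULL, species, box,
                      bonds = matrix(integer(), 0, 2), cargo = NULL,
                      tilt = 0, step = 0, strain = 0, wrap = TRUE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (ncol(positions) != 3) stop("'positions' must have three columns")
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  storage.mode(velocities) <- "double"
  if (!all(dim(velocities) == c(n, 3)))
    stop("'velocities' must match the dimensions of 'positions'")
  species <- as.character(species)
  if (length(species) != n) stop("'species' must have one label per bead")
  unknown <- setdiff(unique(species), DPD_SPECIES)
  if (length(unknown))
    stop("unknown species label: ", paste(unknown, collapse = ", "))
  if (is.null(cargo)) cargo <- rep(FALSE, n)
  cargo <- as.logical(cargo)
  if (length(cargo) != n) stop("'cargo' must have one flag per bead")
  if (any(cargo & species != "S"))
    stop("cargo (S0) tags are only valid on solvent beads")
  box <- as.numeric(box)
  if (length(box) == 1) box <- rep(box, 3)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("'box' must be three positive edge lengths")
  bonds <- as.matrix(bonds)
  if (ncol(bonds) != 2 && nrow(bonds) > 0) stop("'bonds' must have 2 columns")
  if (nrow(bonds) > 0) {
    storage.mode(bonds) <- "integer"
    if (any(bonds < 1L) || any(bonds > n))
      stop("bond list references invalid bead indices")
  } else bonds <- matrix(integer(), 0, 2)
  fr <- structure(
    list(positions = positions, velocities = velocities, species = species,
         cargo = cargo, bonds = bonds, box = box, tilt = tilt,
         step = as.numeric(step), strain = strain),
    class = "dpd_frame")
  if (wrap) fr <- wrap_frame(fr)
  fr
}

#' Number of beads in a frame
#' @param frame A `dpd_frame`.
#' @return Integer bead count.
#' @export
n_beads <- function(frame) nrow(frame$positions)

#' Wrap all bead positions into the primary periodic cell
#'
#' Respects the sheared boundary: a bead leaving through the z faces re-enters
#' displaced by the current tilt (its x velocity is left untouched here; the
#' engine applies the sliding-brick velocity shift during dynamics).
#'
#' @param frame A `dpd_frame`.
#' @return The frame with wrapped positions.
#' @export
wrap_frame <- function(frame) {
  w <- cpp_wrap_positions(frame$positions, frame$velocities, frame$box,
                          frame$tilt, 0L, 2L, 0.0)
  frame$positions <- w$positions
  frame
}

#' Minimum-image displacement in a (possibly tilted) periodic box
#'
#' Maps raw displacement vectors to their shortest periodic image, accounting
#' for the Lees-Edwards tilt of the z image rows.
#'
#' @param d Numeric vector of length 3 or an N x 3 matrix of displacements.
#' @param box Length-3 box edges.
#' @param tilt Lees-Edwards x-offset (default 0).
#' @return Displacement(s) of the same shape as `d`.
#' @export
minimum_image <- function(d, box, tilt = 0) {
  vec <- is.null(dim(d))
  if (vec) d <- matrix(d, 1, 3)
  out <- cpp_min_image(as.matrix(d), as.numeric(box), tilt, 0L, 2L)
  if (vec) drop(out) else out
}

#' Instantaneous kinetic temperature
#'
#' Equipartition estimate `sum(v^2) / (3N - 3)` in reduced units (mass 1),
#' with three degrees of freedom removed for the conserved total momentum.
#'
#' @param frame A `dpd_frame` with at least two beads.
#' @return Kinetic temperature (energy units, kBT).
#' @export
measure_temperature <- function(frame) {
  n <- n_beads(frame)
  if (n < 2) stop("temperature needs at least two beads")
  sum(frame$velocities^2) / (3 * n - 3)
}

#' Total momentum of a frame
#' @param frame A `dpd_frame`.
#' @return Numeric length-3 momentum vector (mass 1 per bead).
#' @export
total_momentum <- function(frame) colSums(frame$velocities)

#' @export
print.dpd_frame <- function(x, ...) {
  n <- n_beads(x)
  tab <- table(factor(x$species, levels = DPD_SPECIES))
  cat(sprintf("DPD frame: %d beads (A:%d B:%d C:%d S:%d, S0-tagged:%d)\n",
              n, tab["A"], tab["B"], tab["C"], tab["S"], sum(x$cargo)))
  cat(sprintf("  box %g x %g x %g, tilt %.4g, step %g, strain %.4g, %d bonds\n",
              x$box[1], x$box[2], x$box[3], x$tilt, x$step, x$strain,
              nrow(x$bonds)))
  invisible(x)
}

# internal: 0-based species index vector in A,B,C,S order for the C++ core
species_index <- function(species) {
  match(species, DPD_SPECIES) - 1L
}

# internal: fractional coordinates for the tilted cell (x = H f with
# H = [[Lx,0,tilt],[0,Ly,0],[0,0,Lz]])
frac_coords <- function(pos, box, tilt) {
  fz <- pos[, 3] / box[3]
  cbind((pos[, 1] - tilt * fz) / box[1], pos[, 2] / box[2], fz)
}

# internal: periodic (circular-mean) centre of a point set, per dimension in
# fractional coordinates, mapped back to Cartesian
periodic_center <- function(pos, box, tilt = 0) {
  f <- frac_coords(pos, box, tilt)
  ang <- 2 * pi * f
  fm <- (atan2(colMeans(sin(ang)), colMeans(cos(ang))) / (2 * pi)) %% 1
  c(fm[1] * box[1] + tilt * fm[3], fm[2] * box[2], fm[3] * box[3])
}
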