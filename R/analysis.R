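# Measurement stack: aggregate clustering, radial composition profiles,
# cargo encapsulation/release, hydrophilic connectivity, membrane thickness
# and morphology classification.

#' Cluster polymer beads into aggregates
#'
#' Single-linkage clustering of all polymer (non-solvent) beads under the
#' minimum-image metric: beads closer than `cutoff` join the same aggregate.
#' Each cluster records whether it is connected to its own periodic image
#' (it "wraps") in each box dimension; a wrapping cluster spans the box, the
#' signature of a lamellar phase.  Centres of mass are computed by
#' circular-mean unwrapping per (fractional) dimension, which is exact for
#' compact clusters under periodic boundaries.
#'
#' @param frame A `dpd_frame`.
#' @param cutoff Contact distance joining beads of different chains (default
#'   `0.8`; see Details).
#' @param min_contacts Minimum number of bead-contact pairs two molecules
#'   must share to be merged (default 3, capped by the smaller molecule's
#'   bead count; see Details).
#' @details Bonded beads always share a cluster (a chain is one molecule), so
#'   the cutoff only decides when two chains touch.  The default contact
#'   distance 0.8 rc is the first-peak scale of the pair correlation at
#'   density 3: the interaction range rc itself is so permissive that at
#'   liquid density loosely dispersed chains chain up into spanning clusters,
#'   which would mask the distinction between a dispersed melt and a true
#'   aggregate.  For the same reason two chains only join an aggregate when
#'   they share a persistent interface — at least `min_contacts`
#'   simultaneous bead contacts — rather than a single grazing touch.
#'   Unbonded beads count as single-bead molecules, for which the threshold
#'   reduces to plain single linkage.
#' @return An `aggregate_set`: list with `clusters` (each a list holding
#'   `members` — frame bead indices —, `com`, `wraps`, `size`) sorted by
#'   decreasing size, plus `n_polymer`.
#' @export
find_aggregates <- function(frame, cutoff = 0.8, min_contacts = 3) {
  if (cutoff <= 0) stop("'cutoff' must be positive")
  poly <- which(frame$species != "S")
  if (length(poly) == 0)
    return(structure(list(clusters = list(), n_polymer = 0L),
                     class = "aggregate_set"))
  bonds <- frame$bonds
  keep <- bonds[, 1] %in% poly & bonds[, 2] %in% poly
  edges <- cbind(match(bonds[keep, 1], poly), match(bonds[keep, 2], poly))
  storage.mode(edges) <- "integer"
  mol <- molecule_ids(length(poly), edges)
  cl <- cpp_cluster(frame$positions, frame$box, frame$tilt, 0L, 2L,
                    poly - 1L, cutoff, edges - 1L, mol - 1L,
                    as.integer(min_contacts))
  clusters <- lapply(seq_len(cl$n_clusters), function(k) {
    members <- poly[cl$labels == k]
    list(members = members,
         com = periodic_center(frame$positions[members, , drop = FALSE],
                               frame$box, frame$tilt),
         wraps = as.logical(cl$wraps[k, ]),
         size = length(members))
  })
  clusters <- clusters[order(-vapply(clusters, `[[`, integer(1), "size"))]
  structure(list(clusters = clusters, n_polymer = length(poly)),
            class = "aggregate_set")
}

#' @export
print.aggregate_set <- function(x, ...) {
  cat(sprintf("Aggregate set: %d cluster(s) over %d polymer beads\n",
              length(x$clusters), x$n_polymer))
  for (k in seq_len(min(5, length(x$clusters)))) {
    cl <- x$clusters[[k]]
    cat(sprintf("  #%d: %d beads, com (%.2f, %.2f, %.2f)%s\n", k, cl$size,
                cl$com[1], cl$com[2], cl$com[3],
                if (any(cl$wraps)) " [wraps]" else ""))
  }
  if (length(x$clusters) > 5) cat("  ...\n")
  invisible(x)
}

#' Radial composition profile about an aggregate
#'
#' Bins every bead of the frame (solvent included) by its minimum-image
#' distance from the aggregate's centre of mass and reports the number
#' fraction of each species per radial bin.  Fractions in every non-empty
#' bin sum to one; empty bins are dropped, not zero-filled.
#'
#' @param frame A `dpd_frame`.
#' @param aggregate One element of `find_aggregates(frame)$clusters`, or a
#'   vector of bead indices (its periodic centre is then computed here).
#' @param bin_width Radial bin width (default 0.25).
#' @return A `composition_profile` data frame with columns `r` (bin centre),
#'   `fA`, `fB`, `fC`, `fS` and `n` (beads in bin); `bin_width` attribute.
#' @export
composition_profile <- function(frame, aggregate, bin_width = 0.25) {
  if (bin_width <= 0) stop("'bin_width' must be positive")
  if (is.list(aggregate)) {
    com <- aggregate$com
    if (length(aggregate$members) == 0) stop("empty aggregate")
  } else {
    if (length(aggregate) == 0) stop("empty aggregate")
    com <- periodic_center(frame$positions[aggregate, , drop = FALSE],
                           frame$box, frame$tilt)
  }
  d <- minimum_image(sweep(frame$positions, 2, com), frame$box, frame$tilt)
  r <- sqrt(rowSums(d^2))
  bin <- floor(r / bin_width)
  tab <- table(bin, factor(frame$species, levels = DPD_SPECIES))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  n <- rowSums(counts)
  keep <- n > 0
  counts <- counts[keep, , drop = FALSE]
  n <- n[keep]
  out <- data.frame(
    r = (as.numeric(rownames(counts)) + 0.5) * bin_width,
    fA = counts[, "A"] / n, fB = counts[, "B"] / n,
    fC = counts[, "C"] / n, fS = counts[, "S"] / n,
    n = as.integer(n), row.names = NULL)
  out <- out[order(out$r), ]
  rownames(out) <- NULL
  attr(out, "bin_width") <- bin_width
  class(out) <- c("composition_profile", "data.frame")
  out
}

#' @export
plot.composition_profile <- function(x, ...) {
  graphics::matplot(x$r, as.matrix(x[, c("fA", "fB", "fC", "fS")]),
                    type = "l", lty = 1, lwd = 2,
                    col = c("goldenrod", "forestgreen", "firebrick",
                            "steelblue"),
                    xlab = "r from centre of mass (rc)",
                    ylab = "number fraction f_i(r)", ...)
  graphics::legend("topright", legend = c("A", "B", "C", "S"), lty = 1,
                   lwd = 2, col = c("goldenrod", "forestgreen", "firebrick",
                                    "steelblue"), bty = "n")
  invisible(x)
}

#' Composition profile along a box axis
#'
#' Planar analogue of [composition_profile()] for slab geometries: bins every
#' bead by its coordinate along one axis.
#'
#' @param frame A `dpd_frame`.
#' @param axis Axis index (1 = x, 2 = y, 3 = z; default 3).
#' @param bin_width Bin width (default 0.25).
#' @return A `composition_profile` data frame (column `r` is the coordinate).
#' @export
axis_profile <- function(frame, axis = 3, bin_width = 0.25) {
  if (bin_width <= 0) stop("'bin_width' must be positive")
  x <- frame$positions[, axis]
  bin <- floor(x / bin_width)
  tab <- table(bin, factor(frame$species, levels = DPD_SPECIES))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  n <- rowSums(counts)
  keep <- n > 0
  counts <- counts[keep, , drop = FALSE]
  n <- n[keep]
  out <- data.frame(
    r = (as.numeric(rownames(counts)) + 0.5) * bin_width,
    fA = counts[, "A"] / n, fB = counts[, "B"] / n,
    fC = counts[, "C"] / n, fS = counts[, "S"] / n,
    n = as.integer(n), row.names = NULL)
  out <- out[order(out$r), ]
  rownames(out) <- NULL
  attr(out, "bin_width") <- bin_width
  class(out) <- c("composition_profile", "data.frame")
  out
}

#' Encapsulated solvent beads
#'
#' Classifies solvent beads as encapsulated or exterior without any geometric
#' assumption about the container: solvent is clustered by single linkage
#' (cutoff `cutoff`), and a cluster that is connected to its own periodic
#' image in any box dimension percolates and is exterior; clusters that wrap
#' in no dimension are finite pockets — encapsulated cargo.  This handles
#' non-spherical vesicles and multiple cavities (each cavity is its own
#' non-wrapping cluster).
#'
#' @param frame A `dpd_frame`.
#' @param cutoff Linkage distance (default 1, the interaction range; solvent
#'   at density 3 percolates robustly at this distance, so pockets are
#'   genuine cavities rather than sampling noise).
#' @return Integer vector of encapsulated solvent bead indices, with
#'   attribute `n_pockets` (number of disjoint encapsulated clusters).
#' @export
encapsulated_solvent <- function(frame, cutoff = 1) {
  if (cutoff <= 0) stop("'cutoff' must be positive")
  solv <- which(frame$species == "S")
  if (length(solv) == 0)
    return(structure(integer(0), n_pockets = 0L))
  cl <- cpp_cluster(frame$positions, frame$box, frame$tilt, 0L, 2L,
                    solv - 1L, cutoff, matrix(integer(), 0, 2),
                    integer(0), 1L)
  wrapping <- apply(cl$wraps, 1, any)
  enc_clusters <- which(!wrapping)
  idx <- solv[cl$labels %in% enc_clusters]
  structure(idx,
            n_pockets = length(unique(cl$labels[cl$labels %in% enc_clusters])))
}

#' Cargo release time series
#'
#' Tracks the fraction of the originally encapsulated cargo (S0) beads that
#' remain encapsulated in each frame of a trajectory.  The reference set
#' `s0_ids` is fixed at the series start, so the first value is 1 whenever
#' the set is taken from the first frame.
#'
#' @param traj A `dpd_traj` or a list of `dpd_frame`s.
#' @param s0_ids Bead indices encapsulated at the series start; defaults to
#'   the first frame's encapsulated solvent.
#' @param cutoff Linkage distance for the encapsulation test.
#' @return A `release_series` data frame with columns `step` and `fraction`.
#' @export
release_timeseries <- function(traj, s0_ids = NULL, cutoff = 1) {
  frames <- if (inherits(traj, "dpd_traj")) traj$frames else traj
  if (length(frames) == 0) stop("empty trajectory")
  if (is.null(s0_ids)) s0_ids <- encapsulated_solvent(frames[[1]], cutoff)
  if (length(s0_ids) == 0) stop("'s0_ids' is empty: no cargo to track")
  frac <- vapply(frames, function(f) {
    enc <- encapsulated_solvent(f, cutoff)
    length(intersect(enc, s0_ids)) / length(s0_ids)
  }, numeric(1))
  out <- data.frame(step = vapply(frames, function(f) f$step, numeric(1)),
                    fraction = frac)
  class(out) <- c("release_series", "data.frame")
  out
}

# internal: molecule labels from a bond list (union-find over n beads)
molecule_ids <- function(n, bonds) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(bonds))) {
    a <- find(bonds[k, 1])
    b <- find(bonds[k, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# internal: contiguous runs of TRUE over profile bins; returns a list of
# (from, to) row index pairs.  Contiguity is judged on the radial grid, not
# on row order: a dropped (empty) bin between two rows breaks a band.
band_runs <- function(flag, r = seq_along(flag), bin_width = 1) {
  bin <- round(r / bin_width - 0.5)
  bands <- list()
  start <- NULL
  for (k in seq_along(flag)) {
    gap <- k > 1 && bin[k] != bin[k - 1] + 1
    if (!is.null(start) && (gap || !flag[k])) {
      bands <- c(bands, list(c(start, k - 1)))
      start <- NULL
    }
    if (flag[k] && is.null(start)) start <- k
  }
  if (!is.null(start)) bands <- c(bands, list(c(start, length(flag))))
  bands
}

#' Interconnected same-species bead count from the inner shell
#'
#' Measures membrane connectivity of a vesicle: same-species beads closer
#' than `cutoff` are considered connected, and the count `n` of beads
#' reachable from the vesicle's inner hydrophilic shell tracks whether the
#' inner and outer shells are linked by a hydrophilic path across the
#' membrane.  The inner (outer) shell is the innermost (outermost) radial
#' band where the species' number fraction exceeds `band_threshold`.
#'
#' @param frame A `dpd_frame`.
#' @param species Species label to trace (e.g. `"A"` for the onion vesicle,
#'   `"C"` for the hydrophilic-C unilamellar vesicle).
#' @param aggregate Optional aggregate (element of
#'   `find_aggregates()$clusters`) providing the bead set and centre.  The
#'   default `NULL` analyses every polymer bead in the frame about the
#'   polymer centre of mass — the right choice for multi-membrane (onion)
#'   structures, whose concentric membranes are disjoint clusters separated
#'   by solvent but belong to one vesicle.
#' @param cutoff Connection distance (default 1, the interaction range).
#' @param bin_width Radial bin width for the shell-finding profile.
#' @param band_threshold Number-fraction threshold defining a shell band
#'   (default 0.25).
#' @return A `connectivity_result`: list with `n` (reachable same-species
#'   beads), `n_inner` (inner-shell seed count), `n_max` (species total in
#'   the aggregate), `linked` (inner and outer shells connected), and the
#'   shell radial ranges as evidence.
#' @export
interconnected_count <- function(frame, species, aggregate = NULL,
                                 cutoff = 1, bin_width = 0.25,
                                 band_threshold = 0.25) {
  if (!species %in% DPD_SPECIES) stop("unknown species: ", species)
  if (is.null(aggregate)) {
    members <- which(frame$species != "S")
    if (length(members) == 0) stop("no polymer beads in the frame")
    aggregate <- list(members = members,
                      com = periodic_center(
                        frame$positions[members, , drop = FALSE],
                        frame$box, frame$tilt))
  }
  members <- aggregate$members
  sp_beads <- members[frame$species[members] == species]
  if (length(sp_beads) == 0)
    stop(sprintf("species '%s' absent from the aggregate", species))
  prof <- composition_profile(frame, aggregate, bin_width)
  fcol <- paste0("f", species)
  bands <- band_runs(prof[[fcol]] > band_threshold, prof$r, bin_width)
  if (length(bands) == 0)
    stop(sprintf("no radial band of species '%s' above the threshold",
                 species))
  rng <- function(b) c(prof$r[b[1]] - bin_width / 2, prof$r[b[2]] + bin_width / 2)
  inner <- rng(bands[[1]])
  outer <- rng(bands[[length(bands)]])
  com <- aggregate$com
  d <- minimum_image(sweep(frame$positions[sp_beads, , drop = FALSE], 2, com),
                     frame$box, frame$tilt)
  r <- sqrt(rowSums(d^2))
  seeds <- sp_beads[r >= inner[1] & r < inner[2]]
  outer_set <- sp_beads[r >= outer[1] & r < outer[2]]
  if (length(seeds) == 0) stop("inner shell contains no beads")
  cl <- cpp_cluster(frame$positions, frame$box, frame$tilt, 0L, 2L,
                    sp_beads - 1L, cutoff, matrix(integer(), 0, 2),
                    integer(0), 1L)
  lab <- setNames(cl$labels, sp_beads)
  seed_labs <- unique(lab[as.character(seeds)])
  reached <- sp_beads[cl$labels %in% seed_labs]
  n <- length(reached)
  n_inner <- length(seeds)
  linked <- n > n_inner &&
    length(bands) > 1 && any(outer_set %in% reached)
  structure(list(n = n, n_inner = n_inner, n_max = length(sp_beads),
                 linked = linked, species = species,
                 inner_range = inner, outer_range = outer,
                 reached = reached),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("Connectivity of %s-beads: n = %d (inner shell n_i = %d, total n_max = %d)\n",
              x$species, x$n, x$n_inner, x$n_max))
  cat(sprintf("  inner shell r in [%.2f, %.2f), outer in [%.2f, %.2f); shells %slinked\n",
              x$inner_range[1], x$inner_range[2], x$outer_range[1],
              x$outer_range[2], if (x$linked) "" else "not "))
  invisible(x)
}

#' Membrane thickness from a composition profile
#'
#' Width of the dominant hydrophobic band: the combined number fraction of
#' the hydrophobic species is scanned for contiguous bins above 0.5, the band
#' with the largest integrated bead count is selected, and the two crossings
#' of the 0.5 level on its flanks are located by linear interpolation between
#' bin centres.  A band touching the profile edge is bounded by the bin edge.
#'
#' @param profile A `composition_profile`.
#' @param hydrophobic_species Character vector of hydrophobic species labels
#'   (e.g. `c("B", "C")` for the hydrophilic-A onion vesicle).
#' @return Thickness (length units), with attribute `band` (the crossing
#'   radii).
#' @export
membrane_thickness <- function(profile, hydrophobic_species) {
  cols <- paste0("f", hydrophobic_species)
  if (!all(cols %in% names(profile)))
    stop("unknown species in 'hydrophobic_species'")
  h <- rowSums(profile[, cols, drop = FALSE])
  r <- profile$r
  bw <- attr(profile, "bin_width")
  if (is.null(bw)) bw <- if (length(r) > 1) min(diff(r)) else 0.25
  bands <- band_runs(h > 0.5, r, bw)
  if (length(bands) == 0)
    stop("no membrane: hydrophobic fraction never exceeds 0.5")
  mass <- vapply(bands, function(b)
    sum(h[b[1]:b[2]] * profile$n[b[1]:b[2]]), numeric(1))
  b <- bands[[which.max(mass)]]
  adjacent <- function(i, j) abs(r[i] - r[j]) < 1.5 * bw
  cross <- function(i_out, i_in) {
    # linear interpolation of the 0.5 crossing between adjacent bin centres
    r[i_out] + (0.5 - h[i_out]) / (h[i_in] - h[i_out]) * (r[i_in] - r[i_out])
  }
  lo <- if (b[1] == 1 || !adjacent(b[1] - 1, b[1]))
    max(0, r[b[1]] - bw / 2) else cross(b[1] - 1, b[1])
  hi <- if (b[2] == length(r) || !adjacent(b[2] + 1, b[2]))
    r[b[2]] + bw / 2 else cross(b[2] + 1, b[2])
  structure(hi - lo, band = c(lo, hi))
}

#' Classify the morphology of a frame
#'
#' Decision tree over the aggregate structure, mirroring the categories of
#' the self-assembly state diagram:
#'
#' 1. `disordered` — the largest polymer cluster holds less than half the
#'    polymer beads (chains remain dispersed);
#' 2. `lamella` — the largest cluster is connected to its own periodic image
#'    (a membrane spanning the box);
#' 3. vesicle family — encapsulated solvent exists: `onion_vesicle` when the
#'    radial profile shows two or more concentric polymer membrane bands,
#'    `vesicle_in_vesicle` when a single band coexists with two or more
#'    disjoint solvent pockets, otherwise `unilamellar_vesicle`;
#' 4. micelle family — no encapsulated solvent: bins dominated by polymer
#'    are assigned their leading species; three or more alternating species
#'    bands give `onion_micelle`, fewer but orderly bands `layered_micelle`,
#'    and the absence of radial species ordering `irregular_sphere`.
#'
#' The returned label carries an `evidence` attribute recording every
#' quantity and threshold the decision used.
#'
#' @param frame A `dpd_frame`.
#' @param cutoff Clustering contact distance (default 0.8, as in
#'   [find_aggregates()]).
#' @param bin_width Radial profile bin width (default 0.25).
#' @param solvent_cutoff Linkage distance for the solvent-pocket test
#'   (default 1, as in [encapsulated_solvent()]).
#' @return Character label with attribute `evidence`.
#' @export
classify_morphology <- function(frame, cutoff = 0.8, bin_width = 0.25,
                                solvent_cutoff = 1) {
  ags <- find_aggregates(frame, cutoff)
  ev <- list(cutoff = cutoff, bin_width = bin_width,
             mass_threshold = 0.5, band_threshold = 0.5)
  lab <- function(label) structure(label, evidence = ev)
  if (length(ags$clusters) == 0) {
    ev$largest_fraction <- 0
    return(lab("disordered"))
  }
  big <- ags$clusters[[1]]
  ev$largest_fraction <- big$size / ags$n_polymer
  if (ev$largest_fraction < 0.5) return(lab("disordered"))
  ev$wraps <- big$wraps
  if (any(big$wraps)) return(lab("lamella"))
  enc <- encapsulated_solvent(frame, solvent_cutoff)
  ev$n_encapsulated <- length(enc)
  ev$n_pockets <- attr(enc, "n_pockets")
  prof <- composition_profile(frame, big, bin_width)
  poly <- prof$fA + prof$fB + prof$fC
  mem_bands <- band_runs(poly > 0.5, prof$r, bin_width)
  ev$n_membrane_bands <- length(mem_bands)
  if (length(enc) > 0) {
    if (length(mem_bands) >= 2) return(lab("onion_vesicle"))
    if (!is.null(ev$n_pockets) && ev$n_pockets >= 2)
      return(lab("vesicle_in_vesicle"))
    return(lab("unilamellar_vesicle"))
  }
  # micelle family: radial species ordering within polymer-dominated bins
  if (length(mem_bands) == 0) return(lab("irregular_sphere"))
  pb <- which(poly > 0.5)
  fr_poly <- cbind(prof$fA, prof$fB, prof$fC)[pb, , drop = FALSE] / poly[pb]
  dom <- apply(fr_poly, 1, max)
  lead <- c("A", "B", "C")[apply(fr_poly, 1, which.max)]
  ordered <- dom >= 0.5
  ev$fraction_ordered_bins <- mean(ordered)
  if (mean(ordered) < 0.5) return(lab("irregular_sphere"))
  runs <- rle(lead[ordered])$values
  ev$species_bands <- runs
  if (length(runs) >= 3) return(lab("onion_micelle"))
  lab("layered_micelle")
}
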