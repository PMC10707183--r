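# Synthetic idealized aggregates with known ground truth.  These are
# geometric constructions, not relaxed configurations: beads are sampled
# uniformly on spherical annuli (or slabs) at the target density, so analysis
# operators can be validated against labels known by construction without
# running dynamics.

# uniform sample inside a spherical annulus [r0, r1)
sample_annulus <- function(n, r0, r1, center) {
  if (n <= 0) return(matrix(numeric(), 0, 3))
  r <- (runif(n) * (r1^3 - r0^3) + r0^3)^(1 / 3)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  sweep(u * r, 2, center, `+`)
}

# exactly n solvent beads in the box outside a sphere of radius R
sample_exterior_n <- function(n, box, center, R, max_tries = 500) {
  out <- matrix(numeric(), 0, 3)
  tries <- 0
  while (nrow(out) < n && tries < max_tries) {
    m <- max(2 * (n - nrow(out)), 100)
    p <- matrix(runif(3 * m), m, 3) %*% diag(box)
    d <- minimum_image(sweep(p, 2, center), box)
    keep <- sqrt(rowSums(d^2)) >= R
    out <- rbind(out, p[keep, , drop = FALSE])
    tries <- tries + 1
  }
  out[seq_len(min(n, nrow(out))), , drop = FALSE]
}

# solvent filling the box outside a sphere of radius R about center
sample_exterior <- function(density, box, center, R) {
  V <- prod(box) - 4 / 3 * pi * R^3
  sample_exterior_n(round(density * V), box, center, R)
}

shells_from <- function(inner_radius, thicknesses) {
  r <- inner_radius + cumsum(c(0, thicknesses))
  cbind(r[-length(r)], r[-1])
}

# Assemble parts into a frame, then repair contiguity: uniform sampling at
# density 3 occasionally leaves a bead more than one cutoff from the rest of
# its region, which would corrupt ground-truth labels (an isolated exterior
# solvent bead would read as a cargo pocket).  Beads disconnected from the
# largest cluster of their repair group are re-drawn from the part's own
# sampler until each group is single-linkage connected.
assemble_fixture <- function(parts, box, meta) {
  pos <- do.call(rbind, lapply(parts, `[[`, "pos"))
  species <- unlist(lapply(parts, function(p) rep(p$species, nrow(p$pos))))
  cargo <- unlist(lapply(parts, function(p) rep(isTRUE(p$cargo), nrow(p$pos))))
  shell <- unlist(lapply(parts, function(p) rep(p$shell, nrow(p$pos))))
  group <- unlist(lapply(parts, function(p)
    rep(if (is.null(p$group)) NA_character_ else p$group, nrow(p$pos))))
  part_of <- rep(seq_along(parts),
                 vapply(parts, function(p) nrow(p$pos), integer(1)))
  for (g in setdiff(unique(group), NA)) {
    idx <- which(group == g)
    if (length(idx) < 2) next
    cutoff <- if (any(species[idx] == "S")) 1 else 0.8
    for (iter in 1:60) {
      cl <- cpp_cluster(pos, box, 0, 0L, 2L, idx - 1L, cutoff,
                        matrix(integer(), 0, 2), integer(0), 1L)
      if (cl$n_clusters == 1) break
      main <- which.max(tabulate(cl$labels))
      stray <- idx[cl$labels != main]
      for (i in stray) {
        rs <- parts[[part_of[i]]]$resample
        if (is.null(rs)) next
        pos[i, ] <- rs(1)
      }
    }
  }
  fr <- dpd_frame(pos, species = species, box = box, cargo = cargo)
  attr(fr, "ground_truth") <- list(
    shell = shell, cargo_ids = which(cargo), spec = meta)
  fr
}

#' Synthetic unilamellar vesicle
#'
#' A single closed membrane of concentric spherical shells (inside to out:
#' C, B, A, B, C — the hydrophilic-C vesicle geometry), a solvent-filled
#' cavity whose beads are tagged as cargo (S0), and untagged exterior solvent.
#' Each region is populated at the bead density of `params` by uniform
#' sampling, so profiles and clusterings face realistic (non-crystalline)
#' point sets.  The construction is rejected if the vesicle would touch its
#' own periodic image.
#'
#' @param inner_radius Cavity radius (length units).
#' @param thicknesses Per-shell thicknesses, inside to out, one per entry of
#'   `shell_species` (default five shells of total thickness 3).
#' @param box Box edge lengths (one number for a cubic box).
#' @param cargo_n Cavity cargo bead count; `NULL` (default) fills the cavity
#'   at the bead density, `0` leaves it empty.
#' @param shell_species Species per shell, inside to out.
#' @param seed Integer RNG seed.
#' @param params A [dpd_params()] (supplies the density).
#' @return A `dpd_frame` with attribute `ground_truth`: per-bead shell label
#'   (`"cavity"`, shell index, or `"exterior"`), cargo indices, and the
#'   construction parameters.
#' @examples
#' v <- make_unilamellar_vesicle(4, box = 20, seed = 1)
#' length(attr(v, "ground_truth")$cargo_ids)
#' @export
make_unilamellar_vesicle <- function(inner_radius = 4,
                                     thicknesses = c(0.5, 0.6, 0.8, 0.6, 0.5),
                                     box = 20, cargo_n = NULL,
                                     shell_species = c("C", "B", "A", "B", "C"),
                                     seed = 1, params = dpd_params()) {
  box <- if (length(box) == 1) rep(box, 3) else as.numeric(box)
  if (length(thicknesses) != length(shell_species))
    stop("'thicknesses' must have one entry per shell")
  R_out <- inner_radius + sum(thicknesses)
  if (R_out + params$rc >= min(box) / 2)
    stop("vesicle does not fit: outer radius + rc exceeds half the box")
  set.seed(as.integer(seed %% .Machine$integer.max))
  center <- box / 2
  rho <- params$density
  sh <- shells_from(inner_radius, thicknesses)
  parts <- list()
  n_cav <- if (is.null(cargo_n))
    round(rho * 4 / 3 * pi * inner_radius^3) else cargo_n
  if (n_cav > 0)
    parts <- c(parts, list(list(
      pos = sample_annulus(n_cav, 0, inner_radius, center), species = "S",
      cargo = TRUE, shell = "cavity", group = "cavity",
      resample = function(n) sample_annulus(n, 0, inner_radius, center))))
  for (k in seq_len(nrow(sh))) {
    n <- round(rho * 4 / 3 * pi * (sh[k, 2]^3 - sh[k, 1]^3))
    r0 <- sh[k, 1]; r1 <- sh[k, 2]
    parts <- c(parts, list(list(
      pos = sample_annulus(n, r0, r1, center),
      species = shell_species[k], cargo = FALSE, shell = as.character(k),
      group = "polymer",
      resample = local({ a <- r0; b <- r1
        function(n) sample_annulus(n, a, b, center) }))))
  }
  parts <- c(parts, list(list(
    pos = sample_exterior(rho, box, center, R_out), species = "S",
    cargo = FALSE, shell = "exterior", group = "exterior",
    resample = function(n) sample_exterior_n(n, box, center, R_out))))
  assemble_fixture(parts, box, list(
    kind = "unilamellar_vesicle", inner_radius = inner_radius,
    thicknesses = thicknesses, shell_species = shell_species,
    membrane_thickness = sum(thicknesses), seed = seed))
}

#' Synthetic onion-like vesicle (or micelle)
#'
#' Concentric multi-membrane aggregate: `n_lamellae` membranes, each a stack
#' of shells (default A, B, C, B, A — the hydrophilic-A onion geometry),
#' separated by solvent-filled gaps.  Interlamellar and cavity solvent is
#' tagged as cargo; optionally a fraction of solvent is co-located inside the
#' hydrophilic shells themselves, reproducing the S-peaks-on-A-peaks
#' signature of onion vesicles.  With `cargo = FALSE`, `gap = 0` and
#' `inner_radius = 0` the construction degenerates to a solvent-free
#' onion-like micelle.
#'
#' @param inner_radius Cavity radius; 0 for a solid (micellar) core.
#' @param n_lamellae Number of concentric membranes.
#' @param membrane_species Species per shell within one membrane, inside out.
#' @param membrane_thicknesses Thickness per shell within one membrane.
#' @param gap Solvent gap between membranes (and around the cavity edge).
#' @param cargo Tag interior solvent as S0 cargo (default TRUE).
#' @param solvent_in_shell Solvent co-located in hydrophilic (first/last
#'   species) shells, as a fraction of the local density (default 0.25).
#' @inheritParams make_unilamellar_vesicle
#' @return A `dpd_frame` with `ground_truth` as in
#'   [make_unilamellar_vesicle()].
#' @export
make_onion_vesicle <- function(inner_radius = 3, n_lamellae = 2,
                               membrane_species = c("A", "B", "C", "B", "A"),
                               membrane_thicknesses = c(0.6, 0.6, 0.8, 0.6, 0.6),
                               gap = 1.2, cargo = TRUE,
                               solvent_in_shell = 0.25, box = 24, seed = 1,
                               params = dpd_params()) {
  box <- if (length(box) == 1) rep(box, 3) else as.numeric(box)
  if (length(membrane_thicknesses) != length(membrane_species))
    stop("'membrane_thicknesses' must have one entry per shell")
  hydro <- unique(membrane_species[c(1, length(membrane_species))])
  thicknesses <- c()
  spec <- c()
  kind <- c()
  for (m in seq_len(n_lamellae)) {
    if (m > 1 && gap > 0) {
      thicknesses <- c(thicknesses, gap)
      spec <- c(spec, "S")
      kind <- c(kind, "gap")
    }
    thicknesses <- c(thicknesses, membrane_thicknesses)
    spec <- c(spec, membrane_species)
    kind <- c(kind, rep("membrane", length(membrane_species)))
  }
  R_out <- inner_radius + sum(thicknesses)
  if (R_out + params$rc >= min(box) / 2)
    stop("onion does not fit: outer radius + rc exceeds half the box")
  set.seed(as.integer(seed %% .Machine$integer.max))
  center <- box / 2
  rho <- params$density
  sh <- shells_from(inner_radius, thicknesses)
  parts <- list()
  if (inner_radius > 0 && cargo)
    parts <- c(parts, list(list(
      pos = sample_annulus(round(rho * 4 / 3 * pi * inner_radius^3), 0,
                           inner_radius, center),
      species = "S", cargo = TRUE, shell = "cavity", group = "cavity",
      resample = function(n) sample_annulus(n, 0, inner_radius, center))))
  for (k in seq_along(spec)) {
    vol <- 4 / 3 * pi * (sh[k, 2]^3 - sh[k, 1]^3)
    r0 <- sh[k, 1]; r1 <- sh[k, 2]
    rs <- local({ a <- r0; b <- r1
      function(n) sample_annulus(n, a, b, center) })
    if (kind[k] == "gap") {
      parts <- c(parts, list(list(
        pos = sample_annulus(round(rho * vol), r0, r1, center),
        species = "S", cargo = cargo, shell = sprintf("gap%d", k),
        group = sprintf("gap%d", k), resample = rs)))
    } else {
      parts <- c(parts, list(list(
        pos = sample_annulus(round(rho * vol), r0, r1, center),
        species = spec[k], cargo = FALSE, shell = as.character(k),
        group = "polymer", resample = rs)))
      if (spec[k] %in% hydro && solvent_in_shell > 0) {
        ns <- round(rho * vol * solvent_in_shell)
        if (ns > 0)
          parts <- c(parts, list(list(
            pos = sample_annulus(ns, r0, r1, center),
            species = "S", cargo = cargo, shell = sprintf("inshell%d", k))))
      }
    }
  }
  parts <- c(parts, list(list(
    pos = sample_exterior(rho, box, center, R_out), species = "S",
    cargo = FALSE, shell = "exterior", group = "exterior",
    resample = function(n) sample_exterior_n(n, box, center, R_out))))
  assemble_fixture(parts, box, list(
    kind = if (cargo) "onion_vesicle" else "onion_micelle",
    inner_radius = inner_radius, n_lamellae = n_lamellae,
    membrane_species = membrane_species,
    membrane_thicknesses = membrane_thicknesses, gap = gap,
    membrane_thickness = sum(membrane_thicknesses), seed = seed))
}

#' Synthetic planar bilayer (lamella)
#'
#' A membrane slab spanning the box in x and y with its normal along z:
#' central C leaflet, flanking B layers, outer A layers, solvent elsewhere
#' (the strongly C-solvophobic lamella geometry).  Both solvent slabs wrap
#' periodically in-plane, so no solvent is encapsulated.
#'
#' @param box Box edge lengths.
#' @param thicknesses Layer thicknesses, bottom to top, for A, B, C, B, A.
#' @param seed Integer RNG seed.
#' @param params A [dpd_params()].
#' @return A `dpd_frame` with `ground_truth` (per-bead layer label and the
#'   construction parameters; no cargo).
#' @export
make_planar_bilayer <- function(box = 16,
                                thicknesses = c(0.6, 0.6, 1.0, 0.6, 0.6),
                                seed = 1, params = dpd_params()) {
  box <- if (length(box) == 1) rep(box, 3) else as.numeric(box)
  layer_species <- c("A", "B", "C", "B", "A")
  total <- sum(thicknesses)
  if (total >= box[3]) stop("membrane thicker than the box")
  set.seed(as.integer(seed %% .Machine$integer.max))
  rho <- params$density
  z0 <- box[3] / 2 - total / 2
  edges <- z0 + cumsum(c(0, thicknesses))
  parts <- list()
  slab <- function(n, zlo, zhi)
    cbind(runif(n) * box[1], runif(n) * box[2], runif(n, zlo, zhi))
  for (k in seq_along(layer_species)) {
    n <- round(rho * box[1] * box[2] * thicknesses[k])
    zlo <- edges[k]; zhi <- edges[k + 1]
    parts <- c(parts, list(list(
      pos = slab(n, zlo, zhi), species = layer_species[k],
      cargo = FALSE, shell = as.character(k), group = "polymer",
      resample = local({ a <- zlo; b <- zhi
        function(n) slab(n, a, b) }))))
  }
  for (side in 1:2) {
    lo <- if (side == 1) 0 else edges[length(edges)]
    hi <- if (side == 1) z0 else box[3]
    n <- round(rho * box[1] * box[2] * (hi - lo))
    parts <- c(parts, list(list(
      pos = slab(n, lo, hi), species = "S", cargo = FALSE,
      shell = sprintf("solvent%d", side), group = sprintf("solvent%d", side),
      resample = local({ a <- lo; b <- hi
        function(n) slab(n, a, b) }))))
  }
  assemble_fixture(parts, box, list(
    kind = "lamella", thicknesses = thicknesses,
    layer_species = layer_species, membrane_thickness = total,
    center_z = box[3] / 2, seed = seed))
}
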