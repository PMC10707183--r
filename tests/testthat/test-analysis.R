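test_that("aggregate clustering separates distant chains and joins a vesicle", {
  # two 5-bead chains 3 rc apart -> two clusters
  p1 <- cbind(4 + 0.4 * (0:4), 5, 5)
  p2 <- cbind(4 + 0.4 * (0:4), 8.5, 5)
  fr <- dpd_frame(rbind(p1, p2), species = rep(c("A"), 10), box = 12)
  ag <- find_aggregates(fr, cutoff = 1)
  expect_length(ag$clusters, 2)
  expect_identical(vapply(ag$clusters, `[[`, integer(1), "size"), c(5L, 5L))

  v <- make_unilamellar_vesicle(box = 20, seed = 1)
  agv <- find_aggregates(v)
  expect_length(agv$clusters, 1)
  expect_identical(agv$clusters[[1]]$size, sum(v$species != "S"))
})

test_that("clustering agrees with the exhaustive-pair oracle", {
  skip_if_not_installed("igraph")
  fr <- build_system(5, 0.8, chain_topology(1, 1, 1), seed = 2)  # 300 polymer beads
  poly <- which(fr$species != "S")
  labels_of <- function(ag) {
    mine <- integer(length(poly))
    for (k in seq_along(ag$clusters))
      mine[match(ag$clusters[[k]]$members, poly)] <- k
    mine
  }
  # plain single linkage (contact or bond) vs exhaustive igraph components
  ag <- find_aggregates(fr, cutoff = 0.8, min_contacts = 1)
  adj <- oracle_dist(fr$positions[poly, ], fr$box) < 0.8
  b <- fr$bonds
  adj[cbind(match(b[, 1], poly), match(b[, 2], poly))] <- TRUE
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  expect_true(same_partition(labels_of(ag), igraph::components(g)$membership))

  # molecule-contact rule vs an independent chain-graph oracle
  ag3 <- find_aggregates(fr, cutoff = 0.8, min_contacts = 3)
  mol <- (poly - 1) %/% 5 + 1            # 5-bead chains, consecutive indices
  d <- oracle_dist(fr$positions[poly, ], fr$box)
  nmol <- max(mol)
  madj <- matrix(FALSE, nmol, nmol)
  for (a in seq_len(nmol)) for (bb in seq_len(nmol)) {
    if (a < bb)
      madj[a, bb] <- madj[bb, a] <-
        sum(d[mol == a, mol == bb] < 0.8) >= 3
  }
  gm <- igraph::graph_from_adjacency_matrix(madj, mode = "undirected")
  mol_comp <- igraph::components(gm)$membership
  expect_true(same_partition(labels_of(ag3), mol_comp[mol]))
})

test_that("profiles agree with a brute-force binning oracle and homogeneity", {
  fr <- build_system(8, 0.3, ref_topology, seed = 3)
  agg <- which(fr$species != "S")
  prof <- composition_profile(fr, agg, bin_width = 1)
  # independent binning: exhaustive-image distances, plain table arithmetic
  com <- pentadpd:::periodic_center(fr$positions[agg, , drop = FALSE],
                                    fr$box, 0)
  r <- apply(fr$positions, 1, function(p)
    sqrt(sum(oracle_min_image(p - com, fr$box)^2)))
  bin <- floor(r / 1)
  for (k in seq_len(nrow(prof))) {
    sel <- bin == round(prof$r[k] - 0.5)
    expect_identical(sum(sel), prof$n[k])
    expect_equal(mean(fr$species[sel] == "A"), prof$fA[k])
    expect_equal(mean(fr$species[sel] == "S"), prof$fS[k])
  }
  # a homogeneous system has no radial structure: busy bins sit near the
  # global fractions (chains clump, so allow generous statistical room)
  glob <- mean(fr$species == "S")
  busy <- prof$n > 200
  expect_true(all(abs(prof$fS[busy] - glob) < 0.2))
  # normalisation in every reported bin
  expect_equal(prof$fA + prof$fB + prof$fC + prof$fS, rep(1, nrow(prof)))
})

test_that("profile and encapsulation are invariant under translation and re-wrapping", {
  v <- make_unilamellar_vesicle(box = 18, seed = 4)
  enc0 <- sort(encapsulated_solvent(v))
  m0 <- classify_morphology(v)
  ag0 <- find_aggregates(v)$clusters[[1]]
  th0 <- membrane_thickness(composition_profile(v, ag0, 0.25), c("A", "B"))
  for (shift in list(c(5.3, -2.2, 9.9), c(-17.1, 0.4, 3.3))) {
    w <- v
    w$positions <- sweep(w$positions, 2, shift, `+`)
    w <- wrap_frame(w)
    expect_identical(sort(encapsulated_solvent(w)), enc0)
    expect_identical(as.character(classify_morphology(w)), as.character(m0))
    agw <- find_aggregates(w)$clusters[[1]]
    thw <- membrane_thickness(composition_profile(w, agw, 0.25), c("A", "B"))
    expect_equal(as.numeric(thw), as.numeric(th0), tolerance = 1e-6)
  }
})

test_that("encapsulation distinguishes cavities from percolating solvent", {
  v <- make_unilamellar_vesicle(box = 18, seed = 5)
  gt <- attr(v, "ground_truth")
  expect_identical(sort(encapsulated_solvent(v)), sort(gt$cargo_ids))

  pure <- solvent_system(6, seed = 6)
  expect_length(encapsulated_solvent(pure), 0)

  b <- make_planar_bilayer(box = 12, seed = 7)
  expect_length(encapsulated_solvent(b), 0)
})

test_that("release series starts at one and tracks teleported cargo", {
  v <- make_unilamellar_vesicle(box = 18, seed = 8)
  s0 <- encapsulated_solvent(v)
  rel <- release_timeseries(list(v), s0)
  expect_identical(rel$fraction, 1)

  # teleport half the cavity beads far outside the vesicle
  v2 <- v
  half <- s0[seq_len(length(s0) %/% 2)]
  v2$positions[half, ] <- matrix(runif(3 * length(half), 0, 1.5),
                                 ncol = 3)
  v2$step <- 100
  rel2 <- release_timeseries(list(v, v2), s0)
  expect_equal(rel2$fraction[2], 1 - length(half) / length(s0),
               tolerance = 0.02)

  # values depend only on bead identity, not on tags of other solvent
  v3 <- v2
  v3$cargo[] <- FALSE
  rel3 <- release_timeseries(list(v, v3), s0)
  expect_identical(rel2$fraction, rel3$fraction)

  expect_error(release_timeseries(list(v), integer(0)), "empty")
})

test_that("connectivity counts reachable shells and detects bridges", {
  skip_if_not_installed("igraph")
  # two concentric A shells separated by > cutoff, solvent elsewhere
  box <- c(20, 20, 20)
  center <- box / 2
  set.seed(9)
  inner <- pentadpd:::sample_annulus(500, 3, 3.6, center)
  outer <- pentadpd:::sample_annulus(1400, 5.4, 6, center)
  # solvent fills the cavity, the inter-shell gap and the exterior, as it
  # would in a simulated vesicle (fraction thresholds need a medium)
  solv <- rbind(pentadpd:::sample_annulus(300, 0, 3, center),
                pentadpd:::sample_annulus(1200, 3.6, 5.4, center),
                pentadpd:::sample_exterior(1.5, box, center, 6))
  fr <- dpd_frame(rbind(inner, outer, solv),
                  species = c(rep("A", 1900), rep("S", nrow(solv))),
                  box = box)
  ag <- list(members = seq_len(1900), com = center, size = 1900,
             wraps = rep(FALSE, 3))
  cn <- interconnected_count(fr, "A", ag, cutoff = 1)
  expect_identical(cn$n, cn$n_inner)
  expect_false(cn$linked)
  expect_identical(cn$n_max, 1900L)

  # add a radial bridge of A beads linking the shells
  bridge <- cbind(center[1] + seq(3.2, 5.6, by = 0.3), center[2], center[3])
  fr2 <- dpd_frame(rbind(inner, outer, bridge, solv),
                   species = c(rep("A", 1900 + nrow(bridge)),
                               rep("S", nrow(solv))),
                   box = box)
  ag2 <- list(members = seq_len(1900 + nrow(bridge)), com = center,
              size = 1900 + nrow(bridge), wraps = rep(FALSE, 3))
  cn2 <- interconnected_count(fr2, "A", ag2, cutoff = 1)
  expect_identical(cn2$n, cn2$n_max)
  expect_true(cn2$linked)

  # oracle agreement: reachable set = components containing inner-shell seeds
  a_beads <- seq_len(1900 + nrow(bridge))
  ora <- oracle_components(fr2$positions[a_beads, ], box, 1)
  seeds <- which(sqrt(rowSums(sweep(fr2$positions[a_beads, ], 2,
                                    center)^2)) < 4)
  expect_identical(cn2$n, sum(ora %in% unique(ora[seeds])))

  # every bead mutually within the cutoff: n = n_max
  tight <- dpd_frame(matrix(runif(60, 9.7, 10.3), 20, 3),
                     species = rep("A", 20), box = box)
  agt <- list(members = 1:20, com = center, size = 20,
              wraps = rep(FALSE, 3))
  cnt <- interconnected_count(tight, "A", agt, cutoff = 1)
  expect_identical(cnt$n, 20L)

  expect_error(interconnected_count(fr, "C", ag), "absent")
})

test_that("membrane thickness interpolates the half-maximum crossings", {
  # step profile: hydrophobic fraction 1 on [5.0, 7.7], bin width 0.1
  r <- seq(0.05, 11.95, by = 0.1)
  inside <- r > 5 & r < 7.7
  prof <- data.frame(r = r, fA = as.numeric(inside), fB = 0, fC = 0,
                     fS = as.numeric(!inside), n = 50)
  attr(prof, "bin_width") <- 0.1
  class(prof) <- c("composition_profile", "data.frame")
  th <- membrane_thickness(prof, "A")
  expect_equal(as.numeric(th), 2.7, tolerance = 1e-12)
  expect_error(membrane_thickness(
    transform(prof, fA = fA * 0.4), "A"), "no membrane")
})

test_that("fixture membrane thickness is recovered within one bin", {
  for (total in c(2.0, 3.0)) {
    v <- make_unilamellar_vesicle(
      inner_radius = 4, thicknesses = rep(total / 5, 5), box = 20, seed = 10)
    ag <- find_aggregates(v)$clusters[[1]]
    prof <- composition_profile(v, ag, 0.25)
    th <- membrane_thickness(prof, c("A", "B", "C"))
    expect_equal(as.numeric(th), total, tolerance = 0.25 / total + 1e-9)
  }
})

test_that("membrane thickness grows with the central block on matched fixtures", {
  # vesicles whose hydrophobic A layer scales with the A-block length
  th <- vapply(c(6, 12, 18), function(lA) {
    v <- make_unilamellar_vesicle(
      inner_radius = 4,
      thicknesses = c(0.5, 0.6, 0.14 * lA, 0.6, 0.5),
      box = 22, seed = 11)
    ag <- find_aggregates(v)$clusters[[1]]
    prof <- composition_profile(v, ag, 0.25)
    as.numeric(membrane_thickness(prof, c("A", "B")))
  }, numeric(1))
  expect_true(all(diff(th) > 0))
})

test_that("the classifier recovers every fixture and the mixed state", {
  expect_identical(
    as.character(classify_morphology(make_unilamellar_vesicle(box = 18,
                                                              seed = 12))),
    "unilamellar_vesicle")
  expect_identical(
    as.character(classify_morphology(make_onion_vesicle(seed = 12))),
    "onion_vesicle")
  expect_identical(
    as.character(classify_morphology(make_onion_vesicle(
      inner_radius = 0, gap = 0, cargo = FALSE, solvent_in_shell = 0,
      box = 20, seed = 12))),
    "onion_micelle")
  expect_identical(
    as.character(classify_morphology(make_planar_bilayer(box = 12,
                                                         seed = 12))),
    "lamella")
  hom <- build_system(10, 0.10, ref_topology, seed = 13)
  expect_identical(as.character(classify_morphology(hom)), "disordered")
  # the label always carries its evidence
  m <- classify_morphology(hom)
  ev <- attr(m, "evidence")
  expect_true(is.list(ev) && !is.null(ev$largest_fraction))
})
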