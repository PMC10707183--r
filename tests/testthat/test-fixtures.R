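test_that("unilamellar fixture places cargo inside the cavity", {
  v <- make_unilamellar_vesicle(inner_radius = 4,
                                thicknesses = c(0.5, 0.6, 0.8, 0.6, 0.5),
                                box = 20, seed = 1)
  gt <- attr(v, "ground_truth")
  center <- v$box / 2
  d <- minimum_image(sweep(v$positions[gt$cargo_ids, , drop = FALSE], 2,
                           center), v$box)
  expect_true(all(sqrt(rowSums(d^2)) < 4))
  expect_identical(gt$cargo_ids, which(v$cargo))
  expect_true(all(v$species[gt$cargo_ids] == "S"))
})

test_that("empty-cavity fixture has no cargo and no encapsulated solvent", {
  v <- make_unilamellar_vesicle(cargo_n = 0, box = 20, seed = 2)
  expect_identical(sum(v$cargo), 0L)
  expect_length(encapsulated_solvent(v), 0)
})

test_that("unilamellar fixture shows the C-B-A-B-C shell ordering in its profile", {
  v <- make_unilamellar_vesicle(inner_radius = 4,
                                thicknesses = c(0.5, 0.6, 0.8, 0.6, 0.5),
                                box = 20, seed = 3)
  ag <- find_aggregates(v)$clusters[[1]]
  prof <- composition_profile(v, ag, 0.25)
  # fractions at shell mid-radii match the constructed species
  at <- function(r) prof[which.min(abs(prof$r - r)), ]
  mids <- 4 + cumsum(c(0.5, 0.6, 0.8, 0.6, 0.5)) -
    c(0.5, 0.6, 0.8, 0.6, 0.5) / 2
  spec <- c("C", "B", "A", "B", "C")
  for (k in seq_along(mids)) {
    row <- at(mids[k])
    expect_gt(row[[paste0("f", spec[k])]], 0.6)
  }
  # cavity and far field are solvent
  expect_gt(at(1)$fS, 0.95)
  expect_gt(at(8)$fS, 0.95)
})

test_that("onion fixture co-locates solvent peaks with hydrophilic A shells", {
  o <- make_onion_vesicle(seed = 4)
  ag <- find_aggregates(o)$clusters[[1]]
  prof <- composition_profile(o, ag, 0.25)
  memb <- prof$fA + prof$fB + prof$fC > 0.5
  # at least two concentric membrane bands
  runs <- rle(memb)
  expect_gte(sum(runs$values), 2)
  # within the membrane region, solvent appears where A dominates the polymer
  inside <- prof$r < max(prof$r[memb])
  a_bins <- inside & prof$fA > 0.3
  b_bins <- inside & memb & prof$fB + prof$fC > 0.6
  expect_gt(mean(prof$fS[a_bins]), mean(prof$fS[b_bins]))
})

test_that("solvent-free onion variant is a micelle with empty encapsulation", {
  m <- make_onion_vesicle(inner_radius = 0, gap = 0, cargo = FALSE,
                          solvent_in_shell = 0, box = 20, seed = 5)
  expect_identical(sum(m$cargo), 0L)
  expect_length(encapsulated_solvent(m), 0)
})

test_that("onion fixture inner shell is internally connected", {
  o <- make_onion_vesicle(seed = 6)
  gt <- attr(o, "ground_truth")
  cn <- interconnected_count(o, "A")
  # the constructed innermost A shell is one connected piece, so the
  # reachable set is at least the whole inner shell
  inner_a <- sum(gt$shell == "1")
  expect_gte(cn$n, inner_a)
  expect_gte(cn$n_inner, 1)
  expect_true(cn$n <= cn$n_max)
})

test_that("planar bilayer encapsulates nothing and layers in order", {
  b <- make_planar_bilayer(box = 12, seed = 7)
  expect_length(encapsulated_solvent(b), 0)
  prof <- axis_profile(b, axis = 3, bin_width = 0.25)
  # A-B-C-B-A ordering along the normal
  memb <- prof$fA + prof$fB + prof$fC > 0.5
  lead <- c("A", "B", "C", "S")[apply(
    as.matrix(prof[memb, c("fA", "fB", "fC", "fS")]), 1, which.max)]
  expect_identical(rle(lead)$values, c("A", "B", "C", "B", "A"))
  # away from the boundary bins the membrane is pure polymer by construction
  core <- which(memb)
  core <- core[-c(1, length(core))]
  expect_true(all((prof$fA + prof$fB + prof$fC)[core] > 0.9))
})

test_that("fixtures are deterministic under a fixed seed", {
  expect_identical(make_unilamellar_vesicle(seed = 9),
                   make_unilamellar_vesicle(seed = 9))
  expect_identical(make_onion_vesicle(seed = 9), make_onion_vesicle(seed = 9))
  expect_identical(make_planar_bilayer(seed = 9), make_planar_bilayer(seed = 9))
  expect_false(identical(make_planar_bilayer(seed = 9)$positions,
                         make_planar_bilayer(seed = 10)$positions))
})

test_that("fixtures refuse geometry that overflows the box", {
  expect_error(make_unilamellar_vesicle(inner_radius = 9, box = 20), "fit")
  expect_error(make_onion_vesicle(inner_radius = 8, n_lamellae = 3,
                                  box = 20), "fit")
  expect_error(make_planar_bilayer(box = 3,
                                   thicknesses = c(1, 1, 1, 1, 1)),
               "thicker")
})
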