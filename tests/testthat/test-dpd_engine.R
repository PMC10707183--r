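test_that("conservative force follows the soft linear repulsion", {
  f <- conservative_force(25, c(0.5, 0, 0))
  expect_equal(f, c(12.5, 0, 0))                 # 25 * (1 - 0.5) along +x
  expect_equal(conservative_force(25, c(1.2, 0, 0)), c(0, 0, 0))
  expect_equal(conservative_force(25, c(1.0, 0, 0)), c(0, 0, 0))
  expect_equal(conservative_force(0, c(0.3, 0.2, 0.1)), c(0, 0, 0))
  # repulsive: pushes i away from j for any orientation
  set.seed(1)
  for (k in 1:10) {
    r <- rnorm(3) * 0.3
    f <- conservative_force(40, r)
    expect_gte(sum(f * r), 0)
  }
})

test_that("dissipative force opposes relative radial motion with the squared weight", {
  f <- dissipative_force(4.5, c(0.5, 0, 0), c(1, 0, 0))
  expect_equal(f, c(-1.125, 0, 0))               # -gamma * 0.25 * 1
  expect_equal(dissipative_force(4.5, c(0.5, 0, 0), c(0, 1, 0)), c(0, 0, 0))
  expect_equal(dissipative_force(4.5, c(1.1, 0, 0), c(1, 0, 0)), c(0, 0, 0))
})

test_that("thermostat weights satisfy omega_D = omega_R^2 on a grid", {
  r <- seq(0, 1.5, by = 0.01)
  expect_identical(omega_D(r), omega_R(r)^2)
  expect_true(all(omega_R(r[r >= 1]) == 0))
})

test_that("random force has the closed-form variance and pair symmetry", {
  # magnitude prefactor variance sigma^2 (1-r)^2 / dt, Monte Carlo
  set.seed(123)
  n <- 1e5
  xi <- runif(n, -sqrt(3), sqrt(3))
  mag <- vapply(xi, function(x) random_force(3, c(0.5, 0, 0), x, 0.04)[1],
                numeric(1))
  expect_equal(var(mag), 3^2 * 0.25 / 0.04, tolerance = 0.02)
  expect_equal(random_force(3, c(1.2, 0, 0), 1, 0.04), c(0, 0, 0))
  expect_error(random_force(3, c(0.5, 0, 0), 1, 0), "positive")
  # engine pair stream: symmetric under index swap, zero mean, unit variance
  i <- sample(0:999, 2000, replace = TRUE)
  j <- sample(0:999, 2000, replace = TRUE)
  expect_identical(pentadpd:::cpp_pair_xi(7, 3, i, j, FALSE),
                   pentadpd:::cpp_pair_xi(7, 3, j, i, FALSE))
  ii <- 0:49999
  draws <- pentadpd:::cpp_pair_xi(7, 3, ii, ii + 1L, FALSE)
  expect_lt(abs(mean(draws)), 0.02)
  expect_equal(var(draws), 1, tolerance = 0.03)
  gdraws <- pentadpd:::cpp_pair_xi(7, 3, ii, ii + 1L, TRUE)
  expect_lt(abs(mean(gdraws)), 0.02)
  expect_equal(var(gdraws), 1, tolerance = 0.03)
})

test_that("bond force is harmonic and attractive toward r_eq = 0", {
  f <- bond_force(8, c(0.5, 0, 0))
  expect_equal(f, c(-4, 0, 0))                   # magnitude C*r toward j
  expect_equal(bond_force(8, c(0, 0, 0)), c(0, 0, 0))
  # restoring toward r_eq when stretched past it
  f2 <- bond_force(8, c(1.5, 0, 0), r_eq = 1)
  expect_equal(f2, c(-4, 0, 0))
})

test_that("cell-list forces equal brute-force evaluation on the same stream", {
  fr <- small_fluid(4, seed = 10)                 # 192 beads
  im <- interaction_matrix(65, 26)
  a <- compute_forces(fr, im, ref_params, seed = 5, use_cells = TRUE)
  b <- compute_forces(fr, im, ref_params, seed = 5, use_cells = FALSE)
  expect_identical(a$n_pairs, b$n_pairs)
  expect_lt(max(abs(a$forces - b$forces)), 1e-12)
  # also with a polymer system (bonds) and under an applied tilt
  fr2 <- build_system(5, 0.3, ref_topology, seed = 11)
  fr2$tilt <- 1.3
  fr2 <- wrap_frame(fr2)
  a2 <- compute_forces(fr2, im, ref_params, seed = 6, use_cells = TRUE)
  b2 <- compute_forces(fr2, im, ref_params, seed = 6, use_cells = FALSE)
  expect_identical(a2$n_pairs, b2$n_pairs)
  expect_lt(max(abs(a2$forces - b2$forces)), 1e-12)
})

test_that("pairwise force terms obey Newton's third law globally", {
  fr <- small_fluid(5, seed = 12)
  im <- interaction_matrix(40, 80)
  f <- compute_forces(fr, im, ref_params, seed = 9)$forces
  expect_true(all(abs(colSums(f)) < 1e-10))
})

test_that("free streaming is exact when every force vanishes", {
  fr <- small_fluid(5, seed = 13)
  quiet <- dpd_params(sigma = 0)
  none <- interaction_matrix(0, 0, aAB = 0, aBS = 0, a_ii = 0)
  tr <- dpd_run(fr, none, quiet, 1, seed = 1)
  expected <- fr$positions + quiet$dt * fr$velocities
  expected <- expected - sweep(floor(sweep(expected, 2, fr$box, `/`)), 2,
                               fr$box, `*`)
  expect_equal(tr$final$positions, expected, tolerance = 1e-14)
  expect_equal(tr$final$velocities, fr$velocities)
})

test_that("bonded pair oscillates at the analytic period", {
  # two beads, bond C = 8, reduced mass 1/2: omega = sqrt(2C) = 4,
  # period 2*pi*sqrt(m/(2C)) = pi/2
  fr <- bonded_pair_frame(0.5)
  quiet <- dpd_params(sigma = 0)
  none <- interaction_matrix(0, 0, aAB = 0, aBS = 0, a_ii = 0)
  tr <- dpd_run(fr, none, quiet, 250, seed = 1, report_every = 1)
  sep <- vapply(tr$frames, function(f) {
    d <- minimum_image(f$positions[1, ] - f$positions[2, ], f$box)
    d[1]
  }, numeric(1))
  t <- vapply(tr$frames, function(f) f$step, numeric(1)) * quiet$dt
  # downward zero crossings of the signed separation, linearly interpolated
  s <- which(sep[-1] < 0 & sep[-length(sep)] >= 0)
  cross <- t[s] + (0 - sep[s]) / (sep[s + 1] - sep[s]) * quiet$dt
  expect_gte(length(cross), 2)
  period <- mean(diff(cross))
  expect_equal(period, pi / 2, tolerance = 0.01)
})

test_that("momentum is conserved to round-off over a thousand steps", {
  fr <- small_fluid(5, seed = 14)                 # 375 beads
  im <- interaction_matrix(26, 26)
  tr <- dpd_run(fr, im, ref_params, 1000, seed = 15)
  expect_true(all(abs(total_momentum(tr$final)) < 1e-8))
})

test_that("energy is conserved with the thermostat off", {
  # integrator-correctness check: at a small step the velocity-Verlet energy
  # envelope is tight (the envelope scales as dt^2 and stays bounded)
  fr <- small_fluid(5, seed = 16)
  quiet <- dpd_params(sigma = 0, dt = 0.005)
  im <- interaction_matrix(26, 26)
  e0 <- system_energy(fr, im, quiet)$total
  tr <- dpd_run(fr, im, quiet, 1000, seed = 17)
  e1 <- system_energy(tr$final, im, quiet)$total
  expect_lt(abs(e1 - e0) / abs(e0), 0.001)
})

test_that("the thermostat holds the fluid near unit temperature", {
  fr <- small_fluid(5, seed = 18)
  im <- interaction_matrix(26, 26)
  tr <- dpd_run(fr, im, ref_params, 2000, seed = 19)
  expect_equal(mean(tail(tr$temperature, 1000)), 1, tolerance = 0.05)
})

test_that("runs are deterministic and restartable", {
  fr <- small_fluid(4, seed = 20)
  im <- interaction_matrix(65, 26)
  whole <- dpd_run(fr, im, ref_params, 100, seed = 21)
  again <- dpd_run(fr, im, ref_params, 100, seed = 21)
  expect_identical(whole$final, again$final)
  half <- dpd_run(fr, im, ref_params, 50, seed = 21)
  rest <- dpd_run(half$final, im, ref_params, 50, seed = 21)
  expect_identical(whole$final$positions, rest$final$positions)
  expect_identical(whole$final$velocities, rest$final$velocities)
  # zero steps returns the input frame unchanged
  expect_identical(dpd_run(fr, im, ref_params, 0, seed = 1)$final, fr)
})

test_that("temperature measurement follows its definition", {
  fr <- solvent_system(4, seed = 22)
  expect_identical(measure_temperature(fr), 0)    # all velocities zero
  fr <- init_velocities(fr, 1, seed = 23)
  expect_equal(measure_temperature(fr), 1, tolerance = 1e-12)
  expect_identical(measure_temperature(fr),
                   sum(fr$velocities^2) / (3 * n_beads(fr) - 3))
  one <- dpd_frame(matrix(1, 1, 3), species = "S", box = 5)
  expect_error(measure_temperature(one), "two beads")
})

test_that("weak mutual repulsion keeps the melt mixed", {
  # at aAS = aCS = 26 chains stay dispersed: the largest polymer cluster
  # holds less than half the polymer beads (a box of ~34 chains keeps the
  # cluster statistics out of the few-chain finite-size regime)
  fr <- build_system(10, 0.10, ref_topology, seed = 24)
  fr <- init_velocities(fr, 1, seed = 25)
  tr <- dpd_run(fr, interaction_matrix(26, 26), ref_params, 6000, seed = 26)
  ag <- find_aggregates(tr$final)
  expect_lt(ag$clusters[[1]]$size / ag$n_polymer, 0.5)
  expect_identical(as.character(classify_morphology(tr$final)), "disordered")
})
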