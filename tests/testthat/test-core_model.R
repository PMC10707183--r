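test_that("friction is derived from the noise amplitude by fluctuation-dissipation", {
  p <- dpd_params()
  expect_identical(p$gamma, 4.5)
  # sigma^2 = 2 gamma kBT holds exactly for arbitrary sigma and kBT
  for (sigma in c(0, 1, 2.5, 3, 7)) {
    for (kBT in c(0.5, 1, 2)) {
      p <- dpd_params(sigma = sigma, kBT = kBT)
      expect_identical(p$sigma^2, 2 * p$gamma * p$kBT)
    }
  }
})

test_that("parameter constructor rejects unphysical values", {
  expect_error(dpd_params(dt = 0), "positive")
  expect_error(dpd_params(rc = -1), "positive")
  expect_error(dpd_params(density = 0), "positive")
  expect_error(dpd_params(kBT = 0), "positive")
  expect_error(dpd_params(sigma = -1), "non-negative")
})

test_that("interaction matrix reproduces the reference amplitude table", {
  a <- interaction_matrix(aAS = 65, aCS = 26, aAB = 40, aBS = 45)
  expect_identical(diag(unclass(a)), setNames(rep(25, 4), DPD_SPECIES))
  expect_identical(unname(a["A", "B"]), 40)
  expect_identical(unname(a["B", "C"]), 40)
  expect_identical(unname(a["A", "C"]), 40)
  expect_identical(unname(a["B", "S"]), 45)
  expect_identical(unname(a["A", "S"]), 65)
  expect_identical(unname(a["C", "S"]), 26)
})

test_that("interaction matrix is symmetric for arbitrary amplitudes", {
  set.seed(42)
  for (k in 1:20) {
    v <- runif(4, 26, 105)
    a <- interaction_matrix(v[1], v[2], v[3], v[4])
    expect_identical(unclass(a), t(unclass(a)))
    expect_true(all(a >= 0))
  }
})

test_that("negative amplitudes are rejected with the pair named", {
  expect_error(interaction_matrix(aAS = -1, aCS = 26), "aAS")
  expect_error(interaction_matrix(aAS = 26, aCS = 26, aBS = -3), "aBS")
})

test_that("amplitude-chi mapping matches the linear relation and inverts", {
  # a_ij = a_ii + 3.27 chi_ij at density 3
  expect_equal(a_to_chi(40), (40 - 25) / 3.27)
  expect_equal(a_to_chi(25), 0)          # identical species: chi = 0, a = 25
  expect_equal(chi_to_a(0), 25)
  set.seed(7)
  a <- runif(50, 0, 120)
  expect_equal(chi_to_a(a_to_chi(a)), a, tolerance = 1e-15)
  chi <- runif(50, -5, 30)
  expect_equal(a_to_chi(chi_to_a(chi)), chi, tolerance = 1e-15)
})

test_that("chain topology builds the palindromic pentablock sequence", {
  top <- chain_topology(3, 3, 6)
  expect_identical(top$length, 18L)
  expect_identical(paste(top$sequence, collapse = ""),
                   "CCCBBBAAAAAABBBCCC")
  expect_identical(nrow(top$bonds), 17L)

  minimal <- chain_topology(1, 1, 1)
  expect_identical(paste(minimal$sequence, collapse = ""), "CBABC")
  expect_identical(nrow(minimal$bonds), 4L)

  long_a <- chain_topology(3, 3, 18)
  expect_identical(long_a$length, 30L)
  expect_identical(sum(long_a$sequence == "A"), 18L)
})

test_that("chain topology properties hold across block lengths", {
  set.seed(11)
  for (k in 1:15) {
    n <- sample(1:9, 3, replace = TRUE)
    top <- chain_topology(n[1], n[2], n[3])
    expect_identical(top$length, 2L * n[1] + 2L * n[2] + n[3])
    expect_identical(nrow(top$bonds), top$length - 1L)
    expect_identical(top$sequence, rev(top$sequence))  # palindrome
    expect_true(all(top$bonds[, 2] == top$bonds[, 1] + 1L))
  }
  expect_error(chain_topology(0, 3, 6), "positive integer")
  expect_error(chain_topology(3, -1, 6), "positive integer")
})
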