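test_that("correction matrix matches the closed form and brute force", {
  m1 <- natural_abundance_matrix(1, isotope_spec(0.0107))
  expect_equal(unname(m1), rbind(c(0.9893, 0), c(0.0107, 1)), tolerance = 1e-12)

  expect_equal(unname(natural_abundance_matrix(5, isotope_spec(0))),
               diag(6))

  m16 <- natural_abundance_matrix(16, isotope_spec(0.0107))
  expect_equal(m16[2, 1], 16 * 0.0107 * 0.9893^15, tolerance = 1e-12)

  for (n in 2:4) {
    for (a in c(0.0107, 0.05)) {
      expect_equal(unname(natural_abundance_matrix(n, isotope_spec(a))),
                   brute_force_na_matrix(n, a), tolerance = 1e-12)
    }
  }
})

test_that("correction matrix columns are stochastic and lower-triangular", {
  for (n in c(2, 8, 16)) {
    for (a in c(0, 0.0107, 0.05)) {
      m <- natural_abundance_matrix(n, isotope_spec(a))
      expect_lt(max(abs(colSums(m) - 1)), 1e-12)
      expect_true(all(m[upper.tri(m)] == 0))
    }
  }
})

test_that("forward convolution shifts mass by the natural-abundance expectation", {
  expect_equal(
    mid_fractions(apply_natural_abundance(palmitate_mid_from_acetyl(0),
                                          isotope_spec(0.0107)))[["M+1"]],
    16 * 0.0107 * 0.9893^15, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:10) {
    f <- stats::runif(17)
    m <- mid(f / sum(f))
    a <- stats::runif(1, 0, 0.1)
    out <- apply_natural_abundance(m, isotope_spec(a))
    expect_equal(sum(mid_fractions(out)), 1, tolerance = 1e-12)
    expect_equal(mean_mass_shift(out) - mean_mass_shift(m),
                 (16 - mean_mass_shift(m)) * a, tolerance = 1e-10)
  }

  m <- mid(c(0.2, 0.3, 0.5), "toy")
  expect_equal(mid_fractions(apply_natural_abundance(m, isotope_spec(0))),
               mid_fractions(m))
})

test_that("correction inverts the forward convolution on noiseless inputs", {
  for (n in c(2, 8, 16)) {
    f <- dbinom(0:n, n, 0.3)
    truth <- mid(f, "toy", n)
    for (a in c(0, 0.0107, 0.05)) {
      spec <- isotope_spec(a)
      back <- correct_natural_abundance(apply_natural_abundance(truth, spec),
                                        spec)
      expect_lt(max(abs(mid_fractions(back) - mid_fractions(truth))), 1e-8)
    }
  }
})

test_that("correction clips deconvolution artifacts at zero and renormalizes", {
  a <- 0.05
  spec <- isotope_spec(a)
  M <- natural_abundance_matrix(2, spec)

  # perturbed forward-convolved MID: compare against the exhaustive
  # simplex-grid deconvolution
  f <- as.numeric(M %*% c(0.7, 0, 0.3))
  f[2] <- f[2] + 0.002
  f <- f / sum(f)
  out <- mid_fractions(correct_natural_abundance(mid(f, "toy", 2), spec))
  oracle <- simplex_grid_deconvolve(M, f)
  expect_lt(max(abs(unname(out) - oracle)), 1e-3)

  # a measured MID whose plain inverse has a negative component
  neg_case <- c(0.995, 0, 0.005) / sum(c(0.995, 0, 0.005))
  expect_true(any(solve(M, neg_case) < 0))
  out2 <- mid_fractions(correct_natural_abundance(mid(neg_case, "toy", 2), spec))
  expect_true(all(out2 >= 0))
  expect_equal(sum(out2), 1, tolerance = 1e-12)
  expect_equal(unname(out2[2]), 0)
})
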