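test_that("source contributions report percentages and the remainder", {
  att <- source_contributions(0.87, 0.06)
  expect_equal(att$glucose, 87)
  expect_equal(att$glutamine, 6)
  expect_equal(att$combined, 93)
  expect_true("combined_from_sum" %in% att$flags)

  att2 <- source_contributions(0.3, 0.2, p_both = 0.49)
  expect_equal(att2$unaccounted, 51)
  expect_equal(att2$additivity_gap, 0.3 + 0.2 - 0.49, tolerance = 1e-12)

  att3 <- source_contributions(0.5, 0.4, p_both = 1)
  expect_equal(att3$unaccounted, 0)

  capped <- source_contributions(0.8, 0.6)
  expect_equal(capped$combined, 100)
  expect_true("combined_capped" %in% capped$flags)

  expect_error(source_contributions(1.2, 0.1), "0, 1")
})

test_that("combined and unaccounted are exact complements", {
  set.seed(11)
  for (i in 1:20) {
    p <- sort(stats::runif(3))
    att <- source_contributions(p[1], p[2], p_both = p[3])
    expect_identical(att$combined + att$unaccounted, 100)
  }
})

test_that("acetate pool labeled fraction is spike over total", {
  expect_equal(acetate_pool_labeled_fraction(250, 285), 250 / 535)
  expect_equal(acetate_pool_labeled_fraction(250, 285), 0.467, tolerance = 1e-3)
  expect_equal(acetate_pool_labeled_fraction(0, 285), 0)
  expect_equal(acetate_pool_labeled_fraction(100, 0), 1)
  expect_error(acetate_pool_labeled_fraction(0, 0), "undefined")
  expect_error(acetate_pool_labeled_fraction(-5, 285), "non-negative")
})

test_that("full-pool extrapolation follows linear pool dilution", {
  ex <- extrapolate_full_acetate_labeling(0.55, 0.73, 0.5)
  expect_equal(ex$p_full, 0.91)
  expect_length(ex$flags, 0)

  expect_equal(extrapolate_full_acetate_labeling(0.5, 0.8, 1)$p_full, 0.8)
  expect_equal(extrapolate_full_acetate_labeling(0.6, 0.6, 0.4)$p_full, 0.6)

  # affine in p_spiked: doubling the increment doubles the attribution
  base <- 0.5
  lf <- 0.4
  d1 <- extrapolate_full_acetate_labeling(base, base + 0.1, lf)$p_full - base
  d2 <- extrapolate_full_acetate_labeling(base, base + 0.2, lf)$p_full - base
  expect_equal(d2, 2 * d1, tolerance = 1e-12)

  over <- extrapolate_full_acetate_labeling(0.5, 0.9, 0.4)
  expect_gt(over$p_full, 1)
  expect_true("overflow" %in% over$flags)
  neg <- extrapolate_full_acetate_labeling(0.7, 0.6, 0.5)
  expect_true("negative_increment" %in% neg$flags)
  expect_error(extrapolate_full_acetate_labeling(0.5, 0.7, 0), "0, 1")
})

test_that("single-tracer contributions add up on independently mixed sources", {
  # two independent acetyl sources with fractions q1, q2: dual-tracer
  # labeling is q1 + q2 when the sources do not overlap
  q1 <- 0.35
  q2 <- 0.25
  obs_both <- observed_mid(q1 + q2, 0.3)
  p_both <- fit_acetyl_labeling(obs_both, mode = "m0_excluded")$p_hat
  p1 <- fit_acetyl_labeling(observed_mid(q1, 0.3), mode = "m0_excluded")$p_hat
  p2 <- fit_acetyl_labeling(observed_mid(q2, 0.3), mode = "m0_excluded")$p_hat
  expect_lt(abs(p1 + p2 - p_both), 0.01)
})
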