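test_that("joint fit recovers p and g from a noiseless mixture", {
  obs <- observed_mid(0.30, 0.40)
  fit <- fit_acetyl_labeling(obs, mode = "joint")
  expect_equal(fit$p_hat, 0.30, tolerance = 1e-4)
  expect_equal(fit$g_hat, 0.40, tolerance = 1e-4)
  expect_lt(fit$ssr, 1e-10)
  expect_equal(fit$n_points, 9L)
})

test_that("m0-excluded fit recovers p on the conditional binomial", {
  obs <- observed_mid(0.87, 0.40)
  fit <- fit_acetyl_labeling(obs, mode = "m0_excluded")
  expect_equal(fit$p_hat, 0.87, tolerance = 1e-4)
  expect_true(is.na(fit$g_hat))
  expect_equal(fit$n_points, 8L)

  # off-grid truth: quadratic refinement beats the raw grid, and the result
  # agrees with an independent two-stage exhaustive grid search
  p_true <- 0.3456
  obs2 <- observed_mid(p_true, 0.2)
  fit2 <- fit_acetyl_labeling(obs2, mode = "m0_excluded")
  expect_equal(fit2$p_hat, p_true, tolerance = 1e-4)
  lab <- mid_fractions(obs2)[2 * (1:8) + 1]
  oracle <- grid_fit_oracle(lab / sum(lab), conditional = TRUE)
  expect_equal(fit2$p_hat, oracle, tolerance = 2e-4)
})

test_that("fit SSR never exceeds the SSR at any grid point", {
  obs <- observed_mid(0.62, 0.3)
  fit <- fit_acetyl_labeling(obs, mode = "m0_excluded")
  lab <- mid_fractions(obs)[2 * (1:8) + 1]
  target <- lab / sum(lab)
  for (p in seq(0.01, 1, 0.01)) {
    mod <- dbinom(1:8, 8, p) / (1 - (1 - p)^8)
    expect_lte(fit$ssr, sum((mod - target)^2) + 1e-15)
  }
})

test_that("fit modes agree on noiseless mixtures and are deterministic", {
  for (p in c(0.1, 0.49, 0.9)) {
    for (g in c(0, 0.5, 0.8)) {
      obs <- observed_mid(p, g)
      f1 <- fit_acetyl_labeling(obs, mode = "m0_excluded")
      f2 <- fit_acetyl_labeling(obs, mode = "joint")
      expect_lt(abs(f1$p_hat - f2$p_hat), 0.005)
    }
  }
  obs <- observed_mid(0.42, 0.35, a13C = 0.0107)
  expect_identical(fit_acetyl_labeling(obs, mode = "joint"),
                   fit_acetyl_labeling(obs, mode = "joint"))
})

test_that("fit rejects degenerate and unnormalized input", {
  pure_m0 <- mix_with_scavenged(palmitate_mid_from_acetyl(0.5), 1)
  expect_error(fit_acetyl_labeling(pure_m0, mode = "m0_excluded"),
               "no de novo signal")
  bad <- palmitate_mid_from_acetyl(0.3)
  bad$fractions <- bad$fractions * 2
  expect_error(fit_acetyl_labeling(bad), "normalized")
  expect_error(fit_acetyl_labeling(mid(c(0.5, 0.5), "toy", 1)), "16-carbon")
})

test_that("mean fit is unbiased under multinomial counting noise", {
  p_true <- 0.3
  truth <- mix_with_scavenged(palmitate_mid_from_acetyl(p_true), 0.4)
  p_hats <- vapply(1:100, function(s) {
    set.seed(s)
    counts <- as.numeric(stats::rmultinom(1, 1e5, mid_fractions(truth)))
    obs <- normalize_intensities(counts)
    fit_acetyl_labeling(obs, mode = "m0_excluded")$p_hat
  }, numeric(1))
  expect_lt(abs(mean(p_hats) - p_true), 0.01)
})

test_that("replicate aggregation computes mean and sample SD", {
  mk <- function(p) structure(list(p_hat = p, g_hat = NA_real_, ssr = 0,
                                   mode = "m0_excluded", n_points = 8L),
                              class = "acetyl_fit")
  s <- aggregate_replicates(list(mk(0.5), mk(0.5), mk(0.5)))
  expect_equal(s$mean_p, 0.5)
  expect_equal(s$sd_p, 0)
  expect_equal(s$n, 3L)

  s2 <- aggregate_replicates(list(mk(0.4), mk(0.6)))
  expect_equal(s2$mean_p, 0.5)
  expect_equal(s2$sd_p, sqrt(0.02), tolerance = 1e-10)

  s1 <- aggregate_replicates(list(mk(0.7)))
  expect_true(is.na(s1$sd_p))

  expect_error(aggregate_replicates(list()), "no fits")
  mixed <- list(mk(0.5),
                structure(list(p_hat = 0.5, g_hat = 0.2, ssr = 0,
                               mode = "joint", n_points = 9L),
                          class = "acetyl_fit"))
  expect_error(aggregate_replicates(mixed), "mixed modes")
})
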