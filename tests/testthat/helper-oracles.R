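# Independent brute-force oracles used to check the closed-form model code.

# Palmitate MID by exhaustive enumeration of the 2^8 acetyl-unit label
# configurations (each unit labeled with probability p, contributing mass 2).
brute_force_palmitate_mid <- function(p) {
  configs <- as.matrix(expand.grid(rep(list(0:1), 8)))
  prob <- apply(configs, 1, function(u) prod(ifelse(u == 1, p, 1 - p)))
  shift <- 2L * rowSums(configs)
  f <- numeric(17L)
  for (i in seq_along(prob)) f[shift[i] + 1L] <- f[shift[i] + 1L] + prob[i]
  f
}

# Natural-abundance matrix by exhaustive enumeration over the isotope state
# of every unlabeled carbon position (feasible for small n).
brute_force_na_matrix <- function(n, a) {
  m <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    free <- n - j
    if (free == 0L) {
      m[j + 1L, j + 1L] <- 1
      next
    }
    states <- as.matrix(expand.grid(rep(list(0:1), free)))
    prob <- apply(states, 1, function(u) prod(ifelse(u == 1, a, 1 - a)))
    extra <- rowSums(states)
    for (i in seq_along(prob))
      m[j + 1L + extra[i], j + 1L] <- m[j + 1L + extra[i], j + 1L] + prob[i]
  }
  m
}

# Exhaustive grid search on the 2-simplex for the sum-constrained
# non-negative deconvolution of a 2-carbon compound.
simplex_grid_deconvolve <- function(M, measured, step = 5e-4) {
  grid <- seq(0, 1, step)
  best <- NULL
  best_ssr <- Inf
  for (x0 in grid) {
    x2 <- seq(0, 1 - x0, step)
    x1 <- 1 - x0 - x2
    resid <- M %*% rbind(x0, x1, x2) - measured
    ssr <- colSums(resid^2)
    i <- which.min(ssr)
    if (ssr[i] < best_ssr) {
      best_ssr <- ssr[i]
      best <- c(x0, x1[i], x2[i])
    }
  }
  best
}

# Independent two-stage exhaustive grid search for the SSR fit (coarse scan
# then a fine scan around the coarse minimum), kept separate from the
# package's optimizer.
grid_fit_oracle <- function(target, conditional, fine_step = 1e-4) {
  ssr_of <- if (conditional) {
    function(p) {
      mod <- dbinom(1:8, 8, p) / (1 - (1 - p)^8)
      sum((mod - target)^2)
    }
  } else {
    function(p) sum((dbinom(0:8, 8, p) - target)^2)
  }
  coarse <- seq(0.001, 1, 0.001)
  s <- vapply(coarse, ssr_of, numeric(1))
  p0 <- coarse[which.min(s)]
  fine <- seq(max(fine_step, p0 - 0.002), min(1, p0 + 0.002), fine_step)
  s2 <- vapply(fine, ssr_of, numeric(1))
  fine[which.min(s2)]
}

# Build an observed palmitate MID for truth (p, g), optionally pushed
# through the natural-abundance forward/backward round trip.
observed_mid <- function(p, g = 0, a13C = 0, corrected = TRUE) {
  m <- mix_with_scavenged(palmitate_mid_from_acetyl(p), g)
  if (a13C > 0) {
    spec <- isotope_spec(a13C)
    m <- apply_natural_abundance(m, spec)
    if (corrected) m <- correct_natural_abundance(m, spec)
  }
  m
}
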