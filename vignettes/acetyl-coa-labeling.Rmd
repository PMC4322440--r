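---
title: "Inferring cytosolic acetyl-CoA labeling from palmitate isotopologues"
author: "acetylTrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cytosolic acetyl-CoA labeling from palmitate isotopologues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetylTrace)
```

## The model

Palmitate (C16:0) is assembled by fatty acid synthase from 8 two-carbon
acetyl units drawn from the cytosolic acetyl-CoA pool. In a U-^13^C tracer
experiment the tracer donates intact ^13^C~2~ acetyl units, so if a
fraction $p$ of the cytosolic acetyl-CoA pool is ^13^C~2~-labeled and the
units incorporated into one molecule are drawn independently from a
well-mixed pool at isotopic steady state, the number of labeled units per
de novo palmitate molecule is Binomial$(8, p)$. The fractional abundance
of the M+2k isotopologue of de novo palmitate is therefore

$$ f_{2k} = \binom{8}{k} p^k (1-p)^{8-k}, \qquad k = 0,\dots,8, $$

with no mass at odd shifts. Cells additionally scavenge pre-formed,
unlabeled fatty acids from serum; this material appears entirely at M+0,
so the cellular palmitate pool is the mixture

$$ f^{\text{pool}} = g\,\delta_{M+0} + (1-g)\,f^{\text{de novo}}, $$

with $g$ the scavenged fraction. `palmitate_mid_from_acetyl()` and
`mix_with_scavenged()` implement these two maps; both are checked in the
test suite against exhaustive enumeration of the $2^8$ unit-label
configurations.

Assumptions worth keeping in mind: a single well-mixed cytosolic
acetyl-CoA pool (no channeling), isotopic steady state (the cells are in
labeled medium long enough for palmitate turnover to equilibrate), intact
transfer of 2-carbon units (no M+1 acetyl units), and palmitate only —
elongation and desaturation products are out of scope.

## Natural-abundance correction

About 1.07% of natural carbon is ^13^C, so even tracer-unlabeled
molecules show M+1/M+2 signal. For a 16-carbon compound with $j$
tracer-labeled carbons, the remaining $16-j$ carbons each carry a natural
^13^C independently, giving the lower-triangular, column-stochastic
convolution matrix built by `natural_abundance_matrix()`. The forward map
(`apply_natural_abundance()`) is what the instrument sees; the analysis
inverts it with `correct_natural_abundance()`.

The inversion is posed as non-negative least squares
(`pracma::lsqnonneg`) rather than a direct triangular solve: on noisy
data a plain inverse can produce small negative fractions, whereas the
active-set solution clips them at zero; the result is then renormalized
to the simplex. On noiseless inputs the round trip
correct(apply(x)) = x holds to better than 1e-8, which the tests verify
for 2-, 8- and 16-carbon compounds.

Only carbon isotopes are corrected. Palmitate is measured as the
carboxylate anion in negative mode, where ^2^H/^18^O contributions are
negligible at the resolving power typical of fatty-acid LC-MS. Tracer
isotopic purity is assumed to be 100%; if a purity correction were
needed it would enter as one more convolution of the same form. The
default `a13C = 0.0107` is the IUPAC representative natural abundance and
can be overridden everywhere an `isotope_spec()` is accepted.

## Fitting the acetyl labeling fraction

`fit_acetyl_labeling()` estimates $p$ by minimizing the sum of squared
residuals (SSR) between the model and the corrected MID. Two policies
handle the M+0 peak, which conflates unlabeled de novo synthesis with
scavenging:

* **`m0_excluded`** (default): M+0 is dropped and the labeled even
  shifts M+2…M+16 renormalized; the model is the binomial conditioned on
  at least one labeled unit,
  $\binom{8}{k}p^k(1-p)^{8-k} / (1-(1-p)^8)$. This treats the M+0 peak as
  uninformative about $p$, which is exactly right when scavenging
  dominates it.
* **`joint`**: the full even-shift vector is fitted by the scavenging
  mixture, estimating $(p, g)$ together. On noiseless mixtures the two
  modes agree within 0.005 for $g \le 0.8$.

Only even mass shifts enter the residual: the model has no mass at odd
shifts, and any small odd-shift residue left by the correction is noise.
Residuals are unweighted.

The optimizer is a deterministic grid scan over $p$ (step 0.001; in
joint mode the optimal $g$ at each grid $p$ is available in closed form
because the model is affine in $g$) followed by parabolic refinement
through the grid minimum and its neighbours. A fixed grid was chosen over
a generic nonlinear solver deliberately: the 1-D problem is cheap, the
scan cannot be trapped by a bad start, ties are broken reproducibly
toward smaller $p$, and identical inputs give bit-identical results —
which the byte-determinism of the whole pipeline relies on. The parabolic
step recovers off-grid optima to ~1e-4 on noiseless data, far below the
replicate-to-replicate spread of real measurements.

Degenerate inputs are rejected rather than guessed at: an all-M+0
observation has no de novo signal and errors in `m0_excluded` mode, and
unnormalized fraction vectors are refused.

## Source attribution

With single-tracer experiments (U-^13^C-glucose, U-^13^C-glutamine) and
the dual-tracer experiment, `source_contributions()` converts labeling
fractions into percent contributions; the dual-tracer value defines what
the two substrates collectively account for and its complement is the
unaccounted remainder. The sum of single-tracer values is reported as an
additivity diagnostic, not enforced — exchange fluxes (e.g. between
α-ketoglutarate and citrate) can make single-tracer labeling
non-additive.

Two further calculations bound and attribute the unaccounted source:

* `expected_mid_from_oxidation()` computes the palmitate labeling that
  *would* appear if β-oxidation of a partially labeled palmitate pool fed
  acetyl-CoA: with a fraction $f_{lab}$ of the pool fully labeled, a
  share $X$ of the unidentified source from oxidation, and an
  unidentified fraction $f_{unid}$, the effective acetyl labeling is
  $p_{\text{eff}} = f_{unid} \cdot X \cdot f_{lab}$ and the expected M+2
  fraction of de novo palmitate is $8\,p_{\text{eff}}(1-p_{\text{eff}})^7$.
  The model is single-pass — newly made labeled palmitate is not itself
  re-oxidized — because the expectation is meant as a one-step bound, and
  iterating it to steady state would only raise the expected signal.
  The default output is the de novo pattern, undiluted by the scavenged
  pool: with $f_{lab}=0.20$, $X=0.13$, $f_{unid}=0.51$ this gives an M+2
  fraction of ~9.7%, i.e. ~10%; diluting into the total pool would halve
  it or more, and the `scavenged_fraction` argument makes that convention
  computable too.
* `extrapolate_full_acetate_labeling()` scales an observed
  acetate-spike response to a fully labeled acetate pool under linear
  pool dilution: if only a fraction $\ell$ of the acetate pool was
  labeled, the full-pool labeling is
  $p_{\text{base}} + (p_{\text{spike}} - p_{\text{base}})/\ell$. For a
  250 µM spike into medium with ~285 µM endogenous acetate, $\ell$ is
  250/535 ≈ 0.467 by `acetate_pool_labeled_fraction()`; the labeled and
  unlabeled fractions are then roughly equal, and $\ell = 0.5$ is the
  convention used when quoting round numbers (0.55 → 0.73 extrapolates
  to 0.91). Results above 1 are returned unclamped with an `"overflow"`
  flag, since clamping would hide a violation of the linear-dilution
  assumption.

## The synthetic-data generator

`simulate_study()` stands in for LC-MS acquisition so the whole pipeline
is testable without instrument data. Its default design mirrors a
two-oxygen-level experiment: normoxia with glucose / glutamine / both
tracers, and hypoxia (1% O₂) with the same three sets, the dual tracer
plus a U-^13^C-acetate spike at 0/50/250/500 µM, and a 20 µM
U-^13^C-palmitate tracer — 11 conditions, 3 replicates each. The default
true values follow the trends such experiments show: glucose dominating
in normoxia ($p$ = 0.87 alone, 0.93 combined), a collapse to ~0.49
combined in hypoxia, acetate restoring labeling to 0.86 at the 500 µM
spike, a near-zero $p$ for the palmitate-tracer arm, and a larger
scavenged fraction under hypoxia (0.6 vs 0.4) reflecting increased
fatty-acid scavenging.

Noise is multinomial ion counting at 10^5 ions per sample — the simplest
model consistent with fractional MS data; a Gaussian-on-fractions option
exists for robustness checks. Randomness comes from one seeded generator
with per-sample substreams derived from (seed, condition index,
replicate index), so any sample can be regenerated independently and the
same seed always yields byte-identical CSV output.

What the generator does **not** emulate: chromatographic drift and peak
integration error, detector saturation, isotopic impurity of tracers,
elongation products contaminating the palmitate peak, and
between-replicate biological variation in $p$ itself (replicates differ
only by counting noise). Passing the recovery tests therefore shows the
statistical machinery is correct and well-calibrated, not that every
real-data artifact is handled.

## Numerical choices and problem sizes

Tolerances used in the tests reflect the arithmetic, not the biology:
1e-12 for closed-form identities (column sums, binomial enumeration),
1e-8 for the NNLS round trip, 1e-3/1e-4 for optimizer recovery. The
recovery studies run at 10^5 ions × 3 replicates × 20 seeds and the
convergence check at 10^7 ions, sizes at which multinomial standard
errors (~1e-3 per fraction) are comfortably below the asserted recovery
bounds while the suite stays fast.

## Limitations

The binomial model ignores kinetic (pre-steady-state) labeling, M+1
acetyl units, positional isotopomers and polymer-length products other
than palmitate. Labeling-based attribution measures *labeling*, not net
flux: exchange reactions can inflate a substrate's apparent contribution,
and the acetate extrapolation assumes source fluxes independent of the
labeling state. The unaccounted remainder is a lumped term — anything
that dilutes acetyl-CoA labeling (unlabeled amino acids, protein
de-acetylation, endogenous acetate) lands in it.
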