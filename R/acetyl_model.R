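#' Binomial palmitate MID from acetyl-CoA labeling
#'
#' Palmitate is assembled by fatty acid synthase from 8 two-carbon acetyl
#' units drawn from the cytosolic acetyl-CoA pool. If a fraction `p` of that
#' pool is 13C2-labeled and units are drawn independently, the number of
#' labeled units per de novo palmitate molecule is Binomial(8, p), so the
#' mass shift is 2k with probability `choose(8, k) p^k (1-p)^(8-k)`;
#' all odd mass shifts carry zero mass.
#'
#' @param p Fraction of cytosolic acetyl-CoA that is 13C2-labeled, in
#'   `[0, 1]`.
#' @return A palmitate `"mid"` (17 entries, M+0 ... M+16).
#' @examples
#' mid_fractions(palmitate_mid_from_acetyl(0.5))[["M+8"]]  # 70/256
#' @export
palmitate_mid_from_acetyl <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("`p` must be a single value in [0, 1]", call. = FALSE)
  f <- numeric(17L)
  f[2L * (0:8) + 1L] <- stats::dbinom(0:8, size = 8, prob = p)
  mid(f, compound_label = "palmitate", n_carbons = 16L)
}

#' Mix a de novo MID with scavenged unlabeled palmitate
#'
#' Cells also take up pre-formed, unlabeled palmitate from serum
#' (scavenging), which appears entirely at M+0. The cellular pool is the
#' mixture `g * (pure M+0) + (1 - g) * de_novo`.
#'
#' @param de_novo A `"mid"` object (de novo synthesized material).
#' @param g Scavenged fraction of the pool, in `[0, 1]`.
#' @return A `"mid"` object for the total cellular pool.
#' @export
mix_with_scavenged <- function(de_novo, g) {
  stopifnot(is_mid(de_novo))
  g <- as.numeric(g)
  if (length(g) != 1L || is.na(g) || g < 0 || g > 1)
    stop("`g` must be a single value in [0, 1]", call. = FALSE)
  m0 <- numeric(de_novo$n_carbons + 1L)
  m0[1L] <- 1
  mid(g * m0 + (1 - g) * de_novo$fractions,
      compound_label = de_novo$compound_label,
      n_carbons = de_novo$n_carbons)
}

#' Oxidation scenario for expected palmitate relabeling
#'
#' Parameters of the one-step expectation used to bound the contribution of
#' palmitate oxidation to acetyl-CoA: a fraction `f_labeled_palmitate` of
#' the cellular palmitate pool is fully 13C-labeled (from a U-13C-palmitate
#' tracer); beta-oxidation of that pool would feed 13C2-acetyl units back
#' into acetyl-CoA; `x_oxidation` is the share of the unidentified
#' acetyl-CoA source attributed to palmitate oxidation and `f_unidentified`
#' the fraction of acetyl-CoA not derived from glucose or glutamine.
#'
#' @param f_labeled_palmitate Fraction of the palmitate pool fully labeled,
#'   in `[0, 1]`.
#' @param x_oxidation Share of the unidentified source coming from
#'   palmitate oxidation, in `[0, 1]`.
#' @param f_unidentified Fraction of acetyl-CoA not from glucose/glutamine,
#'   in `[0, 1]`.
#' @return An object of class `"oxidation_scenario"`.
#' @export
oxidation_scenario <- function(f_labeled_palmitate, x_oxidation, f_unidentified) {
  vals <- c(f_labeled_palmitate = as.numeric(f_labeled_palmitate),
            x_oxidation = as.numeric(x_oxidation),
            f_unidentified = as.numeric(f_unidentified))
  if (anyNA(vals) || any(vals < 0) || any(vals > 1))
    stop("all oxidation-scenario fractions must lie in [0, 1]", call. = FALSE)
  structure(as.list(vals), class = "oxidation_scenario")
}

#' Expected palmitate MID from palmitate oxidation recycling
#'
#' If palmitate oxidation supplied a share `x_oxidation` of the
#' unidentified acetyl-CoA source, the labeled palmitate pool would relabel
#' acetyl-CoA at an effective fraction
#' `p_eff = f_unidentified * x_oxidation * f_labeled_palmitate`, and newly
#' synthesized palmitate would show the corresponding binomial pattern —
#' most visibly an M+2 peak of `8 p_eff (1 - p_eff)^7`. The model is
#' single-pass: newly made labeled palmitate is not itself re-oxidized.
#'
#' @param scenario An [oxidation_scenario()].
#' @param scavenged_fraction Optional scavenged-pool fraction `g`; the
#'   default 0 returns the expectation for de novo synthesized palmitate
#'   only (undiluted). Supplying `g > 0` dilutes the pattern into the total
#'   cellular pool via [mix_with_scavenged()].
#' @return A palmitate `"mid"`.
#' @examples
#' sc <- oxidation_scenario(0.20, 0.13, 0.51)
#' mid_fractions(expected_mid_from_oxidation(sc))[["M+2"]]  # ~0.097
#' @export
expected_mid_from_oxidation <- function(scenario, scavenged_fraction = 0) {
  stopifnot(inherits(scenario, "oxidation_scenario"))
  p_eff <- scenario$f_unidentified * scenario$x_oxidation *
    scenario$f_labeled_palmitate
  out <- palmitate_mid_from_acetyl(p_eff)
  if (scavenged_fraction > 0) out <- mix_with_scavenged(out, scavenged_fraction)
  out
}
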