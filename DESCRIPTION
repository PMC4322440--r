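Package: acetylTrace
Title: Cytosolic Acetyl-CoA 13C Labeling Inferred from Palmitate Isotopologues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the fractional 13C2-labeling of cytosolic acetyl-CoA from
    palmitate mass-isotopologue distributions measured in 13C tracer
    experiments. Implements natural 13C-abundance convolution and
    non-negative least-squares correction of isotopologue spectra, an
    8-acetyl-unit binomial forward model of palmitate labeling with a
    scavenged-pool mixture, sum-of-squared-residuals fitting of the acetyl
    labeling fraction, source attribution of acetyl-CoA to glucose,
    glutamine and acetate with an unaccounted remainder, an expected-labeling
    calculation for palmitate oxidation recycling, extrapolation of acetate
    contributions to a fully labeled acetate pool, and a seeded multinomial
    simulator of isotopologue ion-count tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
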