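Package: potmorph
Title: Outline-Based Morphometrics of Wheel-Thrown Vessel Morphogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the shape development of wheel-thrown ceramic vessels
    from digitized half-profiles. Closed outlines are described by
    size-normalized elliptical Fourier coefficients, embedded in a pooled
    principal-component shape space, and compared across potters and
    communities of practice via cross-projection subspace similarity,
    nested permutation MANOVA on alternative-Gower distances, stage-wise
    multivariate dispersion, UPGMA dendrograms, and hierarchical
    generalized additive trajectory models. Includes a seeded synthetic
    morphogenesis generator so the full pipeline is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    mgcv,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
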