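Package: pbsrobust
Title: Setup-Error Robustness Analysis for Scanned Ion-Beam Treatment Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the dosimetric robustness of scanned carbon-ion and
    proton treatment plans against rigid patient setup errors. Provides seeded
    generators for heterogeneous skull-base-like phantoms with anisotropic
    CTV-to-PTV margin expansion, a simplified pencil-beam dose engine based on
    water-equivalent path-length ray tracing with parameterized Bragg curves and
    energy-dependent Gaussian lateral profiles, inverse spot-weight optimization
    under unconstrained, single-field and multiple-field modulation with
    organ-at-risk maximum-dose constraints, dose-volume-histogram metrics (V95,
    homogeneity and conformity indices, near-maximum doses), complete enumeration
    of rigid setup-shift sets with dose recomputation at frozen spot weights,
    heterogeneity-based beam-direction scoring for robust beam-setup selection,
    and population-level robustness statistics including the exact paired sign
    test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
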