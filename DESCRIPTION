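Package: porescale
Title: Finite-Size Hydropathic Scaling Analysis of Ion-Channel Pores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles the atomic environment around the pore axis of a
    protonated ion-channel structure. Computes pore-axis geometry (pore
    radius, nearest-atom distance, outer-surface radius), samples atoms in
    nested spheres around pore points, fits sigmoid atom-packing models
    (logistic, Gompertz, modified Gompertz, Richards) with AIC selection,
    bootstrap confidence intervals and inflection-point analysis, and
    quantifies the cumulative hydropathic dipole field, hydropathic
    imbalance and atom-packing energy across scales, including bi-phasic
    power-law (scale-invariance) analysis with pre- and post-inflection
    critical exponents. Ships a synthetic-structure generator so every
    stage is testable without external downloads, plus a small command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
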