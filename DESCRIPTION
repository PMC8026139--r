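Package: anthoblue
Title: Spectral, Colorimetric and Mass-Spectrometric Analytics for Cyan
    Anthocyanin Colorants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising anthocyanin-based blue colorants and
    their enzymatic enrichment: UV-visible spectral metrics (lambda-max,
    bathochromic shift, violet contribution), absorbance-based CIELAB
    colorimetry with hue-angle matching, flavylium multistate hydration
    equilibria and apparent-pK'h fitting, first-order colour-loss kinetics,
    exact-mass molecular-formula algebra with metal-complex stoichiometry
    assignment from ESI-TOF-MS peaks, HPLC peak detection and enzymatic
    conversion metrics, esterase-screen sequence-identity statistics, and a
    seeded synthetic-fixture generator that emulates all of these inputs.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
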