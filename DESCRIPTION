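Package: peptadd
Title: Additive Free-Energy Optimization of Peptide Affinity Reagents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for affinity maturation of short peptide ligands by
    thermodynamic additivity of point variations. Enumerates point-variant
    libraries from a lead sequence, converts binding measurements (surface
    plasmon resonance screens, equilibrium isotherms, 1:1 kinetics,
    fluorescence anisotropy titrations) into standard binding free energies,
    combines per-position free-energy contributions additively with
    quadrature error propagation to predict multi-variant affinities, plans
    variant combinations with a nearest-neighbour adjacency rule, and
    quantifies deviation from additivity. Includes a binding-assay simulator
    driven by a ground-truth per-position energy landscape with optional
    adjacent-position coupling.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
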