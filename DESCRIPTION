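Package: fragdd
Title: Shape of Density Dependence and Population Limitation in
    Fragmented Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking forest-fragmentation-mediated shapes of
    density-dependent fecundity to breeding population trends in
    territorial migratory songbirds. Implements a site-dependent habitat
    selection model that fills forest patches largest-first to a
    patch-size-dependent saturation density, generating fecundity-density
    curves per landscape; fits the generalized Beverton-Holt function and
    derives its abruptness, inflection and tipping point, and the realized
    strength of density dependence b'; fits the Sutherland two-season
    shift-decomposition model to diagnose breeding versus non-breeding
    limitation; and tests for buffer or inverse buffer effects from
    abundance-index trends and landscape quality (core-to-total forest
    ratio). A synthetic-data module generates patch-size mosaics along a
    fragmentation gradient, noisy vital-rate observations, and trend
    scenarios so the full pipeline can be exercised end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
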