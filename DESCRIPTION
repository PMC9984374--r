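Package: pammspec
Title: Ensemble-Weighted Infrared Spectra from Probabilistic Conformer Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs finite-temperature infrared spectra of flexible
    peptides as population-weighted averages over representative conformers.
    Provides SOAP-style invariant structural descriptors, PAMM-style
    density-based clustering (farthest point sampling, localized-Silverman
    kernel density estimation, quick-shift mode seeking, adjacency-restricted
    Ward merging), continuous hydrogen-bond counting statistics with
    free-energy surfaces, Gaussian line broadening with weighted ensemble
    averaging, hierarchical-merge spectrum series, and Pendry reliability
    factors for spectral comparison. Includes a synthetic conformer-ensemble
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
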