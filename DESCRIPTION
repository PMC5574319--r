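Package: oplsmet
Title: OPLS-DA Metabolomics with SUS-Plot Comparison and Correlation
    Networks
Version: 0.1.0
Authors@R:
    person("Avery", "Lindqvist", email = "avery.lindqvist@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for 1H-NMR metabolomics chemometrics:
    simulation of multi-group metabolite tables and binned spectra with
    known ground truth, spectral preprocessing (region exclusion, total-area
    normalization, centering/unit-variance/Pareto scaling), two-class
    OPLS-DA with cross-validated Q2 and permutation validation, S-plot and
    VIP marker extraction, Benjamini-Hochberg adjusted fold changes,
    SUS-plot shared/unique classification of two treatment models against a
    common reference, and thresholded Pearson correlation networks with
    structural-similarity edges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
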