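Package: mcindex
Title: Monochromaticity Statistics for Quantitative Genetic Interaction
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the tendency of clusters of quantitative genetic
    interactions (within protein complexes, or between pairs of complexes)
    to carry a single sign, a property known as monochromaticity. Implements
    the monochromatic index (MCI), an interaction-count-weighted purity
    statistic, and its strength-based analogue (sMCI), together with a
    permutation null model yielding empirical p-values and Z-scores, an
    exact binomial test for counts of monochromatic complexes, and the
    background-adjusted monochromatic purity (MP) score for comparison.
    Includes readers for SGA-style interaction tables and gene-set
    catalogs (GMT or two-column), significance-cutoff filters, complex-level
    network export (SIF, GraphML, JSON), and a synthetic-data generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
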