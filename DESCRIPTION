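Package: phenonet
Title: Partial-Correlation Networks of Quantitative Disease Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers Gaussian graphical model networks over quantitative
    disease-related phenotypes using shrinkage partial correlations, tests
    edge significance against the Hotelling null distribution, compares
    networks between subject groups with permutation tests for differential
    connectivity, classifies edges by concordance between groups, and orients
    edges via log-ratios of standardized partial variances. Includes seeded
    multivariate-normal cohort simulators with known partial-correlation
    structure, network summary statistics (density, degree ranking,
    transitive-node shortest-path analysis), and edge-table/GraphML/DOT
    export.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
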