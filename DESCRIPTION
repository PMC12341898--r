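Package: gith
Title: Genetic Intra-Tumor Heterogeneity Before and After Treatment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stochastic birth-death modelling of genetic intra-tumor
    heterogeneity across treatment. Provides an exact Gillespie simulator
    that records the full cell lineage tree with Poisson mutation
    accumulation and resistance mutations, extraction of summary
    statistics from trees (site frequency spectrum, total and single-cell
    mutational burden, divisional and resistant clone size distributions),
    analytic expectations for these statistics at detection and under
    shrinking, constant or growing disease, Luria-Delbruck type clone size
    and largest-clone theory including a numerically evaluated Landau
    distribution, and a discrete power-law maximum likelihood estimator
    with a homogeneity test for treatment response.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp, jsonlite, ape
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, StatisticalMethod, SomaticMutation, Phylogenetics
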