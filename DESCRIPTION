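Package: admixrep
Title: Replicated Admixture Analysis for Ancestry-Informative SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing replicated admixture events between diverged
    lineages genotyped at ancestry-informative SNPs, built around introduced
    admixed mussel populations confined to port habitats. Provides a forward
    simulator of hybrid swarms with recombination junctions, genotype QC
    filters, supervised maximum-likelihood ancestry estimation, hybrid-class
    posteriors, Weir-Cockerham FST and Monte-Carlo Hardy-Weinberg tests,
    per-locus distortions of observed allele frequencies from ancestry-weighted
    expectations with permutation-tested cross-event correlations and
    dependent p-value combination (Empirical Brown's Method), geographic cline
    fitting on least-cost marine distances, two-point F2 linkage-map
    construction, and admixture dating from the decay of admixture linkage
    disequilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
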