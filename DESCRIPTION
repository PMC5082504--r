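Package: mprqtl
Title: QTL Mapping in Multiparent Recombinant Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci in multiparent
    advanced-intercross recombinant inbred line (RIL) panels such as the
    Drosophila Synthetic Population Resource. Implements founder-haplotype
    genome scans on genotype probabilities with permutation genomewide
    significance, local interval refinement (Bayesian credible and LOD-drop
    intervals), mixed-model variance decomposition with repeatability and
    RIL BLUPs, two-class partitioning of founder alleles, Bayesian
    estimation of QTL effect sizes and the proportion of genetic variance
    explained, pairwise epistasis tests and modifier-interaction genome
    scans. A pedigree-based panel simulator generates synthetic RIL panels
    with planted QTL so every stage of the pipeline can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
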