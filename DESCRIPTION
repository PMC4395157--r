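Package: aimpanel
Title: Ancestry-Informative SNP Panel Design and Introgression Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Designs reduced panels of ancestry-informative SNP markers
    (AIMs) for discriminating the M and C evolutionary lineages of the
    honey bee (Apis mellifera) and for estimating C-lineage introgression
    into the dark honey bee A. m. mellifera.  Implements five per-locus
    informativeness statistics (haploid Weir-Cockerham theta, a Bayesian
    F_ST outlier model fitted by MCMC, the allele-frequency differential
    Delta, Rosenberg's informativeness for assignment I_n, and a
    PCA-loadings score), a two-step score aggregation with 0-1
    standardization and global ranking, genetic-map (cM) pruning of linked
    markers, nested panel construction, a calibrated Balding-Nichols
    baseline and hybrid/pooled mixture simulators, supervised and
    unsupervised (EM) admixture estimation with cross-validation choice of
    K, and panel validation metrics (rank correlations, top-N overlap,
    precision and assignment accuracy, rank-sum tests).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
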