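# aimpanel

Design and validation of reduced **ancestry-informative marker (AIM)**
SNP panels for the honey bee: discriminating the western-European M
lineage (*Apis mellifera mellifera*, the dark honey bee) from the
eastern-European C lineage (*A. m. ligustica*, *A. m. carnica*), and
estimating per-individual C-lineage introgression. It is aimed at
conservation genetics workflows in which thousands of candidate SNPs
from a dense assay must be distilled into panels of 48–384 markers that
can be genotyped cheaply at scale, without losing accuracy in ancestry
assignment.

## What it computes

**Per-locus informativeness** (on haploid drone genotypes, under four
groupings of the training populations — M vs C pooled, M vs ligustica,
M vs carnica, and all three separately):

- Weir–Cockerham θ, the variance-components F<sub>ST</sub> estimator
  adapted to haploid samples (pairwise; mean over pairs for >2
  populations),
- the allele-frequency differential Δ = |p<sub>i</sub> − p<sub>j</sub>|,
- Rosenberg's informativeness for assignment
  I<sub>n</sub> = Σ<sub>alleles</sub>(−p̄ ln p̄ + (1/K) Σ<sub>i</sub> p<sub>i</sub> ln p<sub>i</sub>),
- a PCA score: squared loadings summed over the leading 8 components,
- a Bayesian F<sub>ST</sub> outlier score from a hierarchical
  beta-binomial model with logistic decomposition
  F<sub>ij</sub> = logit<sup>−1</sup>(α<sub>i</sub> + β<sub>j</sub>),
  fitted by a pilot-tuned random-walk Metropolis sampler (Rcpp).

**Panel construction**: scores averaged across training datasets per
method, min–max standardized to 0–1, averaged across methods into a
global score; loci ranked, pruned at < 1 cM from higher-ranking
markers on the same chromosome, and cut into nested panels of
48/96/144/192/384.

**Validation**: a calibrated Balding–Nichols synthetic baseline
(median training θ in 0.65–0.78), simulated holdout and mixture sets,
supervised (two-source maximum likelihood) and unsupervised (K-way EM,
with cross-validation choice of K) admixture estimation, and precision
/accuracy metrics: correlation and regression of panel vs full-set
estimates, SD of their differences, per-individual assignment accuracy
100·(1 − |q̂<sub>panel</sub> − q̂<sub>full</sub>|), rank correlations
between selection methods, top-N overlaps, and Mann–Whitney
comparisons.

## Worked example

```r
library(aimpanel)
cfg <- pipeline_config(out_dir = tempfile("aimpanel_demo"),
                       n_loci = 600, panel_sizes = c(24, 48, 96), seed = 7)
res <- run_pipeline(cfg)
#> calibrated baseline divergence f = 0.775 (median theta 0.708)
#> monomorphic filter: 597 / 600 loci retained
#> ranking: 511 retained loci; panels 24/48/96
#> pipeline complete: /tmp/.../aimpanel_demo...

head(res$ranking[, c("locus", "global", "rank", "retained")], 5)
#>     locus    global rank retained
#> 1 snp0400 0.8060915    1     TRUE
#> 2 snp0024 0.8056746    2     TRUE
#> 3 snp0088 0.8054566    3     TRUE
#> 4 snp0092 0.8054391    4     TRUE
#> 5 snp0435 0.8053283    5     TRUE

res$evaluation$holdout[, c("panel", "correlation", "sd_diff", "mean_accuracy")]
#>      panel correlation sd_diff mean_accuracy
#> 1 panel_24      0.9971 0.03368         98.16
#> 2 panel_48      0.9985 0.02373         98.57
#> 3 panel_96      0.9994 0.01501         99.17
```

The pipeline calibrated the synthetic baseline so the M/C training
samples show a median per-locus θ of 0.708, scored the 597 polymorphic
loci with all five methods on the four training datasets, ranked and
pruned them on the genetic map, and cut three nested panels. On the
113-individual simulated holdout, even the 24-marker panel's admixture
estimates correlate at r = 0.997 with the full 597-locus estimates, and
mean per-individual assignment accuracy stays above 98%; precision
improves steadily with panel size. All artifacts (scores, ranking,
panel locus lists, Q estimates, evaluation tables, run manifest) are
written under `cfg$out_dir`.

Real data come in via `read_genotypes()` (genotype TSV or a haploid
PLINK-style ped/map dialect), `read_popmap()` and `read_genetic_map()`;
a thin command-line front end is installed at
`inst/scripts/aimpanel` (`aimpanel run …`, `aimpanel synth …`).

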