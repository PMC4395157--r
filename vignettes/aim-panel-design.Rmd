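---
title: "Designing ancestry-informative SNP panels for honey bee introgression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing ancestry-informative SNP panels for honey bee introgression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The dark honey bee, *Apis mellifera mellifera* (western-European M
lineage), is threatened across its native range by introgression from the
two commercially favoured eastern-European C-lineage subspecies,
*A. m. ligustica* and *A. m. carnica*. Conservation programs need a
cheap, high-throughput way to (i) verify that a colony is of M-lineage
origin and (ii) estimate the proportion of C-lineage ancestry in its
genome. Genotyping a few dozen to a few hundred well-chosen
ancestry-informative markers (AIMs) — SNPs with large allele-frequency
differences between the source gene pools — achieves both at a small
fraction of the cost of a dense assay.

`aimpanel` implements the complete design-and-validation workflow:
per-locus informativeness scoring under several population groupings,
aggregation into a global ranking, genetic-map pruning of redundant
linked markers, nested panel construction, and simulation-based
validation of the panels' admixture estimates. Haploid males (drones)
carry one allele per locus, which keeps every likelihood in the package
haploid.

## Informativeness statistics

Five per-locus statistics are computed on training samples, under four
groupings of the reference populations (M vs C pooled; M vs ligustica;
M vs carnica; M vs ligustica vs carnica as three populations), giving up
to 20 scores per locus:

* **Weir–Cockerham theta** (`wc_fst()`): the variance-components
  estimator of \(F_{ST}\), adapted to haploid samples by dropping the
  within-individual components (each drone contributes a single allele
  draw). Negative estimates are retained — truncation would distort the
  ranking and the later 0–1 standardization absorbs scale. With more
  than two populations the unweighted mean over pairwise estimates is
  used, the same reduction the allele-frequency differential uses.
* **Delta** (`delta_diff()`): the absolute allele-frequency differential
  \(|p_i - p_j|\), averaged over population pairs.
* **Rosenberg's informativeness for assignment** \(I_n\)
  (`informativeness_in()`): the expected information one randomly drawn
  allele provides about its source population under a uniform prior,
  \(\sum_{\text{alleles}} (-\bar p \ln \bar p + \frac{1}{K}\sum_i p_i
  \ln p_i)\) with \(0 \ln 0 = 0\). Its minimum is 0 (identical
  frequencies) and its maximum is \(\ln K\) (no shared alleles); the
  implementation follows the formula and does not rescale to 1.
* **PCA loadings score** (`pca_informativeness()`): squared loadings
  summed over the leading eight principal components of the
  mean-imputed, column-centred (not variance-scaled) call matrix. Eight
  components is a parameter; centring without scaling matches the plain
  PCA whose loadings the score is defined on, and sensitivity to that
  choice is exercised in the test suite.
* **Bayesian F_ST outlier score** (`fit_outlier_model()`): a
  hierarchical model in which the locus/population \(F_{ST}\) decomposes
  on the logistic scale into a locus effect \(\alpha_i\) and a
  population effect \(\beta_j\), and haploid allele counts follow a
  beta-binomial around an ancestral frequency \(\pi_i\) with
  overdispersion \((1-F_{ij})/F_{ij}\). The sampler is random-walk
  Metropolis with per-parameter proposal scales tuned during pilot runs
  toward 25–45% acceptance. The per-locus score is the posterior mean
  of \(\mathrm{mean}_j F_{ij}\). No reversible-jump model choice is
  performed: the pipeline needs a per-locus score on the \(F_{ST}\)
  scale, not posterior inclusion odds. Priors are
  \(\alpha_i \sim N(0,1)\), \(\beta_j \sim N(-1,1)\),
  \(\pi_i \sim U(0,1)\).

Loci that are monomorphic, or nearly so, in the pooled sample (major
allele frequency strictly above 0.98) are removed before scoring
(`filter_monomorphic()`). Besides being uninformative, such loci have a
likelihood that is flat in the outlier model's locus effect, so their
scores would be prior-driven mid-range values that pollute the ranking.

## From 20 scores to nested panels

Aggregation order is fixed and deliberate: per-method scores are first
averaged across the four training datasets (`aggregate_scores()`), each
method's vector is then min–max standardized to \([0,1]\)
(`standardize_scores()`; the "0–1 scale" is implemented as min–max over
the analysed locus set), and the five standardized vectors are averaged
with equal weights into a global score (`global_ranking()`). Reversing
standardization and averaging changes the result; the tests pin the
implemented order. Exact ties are broken lexicographically by locus id,
making the whole pipeline a deterministic function of the score matrix
and the genetic map.

Because linked markers carry redundant ancestry information, the ranking
is pruned (`ld_prune()`): scanning from best to worst, a locus is
dropped when it lies on the same chromosome and strictly closer than
1 cM to an already retained, higher-ranking locus. Dropped loci do not
block others. Pruning runs after global ranking and before panel
cutting; nested panels of 48, 96, 144, 192 and 384 markers (multiplex
sizes of common commercial assays) are then prefixes of the pruned
ranking (`make_panels()`), so smaller panels are subsets of larger ones
by construction.

## Admixture estimation

`supervised_admixture()` estimates each individual's C-lineage
proportion \(q\) by maximizing the haploid two-source likelihood
\(\sum_l \log(q\,c_l + (1-q)\,m_l)\) with the reference frequencies held
fixed at training-sample estimates (clamped to \([10^{-6},
1-10^{-6}]\)). The maximizer is found by EM — \(q\) updated to the mean
posterior ancestry of the observed alleles — with the conventional
\(\varepsilon < 10^{-4}\) log-likelihood termination, followed by a
short projected-Newton polish. The polish exploits the strict concavity
of the one-dimensional likelihood: EM's linear convergence can stall
\(10^{-2}\) away from the optimum on flat likelihoods, and the polish
brings the estimate within grid-search resolution (the tests compare
against a \(10^{-4}\)-step grid oracle).

`em_admixture()` is the unsupervised K-cluster analogue (both ancestry
matrix Q and cluster frequencies estimated by block-relaxation EM,
Dirichlet-seeded, monotone log-likelihood), with `match_clusters()` to
resolve label switching against reference frequencies and
`cv_choose_k()` to pick K by masked-entry cross-validation scored with
binomial deviance. Validation defaults to the supervised estimator — it
is deterministic, faster, and panel-vs-full comparisons are its natural
use; the unsupervised route reproduces the protocol of standard
admixture software on holdout-plus-reference data.

## What the synthetic data emulate — and what they do not

No real genotypes ship with the package; `simulate_baseline()` generates
the study conditions:

* **Baseline populations.** Ancestral frequencies are uniform on
  \([0.05, 0.95]\); population frequencies follow the Balding–Nichols
  construction \(\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)\). The M-vs-C
  divergence \(F\) is calibrated by bisection
  (`calibrate_baseline()`) so the median per-locus theta between the
  training groups (34 M vs 36 C haploids) falls in \([0.65, 0.78]\),
  the level observed between these lineages on the SNP assay this
  baseline emulates. The two C subspecies are drawn around the C-lineage
  frequency with a small within-C divergence (default 0.05), so small
  panels separate M from C but not ligustica from carnica. Because the
  emulated assay carries SNPs ascertained to be polymorphic across the
  study populations, locus draws are rejected unless the pooled true
  major-allele frequency stays below 0.95; nearly all 1,183 loci then
  survive re-filtering.
* **Genetic map.** Sixteen chromosomes (the honey bee karyotype) of
  250 cM each with uniform locus positions — honey bees have an
  exceptionally long genetic map, and this layout leaves ample
  post-pruning loci with spacings of a few cM.
* **Mixture sets.** `simulate_mixture()` has two modes. *Hybrid* mode
  (default) draws per-locus ancestry Bernoulli(\(q\)) then the allele
  from that ancestry's pool — an idealized admixed genome whose
  genome-wide realized ancestry concentrates on \(q\) with SD
  \(\approx\sqrt{q(1-q)/L}\). *Pooled* mode draws each individual pure
  from one pool, C with probability \(q\) — the convention of
  genetic-stock-identification mixture simulators, where a "level" is a
  population mixing proportion. Panel validation uses pooled mode for
  the 10-level × 100-genotype simulated set, matching that convention;
  hybrid mode backs the parameter-recovery checks where a
  per-individual truth is needed.
* **Holdout set.** `simulate_holdout()` mirrors the composition of a
  realistic evaluation sample: 34 protected-stock M bees with
  introgression levels uniform on \([0, 0.01]\), 43 unprotected M bees
  uniform on \([0, 0.30]\) (mean 15%, the level reported for unprotected
  western-European apiaries), and 36 pure C-lineage references —
  113 individuals. A holdout spread uniformly over high admixture
  levels would be unrepresentative of conservation survey data and
  would be dominated by realized-ancestry sampling noise at
  intermediate \(q\).

The simulators deliberately omit linkage disequilibrium *within*
simulated genomes (loci are independent draws), genotyping error, and
allele-intensity artefacts. Passing validation therefore demonstrates
the statistical machinery under idealized sampling, not robustness to
assay-level noise; with real data the monomorphic filter is the only
QC step the package performs.

## Numerical choices

* Frequency clamping at \(10^{-6}\) avoids \(\log 0\) in every
  likelihood; estimated frequencies of exactly 0/1 from small reference
  samples are common at strongly differentiated loci.
* The outlier sampler caches per-cell log-likelihoods and uses a single
  seeded generator, so every fit is bit-reproducible; pilot tuning
  multiplies or divides proposal scales by 1.5 outside the 25–45%
  acceptance window.
* Min–max standardization of a constant score vector returns all zeros
  with a warning (the method then contributes nothing to the ranking).
* Undefined quantities (monomorphic theta denominators, frequencies
  with zero observations) are `NA` and are skipped by later averaging —
  never silently zero.
* EM monotonicity is asserted at run time: a decreasing log-likelihood
  aborts with an internal error rather than returning a wrong fit.
* Default chain lengths for the outlier model are desk-scale (5 pilots
  × 1,000, burn-in 5,000, 2,000 samples at thinning 10 — seconds per
  dataset at a thousand loci). The end-to-end pipeline and the
  acceptance script use a further reduced chain (3 × 300, burn-in
  1,000, 500 samples at thinning 4): the outlier score enters the
  global score with weight 1/5, and panel membership is insensitive to
  its Monte Carlo error at this depth. The full-scale settings of the
  reference software remain available through `mcmc_config()`.

## Problem sizes in the tests

The test suite validates components at reduced sizes (tens of loci,
reduced chains) and runs one full-scale end-to-end replicate: a
calibrated 1,183-locus baseline, all five methods on the four training
datasets, pruning, the five nested panels, a 113-individual holdout and
a 1,000-genotype pooled mixture set. The acceptance script repeats that
replicate three times and reports worst-case panel precision and
accuracy. These sizes are the package's chosen reference configuration;
larger simulations change none of the qualitative conclusions.

## Known limitations

* Two-source supervised estimation only (M vs C); K > 6 unsupervised
  clustering, diploid likelihoods and standard-error estimates for Q are
  out of scope.
* The outlier model fixes the locus effect in the model and reports
  posterior-mean \(F_{ST}\); it is not a selection-detection tool (no
  posterior odds or q-values).
* Per-locus scores from only two populations estimate a dispersion
  parameter from two frequency draws; their ranking is intrinsically
  noisy, which is precisely why the pipeline averages five methods over
  four population groupings before ranking.
* Panels designed for the M-vs-C contrast are unsuitable for general
  population-genetic inference (diversity, bottlenecks, isolation by
  distance): the markers are ascertained to be extreme.
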