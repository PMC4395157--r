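# Synthetic data: a Balding-Nichols baseline calibrated to the level of
# M/C differentiation seen on real honey bee SNP assays, plus the mixture
# simulators used to validate panels.

#' Specification of a synthetic two- or three-population baseline
#'
#' Population allele frequencies follow the Balding-Nichols construction:
#' an ancestral frequency p drawn uniformly on `anc_range`, then each
#' descendant population's frequency drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with differentiation parameter `F`.
#' Structure `"MLC"` (default) first draws an M and a C lineage frequency
#' at divergence `f`, then splits C into ligustica- and carnica-like
#' subspecies with a smaller within-C divergence `within_c_f`, so that
#' small panels can separate M from C but not the two C subspecies.
#' Training sample sizes default to 34 M + 17 ligustica + 19 carnica
#' haploid drones.  The genetic map assigns loci to 16 chromosomes
#' (the honey bee karyotype) with uniform positions over `chrom_cm`
#' centimorgans each — honey bees have an exceptionally long genetic map.
#'
#' @param n_loci number of biallelic loci (default 1183).
#' @param f M-vs-C differentiation parameter, in (0,1); see
#'   [calibrate_baseline()].
#' @param structure `"MLC"` (M + two C subspecies) or `"MC"`.
#' @param within_c_f divergence of the two C subspecies from the C lineage.
#' @param n_m,n_lig,n_car training sample sizes (for `"MC"`,
#'   `n_lig + n_car` individuals form one C population).
#' @param anc_range range of the uniform ancestral-frequency law.
#' @param n_chrom,chrom_cm genetic-map layout.
#' @param seed integer seed; every draw is reproducible from it.
#' @return List of class `baseline_spec`.
#' @export
baseline_spec <- function(n_loci = 1183, f = 0.55,
                          structure = c("MLC", "MC"), within_c_f = 0.05,
                          n_m = 34, n_lig = 17, n_car = 19,
                          anc_range = c(0.05, 0.95),
                          n_chrom = 16, chrom_cm = 250, seed = 1L) {
  structure <- match.arg(structure)
  if (n_loci < 1L) stop_config("n_loci must be >= 1")
  if (f <= 0 || f >= 1) stop_config("f must be in (0,1), got %g", f)
  if (within_c_f <= 0 || within_c_f >= 1)
    stop_config("within_c_f must be in (0,1)")
  spec <- list(n_loci = as.integer(n_loci), f = f, structure = structure,
               within_c_f = within_c_f, n_m = as.integer(n_m),
               n_lig = as.integer(n_lig), n_car = as.integer(n_car),
               anc_range = anc_range, n_chrom = as.integer(n_chrom),
               chrom_cm = chrom_cm, seed = as.integer(seed))
  class(spec) <- "baseline_spec"
  spec
}

bn_draw <- function(p, f) {
  # Balding-Nichols: Beta(p(1-F)/F, (1-p)(1-F)/F); vectorized over loci
  k <- (1 - f) / f
  rbeta(length(p), p * k, (1 - p) * k)
}

draw_haploids <- function(p, ids) {
  G <- matrix(rbinom(length(ids) * length(p), 1L, rep(p, each = length(ids))),
              nrow = length(ids))
  genotype_matrix(G, ids, names(p))
}

#' Simulate a baseline: population frequencies and training genotypes
#'
#' @param spec a [baseline_spec()].
#' @return List with `freq` (a `freq_table` of true population allele
#'   frequencies: rows `M`, `C` and, for `"MLC"`, `C-ligustica` and
#'   `C-carnica`), `genotypes` (training haploid genotype matrix),
#'   `popmap` (all samples, role `"training"`), `locus_info` (genetic
#'   map) and the `spec`.
#' @export
simulate_baseline <- function(spec) {
  stopifnot(inherits(spec, "baseline_spec"))
  set.seed(spec$seed)
  L <- spec$n_loci
  loci <- sprintf("snp%04d", seq_len(L))
  # The assay this baseline emulates carries SNPs ascertained to be
  # polymorphic across the study populations, so locus draws are accepted
  # only if the pooled (training-size weighted) major-allele frequency
  # stays below 0.95; rejected draws are replaced.  This keeps nearly all
  # loci through the in-sample monomorphic filter, as on the real assay.
  w_m <- spec$n_m / (spec$n_m + spec$n_lig + spec$n_car)
  p_anc <- p_m <- p_c <- numeric(0)
  while (length(p_m) < L) {
    need <- L - length(p_m)
    pa <- runif(2L * need, spec$anc_range[1L], spec$anc_range[2L])
    m <- bn_draw(pa, spec$f)
    cc <- bn_draw(pa, spec$f)
    pool <- w_m * m + (1 - w_m) * cc
    ok <- pmax(pool, 1 - pool) <= 0.95
    p_anc <- c(p_anc, pa[ok])[seq_len(min(L, length(p_m) + sum(ok)))]
    p_m <- c(p_m, m[ok])[seq_along(p_anc)]
    p_c <- c(p_c, cc[ok])[seq_along(p_anc)]
  }
  pops <- list(M = setNames(p_m, loci), C = setNames(p_c, loci))
  if (spec$structure == "MLC") {
    pops$`C-ligustica` <- setNames(bn_draw(p_c, spec$within_c_f), loci)
    pops$`C-carnica` <- setNames(bn_draw(p_c, spec$within_c_f), loci)
  }
  ids_m <- sprintf("M%03d", seq_len(spec$n_m))
  if (spec$structure == "MLC") {
    ids_lig <- sprintf("LIG%03d", seq_len(spec$n_lig))
    ids_car <- sprintf("CAR%03d", seq_len(spec$n_car))
    G <- rbind(draw_haploids(pops$M, ids_m),
               draw_haploids(pops$`C-ligustica`, ids_lig),
               draw_haploids(pops$`C-carnica`, ids_car))
    popmap <- data.frame(
      sample = c(ids_m, ids_lig, ids_car),
      population = c(rep("mellifera", spec$n_m),
                     rep("ligustica", spec$n_lig),
                     rep("carnica", spec$n_car)),
      role = "training",
      group = c(rep("M", spec$n_m), rep("C-ligustica", spec$n_lig),
                rep("C-carnica", spec$n_car)),
      stringsAsFactors = FALSE)
  } else {
    n_c <- spec$n_lig + spec$n_car
    ids_c <- sprintf("C%03d", seq_len(n_c))
    G <- rbind(draw_haploids(pops$M, ids_m), draw_haploids(pops$C, ids_c))
    popmap <- data.frame(
      sample = c(ids_m, ids_c),
      population = c(rep("mellifera", spec$n_m), rep("C", n_c)),
      role = "training",
      group = c(rep("M", spec$n_m), rep("C-lineage", n_c)),
      stringsAsFactors = FALSE)
  }
  P <- do.call(rbind, pops)
  colnames(P) <- loci
  freq <- structure(list(p = P,
                         n = matrix(1e6L, nrow(P), L,
                                    dimnames = dimnames(P))),
                    class = "freq_table")
  info <- locus_info(loci,
                     chrom = as.character(sample.int(spec$n_chrom, L,
                                                     replace = TRUE)),
                     cm = round(runif(L, 0, spec$chrom_cm), 2))
  list(freq = freq, genotypes = G, popmap = popmap, locus_info = info,
       spec = spec)
}

#' Calibrate baseline divergence to a target median per-locus theta
#'
#' Adjusts the M-vs-C differentiation parameter `f` by bisection until the
#' median per-locus haploid Weir-Cockerham theta, computed between the M
#' and pooled C training samples generated by the spec, falls in `target`
#' (default `[0.65, 0.78]`, the range observed for the M/C honey bee
#' lineage contrast on the assay this package emulates).  Bisection aims
#' at the midpoint and stops as soon as the realized median is within
#' `tol` of it (always inside `target`).
#'
#' @param spec a [baseline_spec()]; its seed fixes the evaluation draws.
#' @param target length-2 numeric range for the median theta.
#' @param tol stop when `|median - mean(target)| < tol`.
#' @param max_iter bisection iteration cap.
#' @return The spec with calibrated `f`, plus attributes
#'   `median_theta` and `iterations`.
#' @export
calibrate_baseline <- function(spec, target = c(0.65, 0.78), tol = 0.01,
                               max_iter = 40) {
  stopifnot(inherits(spec, "baseline_spec"))
  mid <- mean(target)
  eval_f <- function(f) {
    s <- spec; s$f <- f
    base <- simulate_baseline(s)
    pm <- base$popmap
    pops <- list(M = pm$sample[pm$group == "M"],
                 C = pm$sample[pm$group != "M"])
    ft <- allele_frequencies(base$genotypes, pops)
    median(wc_fst(ft), na.rm = TRUE)
  }
  lo <- 0.02; hi <- 0.95
  f <- spec$f
  m <- eval_f(f)
  it <- 0L
  while (abs(m - mid) >= tol && it < max_iter) {
    if (m < mid) lo <- f else hi <- f
    f <- (lo + hi) / 2
    m <- eval_f(f)
    it <- it + 1L
  }
  if (m < target[1L] || m > target[2L])
    stop_numeric("calibration failed: median theta %.3f outside [%g, %g]",
                 m, target[1L], target[2L])
  spec$f <- f
  attr(spec, "median_theta") <- m
  attr(spec, "iterations") <- it
  spec
}

#' Simulate a mixed/introgressed validation set
#'
#' Given reference allele frequencies for the two source gene pools, draws
#' individuals at each introgression level `q`.  In `"hybrid"` mode
#' (default) each individual is an admixed genome: at every locus the
#' allele's ancestry is C with probability `q`, then the allele is drawn
#' from that ancestry's frequency.  In `"pooled"` mode — the convention of
#' genetic-stock-identification mixture simulators — each individual is a
#' pure draw from one source pool, C with probability `q`, so a "level" is
#' a population-level mixing proportion rather than a per-genome one.
#'
#' @param p_m,p_c named per-locus allele-1 frequencies of the M and C
#'   reference pools (typically training-sample estimates).
#' @param levels introgression proportions in `[0, 1]`; defaults to the
#'   ten validation levels 0-90%.
#' @param n_per_level individuals per level (scalar or per-level vector).
#' @param mode `"hybrid"` or `"pooled"`.
#' @param seed integer seed.
#' @param prefix sample-id prefix.
#' @return List with `genotypes` and `truth`, a data frame of `sample`,
#'   nominal `level`, per-individual true ancestry `q_true` (equal to the
#'   level in hybrid mode; 0/1 in pooled mode) and, in hybrid mode, the
#'   realized genome-wide C-ancestry fraction `q_realized`.
#' @export
simulate_mixture <- function(p_m, p_c, levels = c(0, 0.01, 0.05, 0.1, 0.2,
                                                  0.3, 0.4, 0.5, 0.75, 0.9),
                             n_per_level = 100, mode = c("hybrid", "pooled"),
                             seed = NULL, prefix = "sim") {
  mode <- match.arg(mode)
  if (any(levels < 0 | levels > 1))
    stop_config("introgression levels must lie in [0, 1]")
  if (length(p_m) != length(p_c))
    stop_validation("p_m and p_c must cover the same loci")
  n_per_level <- rep_len(as.integer(n_per_level), length(levels))
  if (any(n_per_level < 1L)) stop_config("individuals per level must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  L <- length(p_m)
  total <- sum(n_per_level)
  G <- matrix(NA_integer_, total, L)
  truth <- data.frame(sample = character(total), level = numeric(total),
                      q_true = numeric(total), q_realized = NA_real_,
                      stringsAsFactors = FALSE)
  row <- 0L
  for (k in seq_along(levels)) {
    q <- levels[k]
    for (i in seq_len(n_per_level[k])) {
      row <- row + 1L
      if (mode == "hybrid") {
        anc <- rbinom(L, 1L, q)
        p <- ifelse(anc == 1L, p_c, p_m)
        G[row, ] <- rbinom(L, 1L, p)
        truth$q_true[row] <- q
        truth$q_realized[row] <- mean(anc)
      } else {
        src <- rbinom(1L, 1L, q)
        G[row, ] <- rbinom(L, 1L, if (src == 1L) p_c else p_m)
        truth$q_true[row] <- src
      }
      truth$level[row] <- q
      truth$sample[row] <- sprintf("%s_q%03d_%03d", prefix, round(q * 100), i)
    }
  }
  list(genotypes = genotype_matrix(G, truth$sample,
                                   names(p_m) %||% paste0("locus", 1:L)),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a study-like holdout set
#'
#' Emulates the composition of the holdout sample on which the panels are
#' validated: a majority of dark-bee (M) individuals — some from protected
#' conservation stocks with nearly no C-lineage ancestry, some from
#' unprotected apiaries with appreciable introgression — plus pure
#' C-lineage reference individuals.  M individuals are hybrid genomes at
#' an introgression level drawn uniformly on `[0, protected_max]`
#' (protected) or `[0, unprotected_max]` (unprotected); C references are
#' pure draws from the C pool.
#'
#' @inheritParams simulate_mixture
#' @param n_protected,n_unprotected,n_ref_c group sizes (defaults 34, 43
#'   and 36, totalling 113 individuals).
#' @param protected_max,unprotected_max upper bounds of the uniform
#'   introgression-level laws (defaults 0.01 and 0.30, i.e. mean levels of
#'   0.5% and 15%).
#' @return As [simulate_mixture()]: `genotypes` plus a `truth` data frame
#'   with per-individual `level`, `q_realized` and a `group` column.
#' @export
simulate_holdout <- function(p_m, p_c, n_protected = 34, n_unprotected = 43,
                             n_ref_c = 36, protected_max = 0.01,
                             unprotected_max = 0.30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(p_m)
  qs <- c(runif(n_protected, 0, protected_max),
          runif(n_unprotected, 0, unprotected_max),
          rep(1, n_ref_c))
  grp <- c(rep("M-protected", n_protected),
           rep("M-unprotected", n_unprotected),
           rep("C-reference", n_ref_c))
  n <- length(qs)
  G <- matrix(NA_integer_, n, L)
  qr <- numeric(n)
  for (i in seq_len(n)) {
    anc <- rbinom(L, 1L, qs[i])
    G[i, ] <- rbinom(L, 1L, ifelse(anc == 1L, p_c, p_m))
    qr[i] <- mean(anc)
  }
  ids <- sprintf("HO%03d", seq_len(n))
  list(genotypes = genotype_matrix(G, ids,
                                   names(p_m) %||% paste0("locus", 1:L)),
       truth = data.frame(sample = ids, group = grp, level = qs,
                          q_realized = qr, stringsAsFactors = FALSE))
}
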