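# Per-locus marker informativeness statistics.  All four statistics here
# (plus the MCMC outlier score in outlier.R) are symmetric to swapping the
# allele labels at a locus and to the order of populations.

pop_idx <- function(F, populations) {
  if (is.null(populations)) populations <- rownames(F$p)
  missing_pops <- setdiff(populations, rownames(F$p))
  if (length(missing_pops))
    stop_config("population(s) not in frequency table: %s",
                paste(missing_pops, collapse = ", "))
  populations
}

#' Per-locus Weir-Cockerham theta for haploid samples
#'
#' Variance-components estimator of F_ST adapted to haploid data: the
#' within-individual (heterozygosity) components of the diploid estimator
#' vanish because each haploid individual contributes a single allele draw.
#' For `r` populations with haploid sample sizes \eqn{n_i} and allele
#' frequencies \eqn{p_i}:
#' \deqn{a = (\bar n/n_c)[s^2 - \frac{1}{\bar n-1}(\bar p(1-\bar p) -
#'   \frac{r-1}{r}s^2)], \quad
#'   b = \frac{\bar n}{\bar n-1}[\bar p(1-\bar p) - \frac{r-1}{r}s^2]}
#' and \eqn{\theta = a/(a+b)}, where \eqn{\bar n} is the mean sample size,
#' \eqn{n_c = (N-\sum n_i^2/N)/(r-1)}, \eqn{\bar p} the count-weighted mean
#' frequency and \eqn{s^2 = \sum n_i(p_i-\bar p)^2/((r-1)\bar n)}.
#' Negative estimates are retained (not truncated): downstream ranking and
#' 0-1 standardization absorb the scale.
#'
#' @param F `freq_table` from [allele_frequencies()].
#' @param populations populations to use (default: all rows of `F`).  With
#'   more than two, the unweighted mean of all pairwise theta values is
#'   returned per locus (pairs undefined at a locus are skipped).
#' @return Named numeric vector of per-locus theta; `NA` where undefined
#'   (pooled-monomorphic locus, i.e. \eqn{a+b=0}, or missing frequencies).
#' @export
wc_fst <- function(F, populations = NULL) {
  populations <- pop_idx(F, populations)
  if (length(populations) < 2L)
    stop_config("wc_fst needs >= 2 populations")
  pairs <- utils::combn(populations, 2L, simplify = FALSE)
  th <- vapply(pairs, function(pr) {
    wc_theta_pair(F$p[pr[1L], ], F$p[pr[2L], ], F$n[pr[1L], ], F$n[pr[2L], ])
  }, numeric(ncol(F$p)))
  th <- matrix(th, ncol = length(pairs))
  out <- rowMeans(th, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  setNames(out, colnames(F$p))
}

# one pair of populations, vectorized over loci
wc_theta_pair <- function(p1, p2, n1, n2) {
  r <- 2
  ok <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  N <- n1 + n2
  nbar <- N / r
  nc <- (N - (n1^2 + n2^2) / N) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / N
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  h <- pbar * (1 - pbar) - (r - 1) / r * s2
  a <- (nbar / nc) * (s2 - h / (nbar - 1))
  b <- (nbar / (nbar - 1)) * h
  theta <- ifelse(a + b == 0, NA_real_, a / (a + b))
  theta[!ok] <- NA_real_
  theta
}

#' Per-locus allele-frequency differential (Delta)
#'
#' \eqn{\Delta = |p_i - p_j|} for a pair of populations; the unweighted
#' mean over all pairwise comparisons when more than two populations are
#' supplied.
#'
#' @inheritParams wc_fst
#' @return Named numeric vector in `[0, 1]`; `NA` where a frequency is
#'   undefined in every pair.
#' @export
delta_diff <- function(F, populations = NULL) {
  populations <- pop_idx(F, populations)
  if (length(populations) < 2L)
    stop_config("delta_diff needs >= 2 populations")
  pairs <- utils::combn(populations, 2L, simplify = FALSE)
  d <- vapply(pairs, function(pr) abs(F$p[pr[1L], ] - F$p[pr[2L], ]),
              numeric(ncol(F$p)))
  d <- matrix(d, ncol = length(pairs))
  out <- rowMeans(d, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  setNames(out, colnames(F$p))
}

#' Rosenberg's informativeness for assignment (I_n)
#'
#' Expected information a single randomly drawn allele carries about which
#' of K source populations it came from, under a uniform prior over
#' populations:
#' \deqn{I_n = \sum_{alleles} \left(-\bar p \ln \bar p +
#'   \frac{1}{K}\sum_i p_i \ln p_i\right)}
#' with \eqn{\bar p} the unweighted mean frequency across populations and
#' the convention \eqn{0\ln 0 = 0}.  Natural logarithm; the maximum is
#' \eqn{\ln K} (attained when no allele is shared between populations) and
#' the minimum 0 (identical frequencies everywhere).
#'
#' @inheritParams wc_fst
#' @return Named numeric vector in `[0, ln K]`; `NA` where any population
#'   frequency is undefined.
#' @export
informativeness_in <- function(F, populations = NULL) {
  populations <- pop_idx(F, populations)
  if (length(populations) < 2L)
    stop_config("informativeness_in needs >= 2 populations")
  P <- F$p[populations, , drop = FALSE]
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  K <- nrow(P)
  out <- 0
  for (Q in list(P, 1 - P)) {           # alleles 1 and 0
    qbar <- colMeans(Q)
    out <- out - xlogx(qbar) + colMeans(xlogx(Q))
  }
  out[colSums(is.na(P)) > 0] <- NA_real_
  out <- pmax(out, 0)                   # guard tiny negative rounding
  setNames(out, colnames(F$p))
}

#' PCA-loadings informativeness score
#'
#' Principal component analysis of the sample-by-locus call matrix
#' (missing calls imputed to the locus mean, columns centered, not
#' variance-scaled).  Each locus is scored by the sum of its squared
#' loadings over the leading `n_components` components, so loci whose
#' allele frequencies drive the dominant axes of genetic structure score
#' highest.
#'
#' @param G genotype matrix (>= 2 samples).
#' @param n_components number of leading components to sum over (default
#'   8); if the matrix rank is lower, the available components are used and
#'   a message is emitted.
#' @return Named non-negative numeric vector of per-locus scores.  Loci
#'   with all calls missing get `NA`.
#' @export
pca_informativeness <- function(G, n_components = 8) {
  if (nrow(G) < 2L) stop_config("pca_informativeness needs >= 2 samples")
  if (n_components < 1L) stop_config("n_components must be >= 1")
  X <- matrix(as.numeric(G), nrow(G), ncol(G))
  mu <- colMeans(X, na.rm = TRUE)
  allmiss <- !is.finite(mu)
  mu[allmiss] <- 0
  for (j in which(colSums(is.na(X)) > 0L)) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2L, mu)
  sv <- svd(X, nu = 0)
  tol <- max(sv$d) * 1e-8
  rank <- sum(sv$d > tol)
  k <- min(n_components, rank)
  if (k < n_components)
    message(sprintf("matrix rank %d < %d components; using %d", rank,
                    n_components, k))
  score <- rowSums(sv$v[, seq_len(k), drop = FALSE]^2)
  score[allmiss] <- NA_real_
  setNames(score, colnames(G))
}

#' Score every locus with every selection method on every training dataset
#'
#' Runs the five selection methods (haploid Weir-Cockerham theta, Delta,
#' I_n, PCA loadings, and the Bayesian F_ST outlier model) on each of the
#' training-population groupings from [build_training_datasets()],
#' producing one information-content value per locus, method and dataset
#' (5 methods x 4 datasets = 20 values per locus with the defaults).
#'
#' @param G genotype matrix containing (at least) the training samples.
#' @param pm population map.
#' @param methods subset of `c("fst","delta","in","pca","outlier_fst")`.
#' @param datasets subset of `c("I","II","III","IV")`.
#' @param mcmc [mcmc_config()] for the outlier model.
#' @param n_components PCA components (see [pca_informativeness()]).
#' @param seed integer; seeds the outlier MCMC (per-dataset offsets are
#'   derived from it so chains are independent but reproducible).
#' @return Long-format data frame (class `score_matrix`) with columns
#'   `locus`, `method`, `dataset`, `value`.  Undefined scores are `NA`
#'   (never silently zero).
#' @export
compute_score_matrix <- function(G, pm,
                                 methods = c("fst", "delta", "in", "pca",
                                             "outlier_fst"),
                                 datasets = c("I", "II", "III", "IV"),
                                 mcmc = mcmc_config(), n_components = 8,
                                 seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  tds <- build_training_datasets(pm, datasets)
  out <- vector("list", length(tds) * length(methods))
  i <- 0L
  for (d in names(tds)) {
    pops <- tds[[d]]
    F <- allele_frequencies(G, pops)
    for (m in methods) {
      v <- switch(m,
        fst = wc_fst(F),
        delta = delta_diff(F),
        `in` = informativeness_in(F),
        pca = pca_informativeness(G[unlist(pops), , drop = FALSE],
                                  n_components),
        outlier_fst = {
          cfg <- mcmc
          cfg$seed <- (if (is.null(mcmc$seed)) seed else mcmc$seed) +
            match(d, c("I", "II", "III", "IV"))
          fit_outlier_model(t(round(ifelse(F$n > 0, F$p, 0) * F$n)),
                            t(F$n), cfg)$score
        })
      i <- i + 1L
      out[[i]] <- data.frame(locus = colnames(G), method = m, dataset = d,
                             value = as.numeric(v),
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("score_matrix", "data.frame")
  res
}

#' Write a score matrix as long-format TSV
#' @param S score matrix data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(S, path) {
  write.table(S, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
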