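# Validation metrics for score vectors and admixture estimates: rank
# correlations between selection methods, top-N overlap, precision
# (regression and SD of differences), assignment accuracy, and a
# Mann-Whitney comparison of admixture distributions.

#' Spearman correlations between all (method, dataset) score vectors
#'
#' Tie-corrected (average-rank) Spearman rho between every pair of score
#' vectors in a long-format score matrix, with two-sided P-values from the
#' asymptotic t approximation.
#'
#' @param S long-format score matrix (columns `locus`, `method`,
#'   `dataset`, `value`), or a numeric matrix loci x vectors.
#' @return List with `rho` and `p` matrices (one row/column per
#'   method-dataset combination).  Constant vectors yield `NA` (flagged,
#'   with a warning from the correlation machinery suppressed).
#' @export
score_correlations <- function(S) {
  if (is.data.frame(S)) {
    key <- paste(S$method, S$dataset, sep = ".")
    loci <- unique(S$locus)
    M <- matrix(NA_real_, length(loci), length(unique(key)),
                dimnames = list(loci, unique(key)))
    for (k in unique(key)) {
      sub <- S[key == k, ]
      M[sub$locus, k] <- sub$value
    }
  } else {
    M <- as.matrix(S)
  }
  if (nrow(M) < 3L) stop_validation("need >= 3 loci for rank correlations")
  nv <- ncol(M)
  rho <- matrix(NA_real_, nv, nv, dimnames = list(colnames(M), colnames(M)))
  pval <- rho
  for (i in seq_len(nv)) {
    for (j in seq_len(i)) {
      ok <- complete.cases_(M[, i], M[, j])
      n <- sum(ok)
      if (n < 3L) next
      if (var(M[ok, i]) == 0 || var(M[ok, j]) == 0) next  # undefined, flagged NA
      r <- cor(M[ok, i], M[ok, j], method = "spearman")
      rho[i, j] <- rho[j, i] <- r
      tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
      pval[i, j] <- pval[j, i] <- 2 * stats::pt(-abs(tstat), n - 2)
    }
  }
  diag(pval) <- NA_real_
  list(rho = rho, p = pval)
}

complete.cases_ <- function(x, y) !is.na(x) & !is.na(y)

#' Overlap of top-N loci between rankings
#'
#' @param rankings named list of rankings over a common locus universe;
#'   each element is either an ordered character vector of loci (best
#'   first) or a `global_ranking` data frame.
#' @param N top-list size (default 384).
#' @return List with `pairwise` (matrix of `|top-N(a) o top-N(b)|`) and
#'   `joint` (size of the intersection across all rankings).
#' @export
topn_overlap <- function(rankings, N = 384) {
  tops <- lapply(rankings, function(r) {
    v <- if (is.data.frame(r)) r$locus else as.character(r)
    if (N > length(v))
      stop_config("N = %d exceeds the %d-locus universe", N, length(v))
    v[seq_len(N)]
  })
  k <- length(tops)
  pw <- matrix(NA_integer_, k, k, dimnames = list(names(tops), names(tops)))
  for (i in seq_len(k))
    for (j in seq_len(k))
      pw[i, j] <- length(intersect(tops[[i]], tops[[j]]))
  list(pairwise = pw, joint = length(Reduce(intersect, tops)))
}

#' Precision and accuracy of panel-based admixture estimates
#'
#' Compares per-individual admixture proportions estimated from a reduced
#' panel with those from the reference (full) marker set: the standard
#' deviation of the differences (n-1 denominator), an ordinary
#' least-squares regression of the panel estimate on the reference
#' estimate, and a per-individual assignment accuracy defined as
#' \eqn{100\,(1 - |\hat q_{panel} - \hat q_{full}|)} percent.
#'
#' @param q_panel,q_full numeric vectors of equal length (>= 2).
#' @return List with `sd_diff`, `slope`, `intercept`, `r_squared`,
#'   `correlation` (Pearson r), `accuracy` (per individual, %) and
#'   `mean_accuracy`.
#' @export
panel_precision <- function(q_panel, q_full) {
  if (length(q_panel) != length(q_full))
    stop_validation("q_panel and q_full must have equal length")
  if (length(q_panel) < 2L) stop_validation("need >= 2 individuals")
  d <- q_panel - q_full
  fit <- lm(q_panel ~ q_full)
  acc <- 100 * (1 - abs(d))
  sst <- sum((q_panel - mean(q_panel))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  list(sd_diff = sd(d),
       slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = r2,
       correlation = cor(q_panel, q_full),
       accuracy = acc,
       mean_accuracy = mean(acc))
}

#' Two-sided Mann-Whitney (rank-sum) comparison
#'
#' Exact permutation P-value (enumeration over all group labelings, valid
#' under ties) when the combined sample size is at most `exact_max`;
#' otherwise the normal approximation with tie correction.
#'
#' @param qA,qB non-empty numeric samples.
#' @param exact_max enumeration threshold on `length(qA) + length(qB)`
#'   (default 20).
#' @return List with `U` (Mann-Whitney U for sample A), `p_value`, and
#'   `method`.
#' @export
compare_distributions <- function(qA, qB, exact_max = 20) {
  nA <- length(qA); nB <- length(qB)
  if (nA == 0L || nB == 0L) stop_validation("both samples must be non-empty")
  x <- c(qA, qB)
  r <- rank(x)
  W <- sum(r[seq_len(nA)])
  U <- W - nA * (nA + 1) / 2
  mu <- nA * (nB + nA + 1) / 2
  if (nA + nB <= exact_max) {
    idx <- utils::combn(nA + nB, nA)
    sums <- colSums(matrix(r[idx], nrow = nA))
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    list(U = U, p_value = p, method = "exact enumeration")
  } else {
    ties <- table(r)
    sigma2 <- nA * nB / 12 *
      ((nA + nB + 1) - sum(ties^3 - ties) / ((nA + nB) * (nA + nB - 1)))
    if (sigma2 <= 0) return(list(U = U, p_value = 1,
                                 method = "normal approximation"))
    z <- (W - mu) / sqrt(sigma2)
    list(U = U, p_value = 2 * pnorm(-abs(z)), method = "normal approximation")
  }
}

#' Assemble a panel-evaluation report
#'
#' Convenience wrapper producing, for each panel, the precision and
#' accuracy of its admixture estimates against the full-set estimates on
#' one or more evaluation sets, plus rank-sum comparisons of the estimate
#' distributions.
#'
#' @param q_by_panel named list: panel name -> per-individual admixture
#'   estimates; must include the reference set under `full`.
#' @param truth optional per-individual true ancestry for additional
#'   comparison columns.
#' @return Data frame with one row per non-reference panel: SD of
#'   differences, regression slope/intercept/r^2, Pearson correlation,
#'   mean accuracy (%), Mann-Whitney P against the full-set distribution,
#'   and (when `truth` is given) mean accuracy against truth.
#' @export
evaluate_panels <- function(q_by_panel, truth = NULL) {
  if (!"full" %in% names(q_by_panel))
    stop_config("q_by_panel must include the reference under name 'full'")
  q_full <- q_by_panel$full
  rows <- lapply(setdiff(names(q_by_panel), "full"), function(nm) {
    pr <- panel_precision(q_by_panel[[nm]], q_full)
    mw <- compare_distributions(q_by_panel[[nm]], q_full)
    out <- data.frame(panel = nm, sd_diff = pr$sd_diff, slope = pr$slope,
                      intercept = pr$intercept, r_squared = pr$r_squared,
                      correlation = pr$correlation,
                      mean_accuracy = pr$mean_accuracy,
                      mw_p = mw$p_value, stringsAsFactors = FALSE)
    if (!is.null(truth))
      out$mean_accuracy_vs_truth <-
        mean(100 * (1 - abs(q_by_panel[[nm]] - truth)))
    out
  })
  do.call(rbind, rows)
}
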