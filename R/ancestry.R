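# Admixture-proportion estimation for haploid genotypes: a supervised
# two-source maximum-likelihood estimator (references fixed), an
# unsupervised K-way EM in the style of model-based clustering software,
# and cross-validation choice of K.

clamp_freq <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' Supervised two-source admixture estimation
#'
#' For each individual, maximizes the haploid likelihood
#' \deqn{\ell(q) = \sum_l \log\left(q\,c_l + (1-q)\,m_l\right)}
#' over \eqn{q \in [0,1]}, where \eqn{c_l}/\eqn{m_l} is the probability of
#' the observed allele under the C/M reference frequency.  The maximizer
#' is found by EM: the ancestry of each observed allele is a latent
#' Bernoulli, and `q` is updated to the mean posterior C-ancestry over
#' non-missing loci.  Iteration stops when the per-individual
#' log-likelihood gain drops below `tol`.
#'
#' @param G genotype matrix (individuals x panel loci).
#' @param p_m,p_c reference allele-1 frequencies at the panel loci
#'   (named vectors or vectors in column order); clamped to
#'   `[1e-6, 1 - 1e-6]` to avoid log(0).
#' @param tol log-likelihood termination gain (default 1e-4, the
#'   conventional admixture-software epsilon).
#' @param max_iter iteration cap.
#' @return Data frame with one row per individual: `sample`, `q`
#'   (estimated C-ancestry), `loglik`, `iters`, `n_loci` (non-missing
#'   panel loci).  Individuals with zero non-missing loci get `NA` and a
#'   warning.
#' @export
supervised_admixture <- function(G, p_m, p_c, tol = 1e-4, max_iter = 5000) {
  if (!is.null(names(p_m)) && !is.null(colnames(G))) {
    missing_loci <- setdiff(colnames(G), names(p_m))
    if (length(missing_loci))
      stop_validation("reference frequencies undefined at %d panel loci",
                      length(missing_loci))
    p_m <- p_m[colnames(G)]
    p_c <- p_c[colnames(G)]
  }
  if (length(p_m) != ncol(G) || length(p_c) != ncol(G))
    stop_validation("reference frequency vectors must match panel loci")
  pm_ <- clamp_freq(as.numeric(p_m))
  pc_ <- clamp_freq(as.numeric(p_c))
  n <- nrow(G); L <- ncol(G)
  X <- matrix(as.numeric(G), n, L)
  # per-cell observation probabilities under each source
  Cm <- sweep(X, 2L, pc_, function(g, p) ifelse(g == 1, p, 1 - p))
  Mm <- sweep(X, 2L, pm_, function(g, p) ifelse(g == 1, p, 1 - p))
  nl <- rowSums(!is.na(X))
  if (any(nl == 0L))
    warning(sprintf("%d individual(s) with zero non-missing panel loci",
                    sum(nl == 0L)))
  q <- rep(0.5, n)
  ll <- rep(-Inf, n)
  iters <- integer(n)
  active <- nl > 0L
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    W1 <- q[active] * Cm[active, , drop = FALSE]
    W0 <- (1 - q[active]) * Mm[active, , drop = FALSE]
    denom <- W1 + W0
    ll_new <- rowSums(log(denom), na.rm = TRUE)
    q[active] <- rowMeans(W1 / denom, na.rm = TRUE)
    done <- (ll_new - ll[active]) < tol
    iters[active] <- it
    ll[active] <- ll_new
    active[active] <- !done
  }
  # The per-individual log-likelihood is strictly concave in q, so a short
  # projected Newton polish removes the slow tail of EM convergence (EM's
  # linear rate can leave q 1e-2 from the maximizer when the likelihood is
  # flat); the epsilon termination above still governs the EM phase.
  ok <- nl > 0L
  q_em <- q
  ll_em <- ll
  D <- Cm - Mm
  for (polish in 1:25) {
    denom <- q * Cm + (1 - q) * Mm
    R <- D / denom
    grad <- rowSums(R, na.rm = TRUE)
    hess <- -rowSums(R^2, na.rm = TRUE)
    step <- ifelse(hess < 0, -grad / hess, 0)
    q_new <- pmin(1, pmax(0, q + step))
    # boundary stationarity: gradient pointing outward means the boundary
    # is the maximizer
    q_new[q == 0 & grad <= 0] <- 0
    q_new[q == 1 & grad >= 0] <- 1
    moved <- abs(q_new - q) > 1e-10 & ok
    q <- ifelse(ok, q_new, q)
    if (!any(moved)) break
  }
  ll[ok] <- rowSums(log(q * Cm + (1 - q) * Mm), na.rm = TRUE)[ok]
  revert <- ok & ll < ll_em            # Newton safeguard (concave, so rare)
  q[revert] <- q_em[revert]
  ll[revert] <- ll_em[revert]
  q[nl == 0L] <- NA_real_
  ll[nl == 0L] <- NA_real_
  data.frame(sample = rownames(G) %||% paste0("ind", seq_len(n)),
             q = q, loglik = ll, iters = iters, n_loci = nl,
             stringsAsFactors = FALSE)
}

#' Unsupervised K-cluster admixture estimation by EM
#'
#' Block-relaxation maximum likelihood for the haploid admixture model:
#' individual i's allele at locus l is drawn from cluster k with
#' probability \eqn{q_{ik}}, then from that cluster's allele frequency
#' \eqn{f_{kl}}.  Both the ancestry matrix Q and the cluster frequencies F
#' are estimated.  Q rows are initialized from a symmetric Dirichlet
#' (seeded); F from Q-weighted allele frequencies.  The log-likelihood is
#' non-decreasing over iterations (an internal error is raised otherwise)
#' and iteration stops when the gain is below `eps`.
#'
#' @param G genotype matrix.
#' @param K number of ancestral clusters (>= 1; `K = 1` reduces to the
#'   pooled-frequency MLE).
#' @param seed integer seed for the random initialization.
#' @param eps log-likelihood termination gain (default 1e-4).
#' @param max_iter iteration cap.
#' @return List of class `admixture_fit`: `Q` (individuals x K, rows sum
#'   to 1), `F` (K x loci cluster allele frequencies), `loglik`,
#'   `loglik_trace`, `iters`, `K`, `seed`, `converged`.
#' @export
em_admixture <- function(G, K, seed = 1L, eps = 1e-4, max_iter = 2000) {
  if (K < 1L) stop_config("K must be >= 1, got %s", K)
  n <- nrow(G); L <- ncol(G)
  if (n < K) stop_config("need at least K individuals (n = %d, K = %d)", n, K)
  set.seed(seed)
  X <- matrix(as.numeric(G), n, L)
  obs <- !is.na(X)
  nl <- rowSums(obs)
  if (any(nl == 0L)) stop_validation("individual(s) with no non-missing calls")
  Qm <- matrix(rgamma(n * K, 1), n, K)
  Qm <- Qm / rowSums(Qm)
  Fm <- matrix(0, K, L)
  for (k in seq_len(K)) {
    wsum <- colSums(Qm[, k] * ifelse(obs, 1, 0))
    Fm[k, ] <- clamp_freq(colSums(Qm[, k] * ifelse(obs, X, 0)) / pmax(wsum, 1e-12))
  }
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  A <- vector("list", K)
  for (it in seq_len(max_iter)) {
    denom <- matrix(0, n, L)
    for (k in seq_len(K)) {
      H <- matrix(rep(Fm[k, ], each = n), n, L)
      H <- ifelse(X == 1, H, 1 - H)          # NA stays NA
      A[[k]] <- Qm[, k] * H
      denom <- denom + ifelse(obs, A[[k]], 0)
    }
    ll <- sum(log(denom[obs]))
    if (ll < ll_old - 1e-8)
      stop_numeric("EM log-likelihood decreased (%.10g -> %.10g): update bug",
                   ll_old, ll)
    trace <- c(trace, ll)
    gain <- ll - ll_old
    ll_old <- ll
    # M-step
    for (k in seq_len(K)) {
      R <- ifelse(obs, A[[k]] / denom, 0)
      Qm[, k] <- rowSums(R) / nl
      num <- colSums(R * ifelse(obs, X, 0))
      den <- colSums(R)
      Fm[k, ] <- clamp_freq(ifelse(den > 0, num / den, Fm[k, ]))
    }
    Qm <- Qm / rowSums(Qm)                   # numeric hygiene
    if (it > 1L && gain < eps) { converged <- TRUE; break }
  }
  dimnames(Qm) <- list(rownames(G), paste0("K", seq_len(K)))
  dimnames(Fm) <- list(paste0("K", seq_len(K)), colnames(G))
  structure(list(Q = Qm, F = Fm, loglik = ll_old, loglik_trace = trace,
                 iters = length(trace), K = as.integer(K),
                 seed = as.integer(seed), converged = converged),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: n = %d, K = %d, loglik = %.2f (%d iters%s)\n",
              nrow(x$Q), x$K, x$loglik, x$iters,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Match unsupervised clusters to reference populations
#'
#' Resolves label switching by assigning each reference population the
#' cluster whose estimated frequency vector correlates with it most
#' strongly (greedy maximum-correlation assignment).
#'
#' @param fit `admixture_fit`.
#' @param ref_p references x loci matrix of allele-1 frequencies (e.g.
#'   rows `M` and `C`).
#' @return Named integer vector: reference label -> cluster column index.
#' @export
match_clusters <- function(fit, ref_p) {
  ref_p <- as.matrix(ref_p)
  cc <- cor(t(fit$F), t(ref_p))              # K x refs
  out <- integer(nrow(ref_p))
  names(out) <- rownames(ref_p)
  used <- logical(fit$K)
  for (step in seq_len(min(fit$K, nrow(ref_p)))) {
    cc_masked <- cc
    cc_masked[used, ] <- -Inf
    cc_masked[, out != 0L] <- -Inf
    hit <- which(cc_masked == max(cc_masked), arr.ind = TRUE)[1L, ]
    out[hit[2L]] <- hit[1L]
    used[hit[1L]] <- TRUE
  }
  out
}

#' Choose K by masked-entry cross-validation
#'
#' Randomly partitions the non-missing (individual, locus) entries into
#' `folds` folds; for each fold, refits the admixture model with those
#' entries masked and scores them by mean binomial deviance of the
#' predicted allele probability \eqn{\hat p_{il} = \sum_k q_{ik} f_{kl}}.
#' The optimal K minimizes the fold-averaged error.
#'
#' @param G genotype matrix.
#' @param K_range candidate K values (default 1:6).
#' @param folds number of folds (default 5).
#' @param seed integer seed (fold assignment and EM initializations).
#' @param ... passed to [em_admixture()].
#' @return List with `cv` (data frame of `K`, `error`) and `best_k`.
#' @export
cv_choose_k <- function(G, K_range = 1:6, folds = 5, seed = 1L, ...) {
  if (any(K_range < 1L)) stop_config("K values must be >= 1")
  set.seed(seed)
  obs_idx <- which(!is.na(G))
  if (length(obs_idx) < folds)
    stop_validation("not enough non-missing calls to form %d folds", folds)
  fold_of <- sample(rep_len(seq_len(folds), length(obs_idx)))
  err <- matrix(NA_real_, length(K_range), folds)
  for (fi in seq_len(folds)) {
    masked <- obs_idx[fold_of == fi]
    Gm <- G
    Gm[masked] <- NA_integer_
    if (any(rowSums(!is.na(Gm)) == 0L))
      stop_validation("a fold left an individual with no data; use fewer folds")
    g <- as.numeric(G[masked])
    for (ki in seq_along(K_range)) {
      fit <- em_admixture(Gm, K_range[ki], seed = seed + fi, ...)
      P <- clamp_freq(fit$Q %*% fit$F)
      ph <- P[masked]
      err[ki, fi] <- mean(-2 * (g * log(ph) + (1 - g) * log(1 - ph)))
    }
  }
  cv <- data.frame(K = K_range, error = rowMeans(err))
  list(cv = cv, best_k = K_range[which.min(cv$error)], per_fold = err)
}

#' Write a Q matrix in the de-facto admixture-tool convention
#'
#' @param fit `admixture_fit` (or a numeric Q matrix).
#' @param path output path; K whitespace-delimited columns, one row per
#'   individual in input order.  A companion `<path>.samples.tsv` holds
#'   the sample ids.
#' @return `path`, invisibly.
#' @export
write_qmatrix <- function(fit, path) {
  Q <- if (inherits(fit, "admixture_fit")) fit$Q else as.matrix(fit)
  writeLines(apply(format(Q, digits = 6), 1L, paste, collapse = " "), path)
  writeLines(rownames(Q) %||% as.character(seq_len(nrow(Q))),
             paste0(path, ".samples.tsv"))
  invisible(path)
}
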