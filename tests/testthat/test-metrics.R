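# Per-locus informativeness statistics, checked against hand-evaluated
# component formulas and a brute-force eigendecomposition.

test_that("haploid Weir-Cockerham theta matches hand-evaluated components", {
  expect_equal(unname(wc_fst(mk_freq(c(1, 0), 50))), 1)
  expect_equal(unname(wc_fst(mk_freq(c(0.5, 0.5), 20))), -1 / 19)
  # p = (0.9, 0.3), n = 50 each: s2 = .18, a = .18 - .15/49, b = (50/49)*.15
  expect_equal(unname(wc_fst(mk_freq(c(0.9, 0.3), 50))),
               (0.18 - 0.15 / 49) / 0.33, tolerance = 1e-12)
  # pooled-monomorphic pair is undefined, flagged
  expect_true(is.na(wc_fst(mk_freq(c(1, 1), 50))))
  expect_error(wc_fst(mk_freq(matrix(0.5, 1, 3), 10)),
               class = "aimpanel_config_error")
})

test_that("multi-population theta is the mean over pairwise estimates", {
  p <- c(0.9, 0.5, 0.2)
  f3 <- mk_freq(p, 40)
  pairs <- combn(3, 2)
  th <- sapply(seq_len(3), function(k) {
    unname(wc_fst(mk_freq(p[pairs[, k]], 40)))
  })
  expect_equal(unname(wc_fst(f3)), mean(th))
})

test_that("Delta is the (mean pairwise) absolute frequency differential", {
  expect_equal(unname(delta_diff(mk_freq(c(0.9, 0.3), 10))), 0.6)
  expect_equal(unname(delta_diff(mk_freq(c(0.5, 0.5), 10))), 0)
  expect_equal(unname(delta_diff(mk_freq(c(1, 0.5, 0), 10))), 2 / 3)
})

test_that("I_n attains its analytic endpoints and worked value", {
  expect_equal(unname(informativeness_in(mk_freq(c(0.4, 0.4), 10))), 0)
  expect_equal(unname(informativeness_in(mk_freq(c(1, 0), 10))), log(2))
  # K = 2, p = (0.9, 0.3): frozen from independent numeric evaluation of
  # -pbar log pbar + mean(p log p), summed over both alleles
  expect_equal(unname(informativeness_in(mk_freq(c(0.9, 0.3), 10))),
               0.2050380, tolerance = 1e-6)
})

test_that("I_n is bounded by ln K and zero only at identical frequencies", {
  set.seed(11)
  for (K in 2:4) {
    P <- matrix(runif(K * 50), K)
    v <- informativeness_in(mk_freq(P, 30))
    expect_true(all(v >= 0 & v <= log(K) + 1e-12))
    expect_gt(min(v[apply(P, 2, function(x) diff(range(x))) > 0.01]), 0)
  }
})

test_that("PCA score matches a brute-force covariance eigendecomposition", {
  set.seed(7)
  G <- genotype_matrix(matrix(rbinom(24, 1, 0.5), 6, 4))
  s <- pca_informativeness(G, n_components = 3)
  X <- scale(matrix(as.numeric(G), 6, 4), scale = FALSE)
  ev <- eigen(crossprod(X))$vectors[, 1:3]
  expect_equal(unname(s), rowSums(ev^2), tolerance = 1e-8)
})

test_that("PCA score is invariant to sample order and duplicated columns tie", {
  set.seed(8)
  G <- genotype_matrix(cbind(matrix(rbinom(40, 1, 0.5), 10, 4)[, c(1, 1, 2, 3)]))
  s <- pca_informativeness(G, 2)
  expect_equal(unname(s[1]), unname(s[2]), tolerance = 1e-10)
  perm <- sample(nrow(G))
  s2 <- pca_informativeness(genotype_matrix(unclass(G)[perm, , drop = FALSE],
                                            rownames(G)[perm], colnames(G)), 2)
  expect_equal(s, s2, tolerance = 1e-10)
})

test_that("all metrics are invariant to allele-label swaps and pop order", {
  set.seed(21)
  for (rep in 1:5) {
    P <- matrix(runif(2 * 30, 0.02, 0.98), 2)
    ft <- mk_freq(P, 45)
    flip <- runif(30) < 0.5
    Pf <- P; Pf[, flip] <- 1 - Pf[, flip]
    ftf <- mk_freq(Pf, 45)
    ftr <- mk_freq(P[2:1, ], 45)
    for (fn in list(wc_fst, delta_diff, informativeness_in)) {
      expect_equal(fn(ft), fn(ftf), tolerance = 1e-12)
      expect_equal(fn(ft), fn(ftr), tolerance = 1e-12)
    }
  }
  # PCA: flipping allele labels flips centered columns' sign only
  set.seed(22)
  G <- genotype_matrix(matrix(rbinom(200, 1, 0.4), 10, 20))
  Gf <- unclass(G); Gf[, 1:7] <- 1L - Gf[, 1:7]
  expect_equal(pca_informativeness(G, 4),
               pca_informativeness(genotype_matrix(Gf, rownames(G),
                                                   colnames(G)), 4),
               tolerance = 1e-8)
})

test_that("theta, Delta and I_n rank loci nearly identically on random pairs", {
  set.seed(33)
  P <- matrix(runif(2 * 1000, 0.05, 0.95), 2)
  ft <- mk_freq(P, 50)
  th <- wc_fst(ft); de <- delta_diff(ft); io <- informativeness_in(ft)
  expect_gt(cor(th, de, method = "spearman"), 0.9)
  expect_gt(cor(th, io, method = "spearman"), 0.9)
  expect_gt(cor(de, io, method = "spearman"), 0.9)
})

test_that("score matrix covers methods x datasets in long format", {
  fx <- mk_training()
  S <- compute_score_matrix(fx$G, fx$popmap,
                            methods = c("fst", "delta", "in", "pca"))
  expect_s3_class(S, "score_matrix")
  expect_identical(nrow(S), 4L * 4L * ncol(fx$G))
  expect_identical(sort(unique(S$method)), sort(c("fst", "delta", "in", "pca")))
  # values present and finite for polymorphic, well-sampled input
  expect_true(mean(is.na(S$value)) < 0.05)
})
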