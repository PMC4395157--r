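# Supervised and unsupervised admixture estimation and CV choice of K.

test_that("supervised estimator hits analytic boundary and symmetric cases", {
  G <- genotype_matrix(matrix(1L, 1, 3))
  expect_equal(supervised_admixture(G, rep(0, 3), rep(1, 3))$q, 1)
  # two mirrored loci, genotype (1,1): likelihood symmetric about q = 1/2
  G2 <- genotype_matrix(matrix(c(1L, 1L), 1, 2))
  expect_equal(supervised_admixture(G2, c(0.2, 0.8), c(0.8, 0.2))$q, 0.5,
               tolerance = 1e-6)
})

test_that("supervised estimates match a 1e-4 grid-search oracle", {
  set.seed(5)
  worst <- 0
  for (i in 1:100) {
    L <- 60
    pm <- runif(L, 0.05, 0.95)
    pc <- runif(L, 0.05, 0.95)
    q <- runif(1)
    g <- rbinom(L, 1, q * pc + (1 - q) * pm)
    qh <- supervised_admixture(genotype_matrix(matrix(g, 1)), pm, pc)$q
    worst <- max(worst, abs(qh - grid_admixture_oracle(g, pm, pc)))
  }
  expect_lt(worst, 1e-3)
})

test_that("individuals with no panel data are flagged, not guessed", {
  G <- genotype_matrix(rbind(a = c(1L, 0L), b = c(NA, NA)))
  expect_warning(r <- supervised_admixture(G, c(.1, .1), c(.9, .9)),
                 "zero non-missing")
  expect_true(is.na(r$q[2]) && !is.na(r$q[1]))
})

test_that("EM: K = 1 reduces to the pooled-frequency MLE in closed form", {
  set.seed(9)
  G <- genotype_matrix(matrix(rbinom(80, 1, 0.3), 8, 10))
  fit <- em_admixture(G, K = 1, seed = 2)
  expect_equal(unname(fit$Q[, 1]), rep(1, 8))
  phat <- pmin(pmax(colMeans(G), 1e-6), 1 - 1e-6)
  ll <- sum(colSums(G) * log(phat) + colSums(1 - G) * log(1 - phat))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("EM log-likelihood is non-decreasing and runs are seed-stable", {
  set.seed(10)
  G <- genotype_matrix(matrix(rbinom(600, 1, runif(30)), 20, 30))
  fit <- em_admixture(G, K = 3, seed = 4, max_iter = 200)
  expect_false(is.unsorted(fit$loglik_trace))
  expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-9))
  fit2 <- em_admixture(G, K = 3, seed = 4, max_iter = 200)
  expect_identical(fit$Q, fit2$Q)
  expect_error(em_admixture(G, K = 0), class = "aimpanel_config_error")
})

test_that("EM separates fully diverged populations at K = 2", {
  # fixed-difference loci: population M all 0, population C all 1 in truth
  set.seed(11)
  L <- 60
  G <- rbind(matrix(rbinom(20 * L, 1, 0.02), 20),
             matrix(rbinom(20 * L, 1, 0.98), 20))
  G[1:20, 1:30] <- 0L; G[21:40, 1:30] <- 1L   # half the loci exactly fixed
  G <- genotype_matrix(G)
  fit <- em_admixture(G, K = 2, seed = 5)
  expect_true(all(apply(fit$Q, 1, max) > 0.99))
  # label switching resolves against reference frequencies
  refs <- rbind(M = c(rep(0, 30), rep(0.02, 30)),
                C = c(rep(1, 30), rep(0.98, 30)))
  mapk <- match_clusters(fit, refs)
  expect_identical(sort(unname(mapk)), 1:2)
  expect_gt(mean(fit$Q[21:40, mapk["C"]]), 0.99)
})

test_that("supervised and unsupervised estimates agree on mixed data", {
  set.seed(12)
  L <- 300
  pm <- runif(L, 0, 0.15); pc <- runif(L, 0.85, 1)
  mix <- simulate_mixture(pm, pc, levels = c(0, .2, .5, 1),
                          n_per_level = 15, seed = 13)
  refs <- rbind(matrix(rbinom(20 * L, 1, rep(pm, each = 20)), 20),
                matrix(rbinom(20 * L, 1, rep(pc, each = 20)), 20))
  rownames(refs) <- sprintf("ref%02d", 1:40)
  all_g <- genotype_matrix(rbind(refs, unclass(mix$genotypes)))
  fit <- em_admixture(all_g, K = 2, seed = 6)
  mapk <- match_clusters(fit, rbind(M = pm, C = pc))
  q_un <- fit$Q[-(1:40), mapk["C"]]
  q_sup <- supervised_admixture(mix$genotypes, pm, pc)$q
  expect_lt(mean(abs(q_un - q_sup)), 0.03)
})

test_that("nested panels correlate increasingly with the full-set estimate", {
  set.seed(14)
  L <- 400
  pm <- runif(L, 0, 0.3); pc <- runif(L, 0.7, 1)
  mix <- simulate_mixture(pm, pc, levels = c(0, .1, .3, .5, .9),
                          n_per_level = 20, seed = 15)
  sizes <- c(20, 80, 300)
  cors <- sapply(sizes, function(s) {
    idx <- seq_len(s)
    cor(supervised_admixture(mix$genotypes[, idx], pm[idx], pc[idx])$q,
        supervised_admixture(mix$genotypes, pm, pc)$q)
  })
  expect_false(is.unsorted(cors))
})

test_that("cross-validation selects K = 2 for two diverged populations", {
  set.seed(16)
  L <- 100
  G <- rbind(matrix(rbinom(25 * L, 1, 0.03), 25),
             matrix(rbinom(25 * L, 1, 0.97), 25))
  G <- genotype_matrix(G)
  cv <- cv_choose_k(G, K_range = 1:3, folds = 3, seed = 2, max_iter = 300)
  expect_identical(cv$best_k, 2L)
  cv2 <- cv_choose_k(G, K_range = 1:3, folds = 3, seed = 2, max_iter = 300)
  expect_identical(cv$cv, cv2$cv)              # seed-deterministic table
  expect_error(cv_choose_k(G, K_range = 0:2), class = "aimpanel_config_error")
})
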