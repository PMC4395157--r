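# Two-step aggregation, 0-1 standardization, global ranking, cM pruning
# and nested panel construction.

mk_scores <- function(values) {
  # values: named list method -> dataset -> locus vector
  do.call(rbind, lapply(names(values), function(m) {
    do.call(rbind, lapply(names(values[[m]]), function(d) {
      v <- values[[m]][[d]]
      data.frame(locus = names(v), method = m, dataset = d, value = unname(v),
                 stringsAsFactors = FALSE)
    }))
  }))
}

test_that("aggregation averages datasets and skips flagged-missing cells", {
  loci <- c("a", "b")
  S <- mk_scores(list(fst = list(
    I = c(a = 0.2, b = 0.3), II = c(a = 0.4, b = NA),
    III = c(a = 0.6, b = 0.6), IV = c(a = 0.8, b = 0.9))))
  M <- aggregate_scores(S)
  expect_equal(M["a", "fst"], 0.5)
  expect_equal(M["b", "fst"], 0.6)              # mean of defined cells
  S1 <- mk_scores(list(fst = list(I = c(a = 0.1, b = 0.7))))
  expect_equal(aggregate_scores(S1)[, "fst"], c(a = 0.1, b = 0.7))
})

test_that("min-max standardization maps to [0,1] with degenerate policy", {
  expect_equal(standardize_scores(c(-0.05, 0.5, 1.0)),
               c(0, 0.55 / 1.05, 1))
  v <- c(0, 0.25, 1)
  expect_equal(standardize_scores(v), v)        # already spans [0,1]
  expect_warning(z <- standardize_scores(c(2, 2, 2)), "constant")
  expect_equal(z, c(0, 0, 0))
  expect_error(standardize_scores(c(NA, NA)),
               class = "aimpanel_validation_error")
})

test_that("global ranking averages standardized methods, ties broken by id", {
  M <- cbind(m1 = c(za = 1, ab = 1, cc = 0.5), m2 = c(za = 1, ab = 1, cc = 0))
  r <- global_ranking(M)
  expect_identical(r$locus, c("ab", "za", "cc"))  # tie at top -> lexicographic
  expect_identical(r$rank, 1:3)
  # single method: ranking by that method's standardized score
  r1 <- global_ranking(M[, 1, drop = FALSE])
  expect_identical(r1$locus[3], "cc")
  expect_equal(r1$global, c(1, 1, 0))
})

test_that("ranking matches a brute-force oracle on random scores", {
  set.seed(14)
  L <- 20
  loci <- sprintf("l%02d", seq_len(L))
  vals <- lapply(setNames(nm = c("fst", "delta", "in", "pca", "outlier_fst")),
    function(m) lapply(setNames(nm = c("I", "II", "III", "IV")),
      function(d) setNames(runif(L), loci)))
  S <- mk_scores(vals)
  r <- global_ranking(aggregate_scores(S))
  # independent recomputation with elementary operations
  arr <- sapply(vals, function(m) rowMeans(sapply(m, identity)))
  std <- apply(arr, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  glob <- rowMeans(std)
  expect_equal(setNames(r$global, r$locus), sort(glob, decreasing = TRUE))
  expect_identical(r$locus, names(sort(glob, decreasing = TRUE)))
})

test_that("pruning follows the greedy strict-< rule and blocked loci do not block", {
  rk <- structure(data.frame(locus = c("a", "b", "c"),
                             global = c(0.9, 0.8, 0.7), rank = 1:3,
                             stringsAsFactors = FALSE),
                  class = c("global_ranking", "data.frame"))
  info <- locus_info(c("a", "b", "c"), chrom = "1", cm = c(0.0, 0.5, 1.0))
  pr <- ld_prune(rk, info, min_cm = 1)
  expect_identical(pr$retained, c(TRUE, FALSE, TRUE))  # 1.0 cM gap retained
  expect_identical(pr$blocker, c(NA, "a", NA))
  # blocked locus must not shadow later loci
  info2 <- locus_info(c("a", "b", "c"), chrom = "1", cm = c(0.0, 0.9, 1.5))
  pr2 <- ld_prune(rk, info2, min_cm = 1)
  expect_identical(pr2$retained, c(TRUE, FALSE, TRUE)) # c is 0.6 from pruned b
  # different chromosomes never block
  info3 <- locus_info(c("a", "b", "c"), chrom = c("1", "2", "3"),
                      cm = c(0, 0.1, 0.2))
  expect_true(all(ld_prune(rk, info3)$retained))
})

test_that("no two retained loci on a chromosome are closer than min_cm", {
  set.seed(15)
  L <- 200
  loci <- sprintf("l%03d", seq_len(L))
  rk <- global_ranking(cbind(x = setNames(runif(L), loci)))
  info <- locus_info(loci, chrom = as.character(sample(1:5, L, TRUE)),
                     cm = round(runif(L, 0, 40), 2))
  pr <- ld_prune(rk, info, min_cm = 1)
  kept <- merge(pr[pr$retained, "locus", drop = FALSE], info, sort = FALSE)
  for (ch in unique(kept$chrom)) {
    pos <- sort(kept$cm[kept$chrom == ch])
    if (length(pos) > 1) expect_true(all(diff(pos) >= 1))
  }
})

test_that("panels are nested prefixes and fail loudly on shortfall", {
  loci <- sprintf("l%03d", 1:400)
  rk <- global_ranking(cbind(x = setNames(seq(1, 0, length.out = 400), loci)))
  p <- make_panels(rk)
  expect_named(p, paste0("panel_", c(48, 96, 144, 192, 384)))
  for (i in 2:5) expect_identical(p[[i]][seq_along(p[[i - 1]])], p[[i - 1]])
  p2 <- make_panels(rk[1:5, ], sizes = c(2, 4))
  expect_identical(p2$panel_2, rk$locus[1:2])
  expect_identical(p2$panel_4, rk$locus[1:4])
  expect_error(make_panels(rk[1:300, ]), "short by 84",
               class = "aimpanel_config_error")
})

test_that("dropping a method never violates panel nesting", {
  set.seed(16)
  L <- 60
  loci <- sprintf("l%02d", seq_len(L))
  M <- sapply(setNames(nm = c("fst", "delta", "in")),
              function(m) setNames(runif(L), loci))
  for (keep in list(c("fst", "delta", "in"), c("fst", "in"))) {
    p <- make_panels(global_ranking(M[, keep, drop = FALSE]),
                     sizes = c(10, 20, 40))
    expect_identical(p$panel_20[1:10], p$panel_10)
    expect_identical(p$panel_40[1:20], p$panel_20)
  }
})
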