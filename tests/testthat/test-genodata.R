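# Data model, file dialects, allele frequencies and locus filters.

test_that("genotype matrix validates calls and identifiers", {
  G <- genotype_matrix(rbind(a = c(0, 1, NA), b = c(1, 1, 0)))
  expect_identical(dim(G), c(2L, 3L))
  expect_error(genotype_matrix(rbind(a = c(0, 2), b = c(1, 0))),
               class = "aimpanel_validation_error")
  expect_error(genotype_matrix(rbind(c(0, 1), c(1, 0)),
                               samples = c("x", "x")),
               class = "aimpanel_validation_error")
})

test_that("genotype TSV round-trips byte-identically", {
  G <- genotype_matrix(rbind(s1 = c(0, 1, NA), s2 = c(1, 1, 0)),
                       loci = c("L1", "L2", "L3"))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(G, f1)
  rt <- read_genotypes(f1, "tsv")
  expect_identical(rt$genotypes, G)
  write_genotypes(rt$genotypes, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("malformed TSV rows are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("L1\tL2", "s1\t0\t1", "s2\t0"), f)
  expect_error(read_genotypes(f, "tsv"), "line 3",
               class = "aimpanel_validation_error")
})

test_that("ped/map input collapses homozygote pairs and rejects heterozygotes", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1\tsnpA\t0.5\t100", "1\tsnpB\t2.5\t200"), map)
  writeLines(c("fam1 s1 0 0 1 -9 1 1 2 2",
               "fam1 s2 0 0 1 -9 2 2 0 0"), ped)
  r <- read_genotypes(ped, "pedmap", map_path = map)
  expect_identical(unname(r$genotypes["s1", ]), c(0L, 1L))
  expect_identical(unname(r$genotypes["s2", ]), c(1L, NA_integer_))
  expect_identical(r$locus_info$cm, c(0.5, 2.5))
  writeLines("fam1 s1 0 0 1 -9 1 2 2 2", ped)
  expect_error(read_genotypes(ped, "pedmap", map_path = map),
               "heterozygous", class = "aimpanel_validation_error")
})

test_that("a study-sized synthetic file parses to the expected shape", {
  set.seed(42)
  G <- genotype_matrix(matrix(rbinom(113 * 1183, 1, 0.4), 113, 1183))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(G, f)
  r <- read_genotypes(f, "tsv")
  expect_identical(dim(r$genotypes), c(113L, 1183L))
})

test_that("allele frequencies count allele 1 over non-missing calls", {
  G <- genotype_matrix(rbind(a = c(1, NA), b = c(1, NA), c = c(0, NA),
                             d = c(NA, NA)))
  ft <- allele_frequencies(G, list(P = c("a", "b", "c", "d")))
  expect_equal(unname(ft$p[1, 1]), 2 / 3)
  expect_identical(unname(ft$n[1, ]), c(3L, 0L))
  expect_true(is.na(ft$p[1, 2]))                 # all-missing locus flagged
  G2 <- genotype_matrix(rbind(a = 1, b = 1, c = 0, d = 0))
  ft2 <- allele_frequencies(G2, list(X = c("a", "b"), Y = c("c", "d")))
  expect_equal(unname(ft2$p[, 1]), c(1, 0))      # fixed difference
  expect_error(allele_frequencies(G2, list(X = c("a", "zz"))),
               class = "aimpanel_validation_error")
})

test_that("complementary allele frequencies sum to 1 wherever defined", {
  set.seed(3)
  G <- genotype_matrix(matrix(sample(c(0L, 1L, NA), 200, TRUE), 10, 20))
  ft1 <- allele_frequencies(G)
  flipped <- genotype_matrix(1L - unclass(G), rownames(G), colnames(G))
  ft0 <- allele_frequencies(flipped)
  ok <- ft1$n[1, ] > 0
  expect_equal(ft1$p[1, ok] + ft0$p[1, ok],
               setNames(rep(1, sum(ok)), colnames(G)[ok]))
})

test_that("monomorphic filter uses a strict pooled cutoff and is idempotent", {
  ft <- mk_freq(rbind(c(0.99, 0.98, 0.50, 0.01)), 100)
  kept <- filter_monomorphic(ft)
  expect_identical(kept, c("L2", "L3"))          # 0.98 retained, 0.99/0.01 out
  ft2 <- mk_freq(ft$p[, kept, drop = FALSE], 100)
  expect_identical(filter_monomorphic(ft2), kept)
  expect_error(filter_monomorphic(ft, cutoff = 0.4),
               class = "aimpanel_config_error")
  # pooled across populations, weighted by sample counts
  ftp <- structure(list(p = rbind(A = c(1, 0.5), B = c(0.9, 0.5)),
                        n = rbind(A = c(90, 90), B = c(10, 10))),
                   class = "freq_table")
  colnames(ftp$p) <- colnames(ftp$n) <- c("L1", "L2")
  expect_identical(filter_monomorphic(ftp), "L2") # pooled p = 0.99 at L1
})

test_that("training datasets I-IV group samples as specified", {
  pm <- mk_popmap(34, 17, 19)
  tds <- build_training_datasets(pm)
  expect_named(tds, c("I", "II", "III", "IV"))
  expect_identical(lengths(tds$I), c(M = 34L, C = 36L))
  expect_identical(lengths(tds$II), c(M = 34L, `C-ligustica` = 17L))
  expect_identical(lengths(tds$III), c(M = 34L, `C-carnica` = 19L))
  expect_identical(lengths(tds$IV),
                   c(M = 34L, `C-ligustica` = 17L, `C-carnica` = 19L))
  no_car <- mk_popmap(4, 3, 2)
  no_car <- no_car[no_car$group != "C-carnica", ]
  expect_silent(build_training_datasets(no_car, "II"))
  expect_error(build_training_datasets(no_car, "III"),
               class = "aimpanel_config_error")
  expect_error(build_training_datasets(no_car, "IV"),
               class = "aimpanel_config_error")
})
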