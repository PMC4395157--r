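# Shared fixture builders.  All data are generated in code at test time.

# frequency table from a populations x loci matrix (or per-pop vectors)
mk_freq <- function(p, n) {
  # vector input: one biallelic locus observed in length(p) populations
  if (is.null(dim(p))) p <- matrix(p, ncol = 1)
  if (is.null(rownames(p))) rownames(p) <- paste0("P", seq_len(nrow(p)))
  if (is.null(colnames(p))) colnames(p) <- paste0("L", seq_len(ncol(p)))
  n <- matrix(n, nrow(p), ncol(p), dimnames = dimnames(p))
  structure(list(p = p, n = n), class = "freq_table")
}

# haploid draws from per-population frequencies; one block per population
mk_two_pop_geno <- function(p_a, p_b, n_a, n_b, prefix = c("A", "B")) {
  G <- rbind(
    matrix(rbinom(n_a * length(p_a), 1, rep(p_a, each = n_a)), n_a),
    matrix(rbinom(n_b * length(p_b), 1, rep(p_b, each = n_b)), n_b))
  genotype_matrix(G, c(sprintf("%s%02d", prefix[1], seq_len(n_a)),
                       sprintf("%s%02d", prefix[2], seq_len(n_b))))
}

# training popmap in the study layout (M / ligustica / carnica)
mk_popmap <- function(n_m = 6, n_lig = 4, n_car = 5) {
  data.frame(
    sample = c(sprintf("M%02d", seq_len(n_m)), sprintf("L%02d", seq_len(n_lig)),
               sprintf("C%02d", seq_len(n_car))),
    population = c(rep("mellifera", n_m), rep("ligustica", n_lig),
                   rep("carnica", n_car)),
    role = "training",
    group = c(rep("M", n_m), rep("C-ligustica", n_lig),
              rep("C-carnica", n_car)),
    stringsAsFactors = FALSE)
}

# small three-group training genotype set matching mk_popmap()
mk_training <- function(L = 40, n_m = 6, n_lig = 4, n_car = 5, seed = 1) {
  set.seed(seed)
  pm <- runif(L, 0.02, 0.3)
  pc <- runif(L, 0.7, 0.98)
  popmap <- mk_popmap(n_m, n_lig, n_car)
  G <- rbind(
    matrix(rbinom(n_m * L, 1, rep(pm, each = n_m)), n_m),
    matrix(rbinom(n_lig * L, 1, rep(pc, each = n_lig)), n_lig),
    matrix(rbinom(n_car * L, 1, rep(pc, each = n_car)), n_car))
  list(G = genotype_matrix(G, popmap$sample, sprintf("snp%03d", seq_len(L))),
       popmap = popmap, p_m = pm, p_c = pc)
}

# tiny reduced MCMC settings for unit tests
test_mcmc <- function(seed = 1) {
  mcmc_config(pilot_runs = 2, pilot_length = 150, burn_in = 300,
              samples = 200, thin = 2, seed = seed)
}

# 1e-4 grid-search oracle for the supervised admixture likelihood
grid_admixture_oracle <- function(g, p_m, p_c, step = 1e-4) {
  cl <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  cvec <- cl(ifelse(g == 1, p_c, 1 - p_c))
  mvec <- cl(ifelse(g == 1, p_m, 1 - p_m))
  grid <- seq(0, 1, step)
  ll <- log(outer(grid, cvec) + outer(1 - grid, mvec))
  grid[which.max(rowSums(ll))]
}
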