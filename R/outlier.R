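#' MCMC settings for the Bayesian F_ST outlier model
#'
#' Defaults are desk-scale (a few seconds per fit on ~1,000 loci).  The
#' full-scale settings used by the reference software for this model class
#' (20 pilot runs of 5,000 iterations, 50,000 burn-in, 5,000 samples at
#' thinning 10) are available by passing those values explicitly.
#'
#' @param pilot_runs number of pilot runs used to tune proposal scales.
#' @param pilot_length sweeps per pilot run.
#' @param burn_in post-tuning sweeps discarded before sampling.
#' @param samples number of recorded posterior samples.
#' @param thin sweeps between recorded samples.
#' @param seed optional integer seed applied (via [set.seed()]) by
#'   [fit_outlier_model()] before the chain starts.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(pilot_runs = 5, pilot_length = 1000, burn_in = 5000,
                        samples = 2000, thin = 10, seed = NULL) {
  cfg <- list(pilot_runs = as.integer(pilot_runs),
              pilot_length = as.integer(pilot_length),
              burn_in = as.integer(burn_in),
              samples = as.integer(samples),
              thin = as.integer(thin),
              seed = if (!is.null(seed)) as.integer(seed))
  counts <- unlist(cfg[c("pilot_runs", "pilot_length", "burn_in",
                         "samples", "thin")])
  if (any(counts < 1L))
    stop_config("all MCMC counts must be >= 1")
  class(cfg) <- "mcmc_config"
  cfg
}

#' Fit the Bayesian F_ST outlier model
#'
#' Hierarchical Bayesian model for detecting loci whose differentiation
#' departs from the genome-wide pattern, used here as the fifth per-locus
#' information score.  The locus/population F_ST is decomposed on the
#' logistic scale into a locus effect \eqn{\alpha_i} and a population
#' effect \eqn{\beta_j}, \eqn{F_{ij} = \mathrm{logit}^{-1}(\alpha_i +
#' \beta_j)}; observed haploid allele counts follow a beta-binomial around
#' an ancestral frequency \eqn{\pi_i} with overdispersion
#' \eqn{(1-F_{ij})/F_{ij}}.  The locus effect is always in the model (no
#' reversible-jump model choice): the output of interest is the per-locus
#' posterior-mean F_ST, \eqn{\mathrm{score}_i = E[\,\mathrm{mean}_j
#' F_{ij}\,]}, not posterior inclusion odds.
#'
#' Sampling is random-walk Metropolis with per-parameter proposal scales
#' tuned during pilot runs toward 25-45% acceptance.  Chains are
#' reproducible: one seeded generator, no parallelism.
#'
#' @param counts loci x populations matrix of allele-1 counts.
#' @param sizes matrix of haploid sample sizes (non-missing calls), same
#'   shape as `counts`.
#' @param config [mcmc_config()].
#' @return List with `score` (named per-locus posterior-mean F_ST, strictly
#'   inside (0,1)), `alpha` and `beta` posterior means, `acceptance` rates
#'   per parameter block, and `samples` recorded.
#' @examples
#' cfg <- mcmc_config(pilot_runs = 2, pilot_length = 100, burn_in = 100,
#'                    samples = 50, thin = 2, seed = 1)
#' fit_outlier_model(counts = cbind(c(48, 2), c(25, 26)),
#'                   sizes = matrix(50, 2, 2), config = cfg)$score
#' @export
fit_outlier_model <- function(counts, sizes, config = mcmc_config()) {
  counts <- as.matrix(counts); sizes <- as.matrix(sizes)
  if (!identical(dim(counts), dim(sizes)))
    stop_validation("counts and sizes must have the same shape")
  if (ncol(counts) < 2L)
    stop_config("outlier model needs >= 2 populations, got %d", ncol(counts))
  if (any(counts < 0 | counts > sizes, na.rm = TRUE))
    stop_validation("counts must satisfy 0 <= count <= size")
  if (!inherits(config, "mcmc_config")) stop_config("config must be mcmc_config()")
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .outlier_mcmc_cpp(counts, sizes, config$pilot_runs,
                           config$pilot_length, config$burn_in,
                           config$samples, config$thin)
  acc <- res$acceptance
  if (any(acc < 0.01 | acc > 0.90, na.rm = TRUE))
    warning(sprintf("MCMC acceptance outside (1%%, 90%%) after tuning: %s",
                    paste(sprintf("%s=%.3f", names(acc), acc), collapse = ", ")))
  names(res$score) <- rownames(counts)
  names(res$alpha) <- rownames(counts)
  res
}
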