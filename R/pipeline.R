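# End-to-end orchestration: score -> rank -> prune -> panels -> simulate
# validation sets -> admixture -> evaluation, with every artifact written
# alongside a config snapshot and manifest so runs are reproducible.

#' Build and validate a pipeline configuration
#'
#' Either `synthetic = TRUE` (a calibrated baseline is generated; the
#' default) or paths to genotype/popmap/map files must be given.
#'
#' @param out_dir output directory.
#' @param synthetic generate the baseline instead of reading files.
#' @param genotypes_path,popmap_path,map_path input files (TSV dialects;
#'   see [read_genotypes()], [read_popmap()], [read_genetic_map()]).
#' @param n_loci loci for the synthetic baseline.
#' @param calibrate calibrate baseline divergence via
#'   [calibrate_baseline()].
#' @param panel_sizes nested panel sizes.
#' @param min_cm pruning distance in centimorgans.
#' @param methods selection methods to run (toggle the outlier MCMC off by
#'   omitting `"outlier_fst"`).
#' @param mcmc [mcmc_config()] for the outlier model; the default here is
#'   a reduced chain sized for pipeline runs.
#' @param mixture_levels,mixture_n simulated-mixture design (defaults: ten
#'   introgression levels x 100 individuals).
#' @param mixture_mode `"pooled"` (stock-identification style pure
#'   genotypes, the validation default) or `"hybrid"`.
#' @param unsupervised also run unsupervised EM (K = 2) on the holdout.
#' @param eps admixture termination gain.
#' @param seed master seed; all stage seeds derive from it.
#' @return Validated list of class `run_config`.
#' @export
pipeline_config <- function(out_dir = "aimpanel_run",
                            synthetic = TRUE,
                            genotypes_path = NULL, popmap_path = NULL,
                            map_path = NULL,
                            n_loci = 1183, calibrate = TRUE,
                            panel_sizes = c(48, 96, 144, 192, 384),
                            min_cm = 1,
                            methods = c("fst", "delta", "in", "pca",
                                        "outlier_fst"),
                            mcmc = mcmc_config(pilot_runs = 3,
                                               pilot_length = 300,
                                               burn_in = 1000, samples = 500,
                                               thin = 4),
                            mixture_levels = c(0, 0.01, 0.05, 0.1, 0.2, 0.3,
                                               0.4, 0.5, 0.75, 0.9),
                            mixture_n = 100,
                            mixture_mode = c("pooled", "hybrid"),
                            unsupervised = FALSE,
                            eps = 1e-4, seed = 1L) {
  mixture_mode <- match.arg(mixture_mode)
  if (!synthetic) {
    for (p in c(genotypes_path, popmap_path)) {
      if (is.null(p) || !file.exists(p))
        stop_config("non-synthetic run needs existing genotypes_path and popmap_path")
    }
    if (min_cm > 0 && (is.null(map_path) || !file.exists(map_path)))
      stop_config("pruning is enabled (min_cm = %g) but no genetic map was given",
                  min_cm)
  }
  cfg <- list(out_dir = out_dir, synthetic = synthetic,
              genotypes_path = genotypes_path, popmap_path = popmap_path,
              map_path = map_path, n_loci = as.integer(n_loci),
              calibrate = calibrate, panel_sizes = as.integer(panel_sizes),
              min_cm = min_cm, methods = methods, mcmc = mcmc,
              mixture_levels = mixture_levels,
              mixture_n = as.integer(mixture_n),
              mixture_mode = mixture_mode, unsupervised = unsupervised,
              eps = eps, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full AIM-panel pipeline
#'
#' Executes, in order: input acquisition (synthetic baseline or files),
#' monomorphic filtering, per-locus scoring on the four training datasets,
#' two-step aggregation and global ranking, genetic-map pruning, nested
#' panel construction, simulation of holdout and mixture validation sets
#' (synthetic mode), supervised admixture estimation per panel and for the
#' full set, and the evaluation report.  Every artifact is written under
#' `cfg$out_dir` together with the config snapshot and a manifest of file
#' checksums; a rerun with the same config reproduces the artifacts
#' bit-for-bit.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory results (`ranking`,
#'   `panels`, `scores`, `admixture`, `evaluation`, `out_dir`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = c(class(e)[1L], "aimpanel_stage_error", "error", "condition")))
    })
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- data -----------------------------------------------------------
  dat <- stage("data", {
    if (cfg$synthetic) {
      spec <- baseline_spec(n_loci = cfg$n_loci, seed = cfg$seed)
      if (cfg$calibrate) {
        spec <- calibrate_baseline(spec)
        say("calibrated baseline divergence f = %.3f (median theta %.3f)",
            spec$f, attr(spec, "median_theta"))
      }
      simulate_baseline(spec)
    } else {
      gr <- read_genotypes(cfg$genotypes_path, "tsv",
                           map_path = cfg$map_path)
      list(genotypes = gr$genotypes, locus_info = gr$locus_info,
           popmap = read_popmap(cfg$popmap_path), freq = NULL, spec = NULL)
    }
  })

  # --- filtering ------------------------------------------------------
  keep <- stage("filter", filter_monomorphic(dat$genotypes))
  say("monomorphic filter: %d / %d loci retained", length(keep),
      ncol(dat$genotypes))
  G <- dat$genotypes[, keep, drop = FALSE]

  # --- scoring --------------------------------------------------------
  scores <- stage("score",
    compute_score_matrix(G, dat$popmap, methods = cfg$methods,
                         mcmc = cfg$mcmc, seed = cfg$seed))
  write_scores(scores, file.path(cfg$out_dir, "scores.tsv"))

  # --- ranking / pruning / panels -------------------------------------
  ranking <- stage("rank", {
    r <- global_ranking(aggregate_scores(scores))
    if (cfg$min_cm > 0) {
      if (is.null(dat$locus_info))
        stop_config("pruning requires a genetic map")
      r <- ld_prune(r, dat$locus_info, min_cm = cfg$min_cm)
    } else {
      r$retained <- TRUE
      r$blocker <- NA_character_
    }
    r
  })
  write_ranking(ranking, file.path(cfg$out_dir, "ranking.tsv"))
  panels <- stage("panels", make_panels(ranking, cfg$panel_sizes))
  write_panels(panels, file.path(cfg$out_dir, "panels"))
  say("ranking: %d retained loci; panels %s", sum(ranking$retained),
      paste(cfg$panel_sizes, collapse = "/"))

  # --- reference frequencies (training estimates) ---------------------
  tr <- dat$popmap[dat$popmap$role == "training", ]
  refs <- stage("refs", allele_frequencies(
    G, list(M = tr$sample[tr$group == "M"],
            C = tr$sample[!tr$group %in% "M"])))
  p_m <- refs$p["M", ]; p_c <- refs$p["C", ]

  # --- validation sets ------------------------------------------------
  sets <- stage("simulate", {
    if (cfg$synthetic) {
      hold <- simulate_holdout(p_m, p_c, seed = cfg$seed + 101L)
      mix <- simulate_mixture(p_m, p_c, levels = cfg$mixture_levels,
                              n_per_level = cfg$mixture_n,
                              mode = cfg$mixture_mode,
                              seed = cfg$seed + 202L)
      write_genotypes(hold$genotypes,
                      file.path(cfg$out_dir, "holdout_genotypes.tsv"))
      write.table(hold$truth, file.path(cfg$out_dir, "holdout_truth.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(mix$truth, file.path(cfg$out_dir, "mixture_truth.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(holdout = hold, mixture = mix)
    } else {
      ho <- dat$popmap$sample[dat$popmap$role == "holdout"]
      list(holdout = list(genotypes = G[ho, , drop = FALSE], truth = NULL),
           mixture = NULL)
    }
  })

  # --- admixture per panel --------------------------------------------
  marker_sets <- c(panels, list(full = colnames(G)))
  admix <- stage("admix", lapply(c(holdout = "holdout", mixture = "mixture"),
    function(nm) {
      set <- sets[[nm]]
      if (is.null(set)) return(NULL)
      sapply(marker_sets, function(loci) {
        supervised_admixture(set$genotypes[, loci, drop = FALSE],
                             p_m[loci], p_c[loci], tol = cfg$eps)$q
      })
    }))
  for (nm in names(admix)) {
    if (is.null(admix[[nm]])) next
    write.table(data.frame(sample = rownames(sets[[nm]]$genotypes),
                           admix[[nm]], check.names = FALSE),
                file.path(cfg$out_dir, paste0("admixture_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (cfg$unsupervised) {
    fit <- stage("admix_unsupervised",
                 em_admixture(sets$holdout$genotypes, K = 2,
                              seed = cfg$seed + 303L, eps = cfg$eps))
    write_qmatrix(fit, file.path(cfg$out_dir, "holdout_K2.Q"))
  }

  # --- evaluation -----------------------------------------------------
  evaluation <- stage("evaluate", {
    out <- list()
    for (nm in names(admix)) {
      if (is.null(admix[[nm]])) next
      qs <- as.list(as.data.frame(admix[[nm]]))
      tru <- sets[[nm]]$truth
      tru_q <- if (is.null(tru)) NULL
        else if (all(is.na(tru$q_realized))) tru$q_true else tru$q_realized
      out[[nm]] <- evaluate_panels(qs, truth = tru_q)
      write.table(out[[nm]],
                  file.path(cfg$out_dir, paste0("evaluation_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    # protected vs unprotected introgression contrast on the holdout
    htru <- sets$holdout$truth
    if (!is.null(htru) && "group" %in% names(htru)) {
      qf <- admix$holdout[, "full"]
      prot <- qf[htru$group == "M-protected"]
      unprot <- qf[htru$group == "M-unprotected"]
      if (length(prot) > 1 && length(unprot) > 1)
        out$protection_contrast <- stats::t.test(unprot, prot)
    }
    out$correlations <- score_correlations(scores)
    out
  })

  # --- manifest -------------------------------------------------------
  cfg_out <- cfg
  cfg_out$mcmc <- unclass(cfg$mcmc)
  files <- sort(setdiff(list.files(cfg$out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "aimpanel",
    version = as.character(utils::packageVersion("aimpanel")),
    config = unclass(cfg_out),
    seed = cfg$seed,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(cfg$out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  say("pipeline complete: %s", cfg$out_dir)
  invisible(list(ranking = ranking, panels = panels, scores = scores,
                 refs = refs, sets = sets, admixture = admix,
                 evaluation = evaluation, out_dir = cfg$out_dir))
}
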