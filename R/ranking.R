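# Aggregation of the per-(method, dataset) score vectors into one global
# ranking, genetic-map pruning, and nested panel construction.  The order
# of operations matters and is fixed: dataset-mean per method first, then
# 0-1 standardization per method, then the unweighted method mean.

#' Average score vectors across training datasets, per method
#'
#' @param S long-format score matrix from [compute_score_matrix()].
#' @return Numeric matrix loci x methods of unweighted dataset means;
#'   flagged-missing (`NA`) cells are skipped, and a locus with no defined
#'   cell for a method stays `NA`.
#' @export
aggregate_scores <- function(S) {
  if (!all(c("locus", "method", "dataset", "value") %in% names(S)))
    stop_validation("score matrix needs columns locus, method, dataset, value")
  methods <- unique(S$method)
  loci <- unique(S$locus)
  out <- matrix(NA_real_, length(loci), length(methods),
                dimnames = list(loci, methods))
  for (m in methods) {
    sub <- S[S$method == m, , drop = FALSE]
    if (nrow(sub) == 0L) stop_config("method '%s' has zero datasets", m)
    w <- tapply(sub$value, sub$locus, mean, na.rm = TRUE)
    w[is.nan(w)] <- NA_real_
    out[names(w), m] <- w
  }
  out
}

#' Min-max standardization of a score vector to [0, 1]
#'
#' @param v numeric vector with at least 2 finite values.
#' @return `(v - min) / (max - min)`; a constant vector maps to all zeros
#'   with a warning; `NA`s are preserved.
#' @export
standardize_scores <- function(v) {
  fin <- is.finite(v)
  if (sum(fin) < 2L) stop_validation("need >= 2 finite values to standardize")
  lo <- min(v[fin]); hi <- max(v[fin])
  if (hi == lo) {
    warning("constant score vector; standardized to all zeros")
    out <- ifelse(fin, 0, NA_real_)
    names(out) <- names(v)
    return(out)
  }
  (v - lo) / (hi - lo)
}

#' Global 0-1 score and ranking of loci
#'
#' Standardizes each method's dataset-mean vector to `[0, 1]` and averages
#' across methods with equal weights (configurable).  Loci are ranked by
#' descending global score; exact ties are broken lexicographically by
#' locus id so the ranking is deterministic.
#'
#' @param M loci x methods matrix of dataset means (from
#'   [aggregate_scores()]), or an already-standardized matrix with
#'   `standardized = TRUE`.
#' @param weights optional named method weights (default uniform).
#' @param standardized set `TRUE` if `M` is already on the 0-1 scale.
#' @return A `global_ranking` data frame sorted by rank, with the
#'   per-method mean and standardized scores, `global` score, and `rank`.
#' @export
global_ranking <- function(M, weights = NULL, standardized = FALSE) {
  if (is.null(colnames(M))) stop_validation("M must have method column names")
  Z <- if (standardized) M else apply(M, 2L, standardize_scores)
  if (is.null(weights)) weights <- rep(1, ncol(M))
  if (!is.null(names(weights)) && all(colnames(M) %in% names(weights)))
    weights <- weights[colnames(M)]
  if (length(weights) != ncol(M))
    stop_config("need one weight per method")
  w <- weights / sum(weights)
  global <- as.numeric(Z %*% w)
  # with any NA cells, renormalize over the defined methods for that locus
  miss <- is.na(Z)
  if (any(miss)) {
    Z0 <- ifelse(miss, 0, Z)
    denom <- as.numeric((!miss) %*% w)
    global <- ifelse(denom > 0, as.numeric(Z0 %*% w) / denom, NA_real_)
  }
  ord <- order(-global, rownames(M), na.last = TRUE)
  out <- data.frame(locus = rownames(M)[ord],
                    M[ord, , drop = FALSE],
                    setNames(as.data.frame(Z[ord, , drop = FALSE]),
                             paste0(colnames(Z), "_std")),
                    global = global[ord],
                    rank = seq_len(nrow(M)),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("global_ranking", "data.frame")
  out
}

#' Prune ranked loci closer than a genetic-map distance
#'
#' Linked loci carry redundant ancestry information.  Scanning the ranking
#' from best to worst, a locus is excluded when it lies on the same
#' chromosome and strictly less than `min_cm` centimorgans from a
#' higher-ranking locus that was itself retained; excluded loci do not
#' block other loci.
#'
#' @param ranking `global_ranking` data frame.
#' @param info [locus_info()] data frame with map positions.
#' @param min_cm exclusion distance in cM (default 1; strict "<", so a
#'   locus at exactly `min_cm` is retained).
#' @param unmapped what to do with ranked loci absent from the map:
#'   `"retain"` (default; kept, never blocked, warn) or `"drop"`.
#' @return The ranking with logical column `retained` and character column
#'   `blocker` (the retained locus that excluded it, or `NA`).
#' @export
ld_prune <- function(ranking, info, min_cm = 1, unmapped = c("retain", "drop")) {
  unmapped <- match.arg(unmapped)
  idx <- match(ranking$locus, info$locus)
  if (anyNA(idx)) {
    if (unmapped == "drop") {
      ranking$retained <- !is.na(idx)
      ranking$blocker <- NA_character_
      ranking <- ranking[!is.na(idx), , drop = FALSE]
      idx <- idx[!is.na(idx)]
    } else {
      warning(sprintf("%d ranked loci have no map position; retaining them",
                      sum(is.na(idx))))
    }
  }
  chrom <- info$chrom[idx]
  cm <- info$cm[idx]
  n <- nrow(ranking)
  retained <- logical(n)
  blocker <- rep(NA_character_, n)
  kept_by_chrom <- list()
  for (i in seq_len(n)) {
    if (is.na(idx[i])) { retained[i] <- TRUE; next }   # unmapped, policy retain
    prev <- kept_by_chrom[[chrom[i]]]
    hit <- prev[abs(cm[prev] - cm[i]) < min_cm]
    if (length(hit)) {
      blocker[i] <- ranking$locus[hit[1L]]
    } else {
      retained[i] <- TRUE
      kept_by_chrom[[chrom[i]]] <- c(prev, i)
    }
  }
  ranking$retained <- retained
  ranking$blocker <- blocker
  ranking
}

#' Cut nested AIM panels from a pruned ranking
#'
#' @param ranking `global_ranking`, ideally with a `retained` column from
#'   [ld_prune()] (all loci are used if absent).
#' @param sizes panel sizes; defaults to the multiplex sizes of common
#'   commercial genotyping assays.
#' @return Named list (class `aim_panels`) of ordered locus-id vectors,
#'   `panel_48`, `panel_96`, ...; smaller panels are prefixes of larger
#'   ones by construction.
#' @export
make_panels <- function(ranking, sizes = c(48, 96, 144, 192, 384)) {
  pool <- if ("retained" %in% names(ranking))
    ranking$locus[ranking$retained] else ranking$locus
  sizes <- sort(as.integer(sizes))
  if (any(sizes < 1L)) stop_config("panel sizes must be >= 1")
  if (length(pool) < max(sizes))
    stop_config("only %d retained loci; cannot build a %d-marker panel (short by %d)",
                length(pool), max(sizes), max(sizes) - length(pool))
  out <- lapply(sizes, function(s) pool[seq_len(s)])
  names(out) <- paste0("panel_", sizes)
  class(out) <- "aim_panels"
  out
}

#' @export
print.aim_panels <- function(x, ...) {
  cat(sprintf("aim_panels: %s markers (nested)\n",
              paste(vapply(x, length, 1L), collapse = "/")))
  invisible(x)
}

#' Write ranking and panels to disk
#'
#' @param ranking `global_ranking` data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @param panels `aim_panels` list.
#' @param dir output directory; one `<name>.txt` locus list per panel.
#' @export
write_panels <- function(panels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(panels))
    writeLines(panels[[nm]], file.path(dir, paste0(nm, ".txt")))
  invisible(dir)
}
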