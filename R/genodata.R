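#' Construct a validated haploid genotype matrix
#'
#' The core data container of the package is a plain integer matrix with one
#' row per (haploid) individual and one column per biallelic locus.  Calls
#' are coded `0` (reference-type allele), `1` (alternate allele) or `NA`
#' (missing).  Honey bee drones are haploid males, so a single allele call
#' per locus is a complete genotype.
#'
#' @param calls matrix (or object coercible to one) of 0/1/`NA` calls,
#'   individuals in rows, loci in columns.
#' @param samples optional character vector of sample identifiers
#'   (defaults to existing rownames).
#' @param loci optional character vector of locus identifiers (defaults to
#'   existing colnames).
#' @return An integer matrix with unique row (sample) and column (locus)
#'   names, entries in `{0, 1, NA}`.
#' @examples
#' genotype_matrix(rbind(a = c(0, 1, NA), b = c(1, 1, 0)),
#'                 loci = c("L1", "L2", "L3"))
#' @export
genotype_matrix <- function(calls, samples = rownames(calls),
                            loci = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(samples)) samples <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(calls)))
  if (length(samples) != nrow(calls))
    stop_validation("%d sample ids for %d rows", length(samples), nrow(calls))
  if (length(loci) != ncol(calls))
    stop_validation("%d locus ids for %d columns", length(loci), ncol(calls))
  if (anyDuplicated(samples))
    stop_validation("duplicated sample identifiers: %s",
                    paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(loci))
    stop_validation("duplicated locus identifiers: %s",
                    paste(unique(loci[duplicated(loci)]), collapse = ", "))
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% c(0L, 1L))
  if (any(bad))
    stop_validation("genotype calls must be 0, 1 or NA; found %s",
                    paste(unique(calls[bad]), collapse = ", "))
  dimnames(calls) <- list(samples, loci)
  calls
}

#' Read haploid genotypes from TSV or PLINK-style ped/map files
#'
#' Two on-disk dialects are supported.  `tsv`: a header row of locus ids,
#' then one row per sample holding the sample id followed by 0/1/NA fields.
#' `pedmap`: a PLINK-style pair of files in which the `.map` file carries
#' chromosome, locus id, genetic position (cM) and (ignored) physical
#' position, and the `.ped` file stores each haploid genotype as a
#' duplicated allele pair ("1 1" -> 0, "2 2" -> 1, "0 0" -> missing).
#' Heterozygous pairs are rejected: the pipeline is haploid.
#'
#' @param path path to the genotype file (for `pedmap`, the `.ped` file).
#' @param format `"tsv"` or `"pedmap"`.
#' @param map_path optional path to the `.map` file (defaults to `path`
#'   with its extension replaced by `.map`) or, for `tsv`, to a genetic-map
#'   TSV read with [read_genetic_map()].
#' @return A list with elements `genotypes` (see [genotype_matrix()]) and
#'   `locus_info` (a data frame of locus, chromosome and cM position for
#'   `pedmap`/map input, otherwise `NULL`).
#' @seealso [write_genotypes()], [read_popmap()], [read_genetic_map()]
#' @export
read_genotypes <- function(path, format = c("tsv", "pedmap"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("genotype file not found: %s", path)
  if (format == "tsv") {
    lines <- readLines(path)
    if (length(lines) < 1L) stop_validation("empty genotype file: %s", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    loci <- fields[[1L]]
    want <- length(loci) + 1L
    rows <- fields[-1L]
    len <- lengths(rows)
    if (any(len != want))
      stop_validation("line %d of %s has %d fields, expected %d",
                      which(len != want)[1L] + 1L, path,
                      len[len != want][1L], want)
    samples <- vapply(rows, `[[`, "", 1L)
    calls <- matrix(NA_integer_, length(rows), length(loci))
    for (i in seq_along(rows)) {
      v <- rows[[i]][-1L]
      x <- suppressWarnings(as.integer(v))
      bad <- is.na(x) & v != "NA"
      if (any(bad))
        stop_validation("line %d of %s: unparseable call '%s'",
                        i + 1L, path, v[bad][1L])
      calls[i, ] <- x
    }
    info <- if (!is.null(map_path)) read_genetic_map(map_path) else NULL
    list(genotypes = genotype_matrix(calls, samples, loci), locus_info = info)
  } else {
    if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", path)
    if (!file.exists(map_path)) stop_config(".map file not found: %s", map_path)
    map <- read.table(map_path, header = FALSE, sep = "",
                      colClasses = c("character", "character",
                                     "numeric", "character"))
    names(map) <- c("chrom", "locus", "cm", "bp")
    info <- locus_info(map$locus, map$chrom, map$cm)
    lines <- readLines(path)
    fields <- strsplit(trimws(lines), "[ \t]+")
    want <- 6L + 2L * nrow(map)
    len <- lengths(fields)
    if (any(len != want))
      stop_validation("line %d of %s has %d fields, expected %d",
                      which(len != want)[1L], path, len[len != want][1L], want)
    samples <- vapply(fields, `[[`, "", 2L)
    calls <- matrix(NA_integer_, length(fields), nrow(map))
    for (i in seq_along(fields)) {
      g <- fields[[i]][-(1:6)]
      a1 <- g[c(TRUE, FALSE)]
      a2 <- g[c(FALSE, TRUE)]
      het <- a1 != a2 & a1 != "0" & a2 != "0"
      if (any(het))
        stop_validation("sample '%s': heterozygous call '%s %s' in haploid data",
                        samples[i], a1[het][1L], a2[het][1L])
      calls[i, ] <- ifelse(a1 == "0" | a2 == "0", NA_integer_,
                           ifelse(a1 == "2", 1L, 0L))
    }
    list(genotypes = genotype_matrix(calls, samples, map$locus),
         locus_info = info)
  }
}

#' Write a genotype matrix as TSV
#'
#' Inverse of [read_genotypes()] for the `tsv` dialect; reading a canonical
#' file and writing it back is byte-stable.
#'
#' @param G genotype matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  header <- paste(colnames(G), collapse = "\t")
  body <- vapply(seq_len(nrow(G)), function(i) {
    v <- G[i, ]
    paste(c(rownames(G)[i], ifelse(is.na(v), "NA", as.character(v))),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Locus annotation table
#'
#' @param locus character locus ids.
#' @param chrom chromosome labels (opaque strings).
#' @param cm genetic position in centimorgans (cM), non-negative.
#' @param ref,alt optional allele labels; "allele 1" throughout the package
#'   is `alt` in this table (all statistics are symmetric to the choice).
#' @return data frame with columns `locus`, `chrom`, `cm`, `ref`, `alt`.
#' @export
locus_info <- function(locus, chrom, cm, ref = NA_character_,
                       alt = NA_character_) {
  if (anyDuplicated(locus))
    stop_validation("duplicated locus ids in locus_info")
  if (any(cm < 0, na.rm = TRUE))
    stop_validation("genetic positions (cM) must be >= 0")
  data.frame(locus = as.character(locus), chrom = as.character(chrom),
             cm = as.numeric(cm), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Read a genetic map TSV (locus, chrom, cm)
#'
#' @param path TSV with header columns `locus`, `chrom`, `cm`.
#' @return A [locus_info()] data frame.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop_config("genetic map not found: %s", path)
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("locus", "chrom", "cm")
  if (!all(need %in% names(d)))
    stop_validation("genetic map %s must have columns %s", path,
                    paste(need, collapse = ", "))
  locus_info(d$locus, d$chrom, d$cm)
}

#' Read a population map TSV
#'
#' Columns: `sample`, `population`, `role` (training/holdout) and `group`
#' (`M`, `C-ligustica`, `C-carnica` or other labels).
#'
#' @param path TSV path.
#' @return data frame with those four character columns.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop_config("population map not found: %s", path)
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "population", "role", "group")
  if (!all(need %in% names(d)))
    stop_validation("population map %s must have columns %s", path,
                    paste(need, collapse = ", "))
  bad <- !d$role %in% c("training", "holdout")
  if (any(bad))
    stop_validation("unknown role '%s' in population map", d$role[bad][1L])
  d[need]
}

#' Write a population map TSV
#' @param pm population map data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  write.table(pm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-population allele-1 frequencies
#'
#' Computes, for each population and locus, the frequency of allele 1 among
#' non-missing calls together with the haploid count of non-missing calls.
#' A locus with no non-missing calls in a population has `NA` frequency and
#' `n = 0`.  Diploid input (calls 0/1/2 = alternate-allele dosage) is
#' accepted as an extension by setting `ploidy = 2`; the core pipeline is
#' haploid.
#'
#' @param G genotype matrix.
#' @param populations named list mapping population label to a character
#'   vector of sample ids, or `NULL` to pool every sample into a single
#'   population `"all"`.
#' @param ploidy 1 (default, haploid) or 2.
#' @return An object of class `freq_table`: a list with matrices `p`
#'   (populations x loci, allele-1 frequency) and `n` (haploid counts of
#'   non-missing calls, i.e. allele draws).
#' @examples
#' G <- genotype_matrix(rbind(a = c(1, 0), b = c(1, 1), c = c(0, NA)))
#' allele_frequencies(G, list(P = c("a", "b", "c")))
#' @export
allele_frequencies <- function(G, populations = NULL, ploidy = 1) {
  if (is.null(populations)) populations <- list(all = rownames(G))
  if (is.null(names(populations)) || any(names(populations) == ""))
    stop_config("populations must be a named list")
  p <- matrix(NA_real_, length(populations), ncol(G),
              dimnames = list(names(populations), colnames(G)))
  n <- matrix(0L, length(populations), ncol(G),
              dimnames = dimnames(p))
  for (k in seq_along(populations)) {
    ids <- populations[[k]]
    missing_ids <- setdiff(ids, rownames(G))
    if (length(missing_ids))
      stop_validation("population '%s': sample(s) not in genotype matrix: %s",
                      names(populations)[k],
                      paste(head(missing_ids, 3L), collapse = ", "))
    if (length(ids) < 1L)
      stop_config("population '%s' has no samples", names(populations)[k])
    sub <- G[ids, , drop = FALSE]
    nn <- colSums(!is.na(sub)) * ploidy
    tot <- colSums(sub, na.rm = TRUE)
    p[k, ] <- ifelse(nn > 0, tot / nn, NA_real_)
    n[k, ] <- as.integer(nn)
  }
  structure(list(p = p, n = n), class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d population(s) x %d loci\n",
              nrow(x$p), ncol(x$p)))
  invisible(x)
}

#' Filter monomorphic and near-monomorphic loci
#'
#' A locus is removed when the frequency of its most common allele, pooled
#' over all samples, is strictly greater than `cutoff` (default 0.98, i.e.
#' loci that are monomorphic or nearly so across all populations).
#'
#' @param x a pooled (single-population) `freq_table` or a genotype matrix
#'   (pooled internally).
#' @param cutoff major-allele frequency cutoff, in `(0.5, 1]`; strict ">"
#'   comparison, so a locus at exactly the cutoff is retained.
#' @return Character vector of retained locus ids, in input order.  Loci
#'   with no data (all missing) are removed.
#' @export
filter_monomorphic <- function(x, cutoff = 0.98) {
  if (cutoff <= 0.5 || cutoff > 1)
    stop_config("cutoff must be in (0.5, 1], got %g", cutoff)
  if (inherits(x, "freq_table")) {
    if (nrow(x$p) != 1L) {
      num <- colSums(ifelse(x$n > 0, x$p, 0) * x$n)
      den <- colSums(x$n)
      p <- ifelse(den > 0, num / den, NA_real_)
    } else {
      p <- x$p[1L, ]
    }
    loci <- colnames(x$p)
  } else {
    ft <- allele_frequencies(x)
    p <- ft$p[1L, ]
    loci <- colnames(ft$p)
  }
  major <- pmax(p, 1 - p)
  keep <- !is.na(major) & major <= cutoff
  loci[keep]
}

#' Build the four training datasets (population groupings I-IV)
#'
#' Marker informativeness is scored under four groupings of the training
#' samples, to average out the effect of how reference populations are
#' clustered: I = M vs the two C-lineage subspecies pooled as one
#' population; II = M vs ligustica; III = M vs carnica; IV = M, ligustica
#' and carnica as three populations.
#'
#' @param pm population map (see [read_popmap()]); only `role == "training"`
#'   samples are used, and `group` must label them `M`, `C-ligustica` or
#'   `C-carnica`.
#' @param datasets subset of `c("I","II","III","IV")` to build.
#' @return Named list of datasets; each dataset is a named list of
#'   population -> sample-id vectors, suitable for [allele_frequencies()].
#' @export
build_training_datasets <- function(pm, datasets = c("I", "II", "III", "IV")) {
  datasets <- match.arg(datasets, several.ok = TRUE)
  tr <- pm[pm$role == "training", , drop = FALSE]
  m <- tr$sample[tr$group == "M"]
  lig <- tr$sample[tr$group == "C-ligustica"]
  car <- tr$sample[tr$group == "C-carnica"]
  need <- list(I = c(m = TRUE, lig = TRUE, car = TRUE),
               II = c(m = TRUE, lig = TRUE, car = FALSE),
               III = c(m = TRUE, lig = FALSE, car = TRUE),
               IV = c(m = TRUE, lig = TRUE, car = TRUE))
  out <- list()
  for (d in datasets) {
    req <- need[[d]]
    if (req["m"] && length(m) == 0L)
      stop_config("dataset %s: no training samples in group M", d)
    if (req["lig"] && length(lig) == 0L)
      stop_config("dataset %s: no training samples in group C-ligustica", d)
    if (req["car"] && length(car) == 0L)
      stop_config("dataset %s: no training samples in group C-carnica", d)
    out[[d]] <- switch(d,
      I = list(M = m, C = c(lig, car)),
      II = list(M = m, `C-ligustica` = lig),
      III = list(M = m, `C-carnica` = car),
      IV = list(M = m, `C-ligustica` = lig, `C-carnica` = car))
  }
  out
}
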