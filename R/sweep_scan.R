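#' Top-quantile windows of a score track
#'
#' Selects the windows whose score falls in the upper tail of the empirical
#' distribution: with `n` defined windows and quantile `q`, the threshold is
#' the `ceiling(q * n)`-th largest defined score and every window scoring at
#' or above it is returned (ties at the threshold are all included, so the
#' selection can only grow beyond `ceiling(q * n)`). Undefined windows are
#' excluded from both the ranking and the denominator. The candidate-region
#' procedure of the study design uses `q = 0.03` on each of two independent
#' scans.
#'
#' @param track a window track data frame with `chrom`, `start`, `end`, a
#'   score column and (optionally) a logical `defined` column; e.g. a
#'   `pbs_track` or the output of [window_max_score].
#' @param q upper-tail fraction in `[0, 1]` (`q = 0` gives an empty set,
#'   `q = 1` all defined windows).
#' @param score_col name of the score column (default `"pbs"`, falling back
#'   to `"score"`).
#' @return an [interval_set] (merged) of the selected windows.
#' @export
top_quantile_windows <- function(track, q, score_col = NULL) {
  stopifnot(q >= 0, q <= 1)
  if (is.null(score_col))
    score_col <- intersect(c("pbs", "score", "fst"), names(track))[1]
  if (is.na(score_col) || is.null(track[[score_col]]))
    stop("no score column found in track")
  defined <- if (!is.null(track$defined)) track$defined
             else !is.na(track[[score_col]])
  defined <- defined & !is.na(track[[score_col]])
  if (!any(defined)) stop("all windows are undefined")
  scores <- track[[score_col]][defined]
  k <- ceiling(q * length(scores))
  if (k == 0)
    return(interval_set("top_windows", character(0), numeric(0), numeric(0)))
  threshold <- sort(scores, decreasing = TRUE)[k]
  sel <- defined & track[[score_col]] >= threshold
  interval_set("top_windows", track$chrom[sel], track$start[sel],
               track$end[sel])
}

#' Gridify a per-position score track
#'
#' Maps an ingested per-position sweep-score track (e.g. composite-likelihood
#' ratios) onto a window grid, so the two scans of the dual-scan procedure
#' rank comparable units. Each window's score is the aggregate (default: max)
#' of the positions it contains; windows containing no scored position are
#' undefined.
#'
#' @param score_track data frame from [read_score_track].
#' @param grid a [window_grid].
#' @param agg aggregation function over the positions in a window.
#' @return window track data frame with `chrom`, `start`, `end`, `score`,
#'   `n_pos`, `defined`.
#' @export
window_max_score <- function(score_track, grid, agg = max) {
  wins <- tile_windows(grid)
  wins$score <- NA_real_
  wins$n_pos <- 0L
  for (ch in unique(wins$chrom)) {
    wi <- which(wins$chrom == ch)
    st <- score_track[score_track$chrom == ch, , drop = FALSE]
    if (!nrow(st)) next
    for (w in wi) {
      inw <- st$pos >= wins$start[w] & st$pos < wins$end[w]
      wins$n_pos[w] <- sum(inw)
      if (any(inw)) wins$score[w] <- agg(st$score[inw])
    }
  }
  wins$defined <- wins$n_pos > 0L
  wins
}

#' Intersect two candidate-window sets and merge the result
#'
#' Base-pair-level intersection of two interval sets (e.g. the top 3% of a
#' PBS scan and the top 3% of an independent composite-likelihood sweep
#' scan), with adjacent or overlapping output intervals merged. The covered
#' length and, when chromosome lengths are supplied, the genome fraction are
#' reported — the study design summarises its candidate set as a fraction of
#' the whole genome.
#'
#' @param a,b [interval_set]s on the same genome.
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   given, `genome_fraction = covered / sum(chrom_lengths)`.
#' @return object of class `candidate_regions`: list with `regions` (a
#'   merged [interval_set]), `covered` (bp) and `genome_fraction` (or `NA`).
#' @export
intersect_and_merge <- function(a, b, chrom_lengths = NULL) {
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"))
  ca <- unique(as.character(GenomicRanges::seqnames(a$gr)))
  cb <- unique(as.character(GenomicRanges::seqnames(b$gr)))
  if (length(ca) && length(cb) && !length(intersect(ca, cb)))
    stop("mismatched chromosome namespaces: '",
         paste(ca, collapse = ","), "' vs '", paste(cb, collapse = ","), "'")
  ga <- GenomicRanges::reduce(a$gr)
  gb <- GenomicRanges::reduce(b$gr)
  suppressWarnings(
    gi <- GenomicRanges::reduce(GenomicRanges::intersect(ga, gb,
                                                         ignore.strand = TRUE)))
  regions <- iset_from_granges("candidate_regions", gi, merged = TRUE)
  covered <- total_width(regions)
  structure(list(regions = regions, covered = covered,
                 genome_fraction = if (is.null(chrom_lengths)) NA_real_
                                   else covered / sum(chrom_lengths)),
            class = "candidate_regions")
}

#' @export
print.candidate_regions <- function(x, ...) {
  cat("candidate_regions:", length(x$regions), "merged intervals,",
      x$covered, "bp covered")
  if (!is.na(x$genome_fraction))
    cat(sprintf(" (%.3f%% of the genome)", 100 * x$genome_fraction))
  cat("\n")
  invisible(x)
}

#' Genes overlapping candidate regions
#'
#' Ids of genes whose interval overlaps any candidate region by at least one
#' base pair, deduplicated and sorted.
#'
#' @param regions a `candidate_regions` object or an [interval_set].
#' @param genes an [interval_set] with per-interval ids (a gene annotation).
#' @return sorted character vector of gene ids.
#' @export
genes_in_regions <- function(regions, genes) {
  if (inherits(regions, "candidate_regions")) regions <- regions$regions
  stopifnot(inherits(genes, "interval_set"))
  ids <- S4Vectors::mcols(genes$gr)$id
  if (is.null(ids)) stop("gene intervals must carry ids")
  hits <- GenomicRanges::findOverlaps(genes$gr, regions$gr,
                                      ignore.strand = TRUE)
  sort(unique(ids[S4Vectors::queryHits(hits)]))
}

#' Overlap candidate genes with curated trait gene lists
#'
#' Intersects a candidate gene set with one or more named reference lists
#' (e.g. tooth-development pathway genes, pigmentation genes) and reports the
#' intersection and its size per list. When a universe size is supplied, a
#' hypergeometric enrichment p-value is added; this is a plain
#' `stats::phyper` tail test on user-supplied lists, not the modified Fisher
#' statistic of external GO services.
#'
#' @param gene_ids character vector of candidate gene ids.
#' @param gene_lists named list of character vectors.
#' @param universe optional total number of genes in the annotation.
#' @return data frame with `list`, `n_ref`, `n_overlap`, `genes`
#'   (comma-separated) and, with `universe`, `p_hyper`.
#' @export
candidate_gene_pathway_overlap <- function(gene_ids, gene_lists,
                                           universe = NULL) {
  stopifnot(is.list(gene_lists), !is.null(names(gene_lists)))
  gene_ids <- unique(gene_ids)
  rows <- lapply(names(gene_lists), function(nm) {
    ref <- unique(gene_lists[[nm]])
    if (!length(ref))
      warning("reference list '", nm, "' is empty")
    ov <- sort(intersect(gene_ids, ref))
    data.frame(list = nm, n_ref = length(ref), n_overlap = length(ov),
               genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(universe)) {
    out$p_hyper <- stats::phyper(out$n_overlap - 1, out$n_ref,
                                 universe - out$n_ref,
                                 length(gene_ids), lower.tail = FALSE)
  }
  out
}
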