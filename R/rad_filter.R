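#' Annotation-distance filtering of RAD loci
#'
#' Applies the neutrality filters of the locus-selection cascade to loci that
#' are still passing. A locus is rejected when its (trimmed) interval
#' overlaps a CpG island, repeat or assembly-gap interval by at least 1 bp;
#' when its distance to the nearest exon is below `cfg$exon_dist`
#' ("at least 10 kb from exons": a locus exactly 10 kb away passes); or when
#' its distance to the nearest conserved noncoding element is at or below
#' `cfg$cne_dist` ("more than 100 bp away": a locus exactly 100 bp away is
#' rejected). Distance is the gap between closest interval ends on the
#' 0-based half-open system, 0 when overlapping or abutting. Absent tracks
#' impose no constraint. The five predicates are independent; rejection
#' reasons are assigned in the fixed order cpg, repeat, gap, exon, cne.
#'
#' @param loci a `rad_loci` data frame from [extract_loci].
#' @param tracks named list of [interval_set]s; allowed names: `cpg`,
#'   `repeat`, `gap`, `exon`, `cne` (any subset).
#' @param cfg a [digest_config].
#' @return the loci with updated `status`/`reason`.
#' @export
filter_by_annotation <- function(loci, tracks, cfg = digest_config()) {
  allowed <- c("cpg", "repeat", "gap", "exon", "cne")
  bad <- setdiff(names(tracks), allowed)
  if (length(bad))
    stop("unknown track name(s): ", paste(bad, collapse = ", "))
  live <- which(loci$status == "pass")
  if (!length(live)) return(loci)
  lg <- GenomicRanges::GRanges(loci$chrom[live],
                               IRanges::IRanges(loci$locus_start[live] + 1,
                                                loci$locus_end[live]))
  reject <- function(idx, why) {
    loci$status[live[idx]] <<- "rejected"
    loci$reason[live[idx]] <<- why
  }
  for (nm in c("cpg", "repeat", "gap")) {
    if (is.null(tracks[[nm]])) next
    ov <- IRanges::overlapsAny(lg, tracks[[nm]]$gr, ignore.strand = TRUE)
    hit <- ov & loci$status[live] == "pass"
    reject(which(hit), nm)
  }
  if (!is.null(tracks$exon)) {
    d <- track_distance(lg, tracks$exon$gr)
    hit <- !is.na(d) & d < cfg$exon_dist & loci$status[live] == "pass"
    reject(which(hit), "exon")
  }
  if (!is.null(tracks$cne)) {
    d <- track_distance(lg, tracks$cne$gr)
    hit <- !is.na(d) & d <= cfg$cne_dist & loci$status[live] == "pass"
    reject(which(hit), "cne")
  }
  loci
}

# distance in bp from each query range to the nearest subject range on the
# same chromosome; NA when the chromosome carries no subject interval
track_distance <- function(query, subject) {
  suppressWarnings(
    d <- GenomicRanges::distanceToNearest(query, subject,
                                          ignore.strand = TRUE))
  out <- rep(NA_real_, length(query))
  out[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  out
}

#' Per-individual coverage filtering of RAD loci
#'
#' A locus passes only if every base of both full (untrimmed) flanks has
#' read depth of at least `cfg$min_depth` in every listed sample — the
#' "sequenced at least five times in each individual" rule, with the bound
#' inclusive. Positions absent from the depth table count as depth 0.
#'
#' @param loci a `rad_loci` data frame.
#' @param depth_table data frame with columns `chrom`, `pos` (0-based) and
#'   one numeric depth column per sample (see [make_depth_table]).
#' @param samples sample names that must satisfy the rule; all must be
#'   columns of `depth_table`.
#' @param cfg a [digest_config].
#' @return the loci with updated `status`/`reason` (`"coverage"`).
#' @export
filter_by_coverage <- function(loci, depth_table, samples,
                               cfg = digest_config()) {
  missing_s <- setdiff(samples, names(depth_table))
  if (length(missing_s))
    stop("sample(s) missing from depth table: ",
         paste(missing_s, collapse = ", "))
  ml <- nchar(cfg$motif)
  live <- which(loci$status == "pass")
  for (i in live) {
    fs <- loci$cut_site[i] - cfg$flank
    fe <- loci$cut_site[i] + ml + cfg$flank
    flank_pos <- c(seq(fs, loci$cut_site[i] - 1),
                   seq(loci$cut_site[i] + ml, fe - 1))
    dt <- depth_table[depth_table$chrom == loci$chrom[i] &
                        depth_table$pos %in% flank_pos, , drop = FALSE]
    ok <- nrow(dt) == length(flank_pos) &&
      all(as.matrix(dt[, samples, drop = FALSE]) >= cfg$min_depth)
    if (!ok) {
      loci$status[i] <- "rejected"
      loci$reason[i] <- "coverage"
    }
  }
  loci
}

#' Thin loci to a minimum spacing
#'
#' Greedy left-to-right walk per chromosome over the still-passing loci:
#' a locus is kept if its cut site is at least `spacing` bp from the last
#' kept cut site on that chromosome, otherwise rejected with reason
#' `"spacing"`. The greedy walk guarantees the independence property the
#' downstream coalescent sampler needs — no two retained loci closer than
#' the spacing — which fixed-bin subsampling does not. Thinning runs last in
#' the pipeline so that loci rejected by earlier filters cannot shadow a
#' passing neighbour.
#'
#' @param loci a `rad_loci` data frame sorted by `(chrom, cut_site)`.
#' @param spacing minimum distance between kept cut sites, bp.
#' @return the loci with updated `status`/`reason`.
#' @export
thin_loci <- function(loci, spacing = 100000) {
  o <- order(loci$chrom, loci$cut_site)
  last_kept <- list()
  for (i in o) {
    if (loci$status[i] != "pass") next
    ch <- loci$chrom[i]
    lk <- last_kept[[ch]]
    if (!is.null(lk) && loci$cut_site[i] - lk < spacing) {
      loci$status[i] <- "rejected"
      loci$reason[i] <- "spacing"
    } else {
      last_kept[[ch]] <- loci$cut_site[i]
    }
  }
  loci
}

#' Run the full locus-selection cascade
#'
#' Fixed pipeline order: digest, extract, annotation filters, coverage
#' filter, spacing thinning.
#'
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param tracks named list of annotation [interval_set]s (see
#'   [filter_by_annotation]).
#' @param depth_table,samples optional coverage filter inputs (both or
#'   neither; see [filter_by_coverage]).
#' @param cfg a [digest_config].
#' @return a `rad_loci` data frame with terminal statuses.
#' @export
rad_pipeline <- function(genome, tracks = list(), depth_table = NULL,
                         samples = NULL, cfg = digest_config()) {
  genome <- load_genome(genome)
  sites <- find_cut_sites(genome, cfg$motif)
  loci <- extract_loci(genome, sites, cfg)
  loci <- filter_by_annotation(loci, tracks, cfg)
  if (!is.null(depth_table))
    loci <- filter_by_coverage(loci, depth_table, samples, cfg)
  loci <- thin_loci(loci, cfg$spacing)
  loci
}

#' Export the locus-selection results
#'
#' Writes a FASTA of the passing locus sequences, a BED of their (trimmed)
#' intervals and a TSV audit table with one row per digested site and its
#' terminal status, then reports the counts per rejection reason.
#'
#' @param loci a `rad_loci` data frame with final statuses.
#' @param prefix output path prefix; writes `<prefix>.fa`, `<prefix>.bed`,
#'   `<prefix>_audit.tsv`.
#' @return named list of output paths and the per-reason counts, invisibly.
#' @export
export_loci <- function(loci, prefix) {
  pass <- loci[loci$status == "pass", , drop = FALSE]
  fa <- paste0(prefix, ".fa")
  bed <- paste0(prefix, ".bed")
  audit <- paste0(prefix, "_audit.tsv")
  fa_lines <- if (nrow(pass))
    as.vector(rbind(sprintf(">%s_%d", pass$chrom, pass$cut_site),
                    pass$sequence)) else character(0)
  writeLines(fa_lines, fa)
  write.table(pass[, c("chrom", "locus_start", "locus_end")], bed,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(loci[, c("chrom", "cut_site", "locus_start", "locus_end",
                       "status", "reason")],
              audit, sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- table(ifelse(loci$status == "pass", "pass", loci$reason))
  message("export_loci: ", nrow(pass), "/", nrow(loci), " loci pass (",
          paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                collapse = ", "), ")")
  invisible(list(fasta = fa, bed = bed, audit = audit, counts = counts))
}
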