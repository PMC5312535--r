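#' Restriction-digest and locus-selection configuration
#'
#' Bundles every constant of the neutral-locus selection cascade. The
#' defaults are the study design's: the SpeI recognition motif `ACTAGT`
#' (a palindromic 6-mer), 100 bp flanks joined around the motif with 3 bp
#' trimmed from each end (yielding 200 bp loci), a per-individual depth floor
#' of 5x over both flanks, at least 10 kb from exons (inclusive), more than
#' 100 bp from conserved noncoding elements (exclusive), and one locus every
#' 100 kb.
#'
#' @param motif recognition sequence over `{A, C, G, T}`.
#' @param flank flank length on each side of the motif, bp.
#' @param trim bases trimmed from each end of the joined sequence.
#' @param min_depth minimum per-base per-sample depth over the flanks.
#' @param exon_dist minimum distance to the nearest exon, bp (locus passes at
#'   exactly this distance).
#' @param cne_dist distance to the nearest conserved noncoding element at or
#'   below which the locus is rejected (locus passes strictly beyond it).
#' @param spacing minimum distance between retained cut sites, bp.
#' @return object of class `digest_config`.
#' @export
digest_config <- function(motif = "ACTAGT", flank = 100, trim = 3,
                          min_depth = 5, exon_dist = 10000, cne_dist = 100,
                          spacing = 100000) {
  motif <- toupper(motif)
  stopifnot(grepl("^[ACGT]+$", motif), flank > 0, trim >= 0, min_depth >= 0,
            exon_dist >= 0, cne_dist >= 0, spacing > 0,
            2 * trim < 2 * flank + nchar(motif))
  structure(list(motif = motif, flank = flank, trim = trim,
                 min_depth = min_depth, exon_dist = exon_dist,
                 cne_dist = cne_dist, spacing = spacing,
                 locus_length = 2 * flank + nchar(motif) - 2 * trim),
            class = "digest_config")
}

#' In-silico restriction digest of a genome
#'
#' All 0-based start positions of exact occurrences of the recognition motif
#' on the forward strand of each sequence. Positions containing ambiguity
#' codes (N) never match. For palindromic motifs such as SpeI's `ACTAGT` the
#' forward-strand scan already covers both strands.
#'
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param motif recognition sequence (default SpeI).
#' @return data frame with `chrom` and `pos` (0-based motif start), in genome
#'   order.
#' @export
find_cut_sites <- function(genome, motif = "ACTAGT") {
  genome <- load_genome(genome)
  if (!length(genome) || all(Biostrings::width(genome) == 0))
    stop("empty genome")
  motif <- Biostrings::DNAString(toupper(motif))
  hits <- Biostrings::vmatchPattern(motif, genome, fixed = TRUE)
  out <- lapply(seq_along(genome), function(i) {
    st <- Biostrings::start(hits[[i]])
    if (!length(st)) return(NULL)
    data.frame(chrom = names(genome)[i], pos = st - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(0), pos = integer(0))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

load_genome <- function(genome) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

#' Extract joined-flank loci at cut sites
#'
#' For each cut site, joins the upstream flank, the motif and the downstream
#' flank, then trims `cfg$trim` bases from each end, yielding loci of
#' `2*flank + motif - 2*trim` bp (200 bp at the defaults). A locus is
#' rejected with reason `"edge"` when either full (untrimmed) flank extends
#' past the contig boundary or the footprint overlaps an N run; rejection is
#' a status, never an error.
#'
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param sites data frame from [find_cut_sites].
#' @param cfg a [digest_config].
#' @return object of class `rad_loci`: data frame with `chrom`, `cut_site`,
#'   `locus_start`, `locus_end` (0-based half-open, trimmed), `sequence`
#'   (`NA` when rejected), `status` (`"pass"` or `"edge"`), `reason`.
#' @export
extract_loci <- function(genome, sites, cfg = digest_config()) {
  genome <- load_genome(genome)
  ml <- nchar(cfg$motif)
  n <- nrow(sites)
  seqs <- rep(NA_character_, n)
  status <- rep("pass", n); reason <- rep(NA_character_, n)
  lens <- setNames(Biostrings::width(genome), names(genome))
  foot_start <- sites$pos - cfg$flank             # untrimmed footprint
  foot_end <- sites$pos + ml + cfg$flank
  locus_start <- foot_start + cfg$trim
  locus_end <- foot_end - cfg$trim
  for (i in seq_len(n)) {
    ch <- sites$chrom[i]
    if (foot_start[i] < 0 || foot_end[i] > lens[[ch]]) {
      status[i] <- "rejected"; reason[i] <- "edge"; next
    }
    s <- as.character(Biostrings::subseq(genome[[ch]],
                                         foot_start[i] + 1L, foot_end[i]))
    if (grepl("[^ACGT]", s)) {
      status[i] <- "rejected"; reason[i] <- "edge"; next
    }
    seqs[i] <- substr(s, cfg$trim + 1L, nchar(s) - cfg$trim)
  }
  structure(data.frame(chrom = sites$chrom, cut_site = sites$pos,
                       locus_start = locus_start, locus_end = locus_end,
                       sequence = seqs, status = status, reason = reason,
                       stringsAsFactors = FALSE),
            class = c("rad_loci", "data.frame"), cfg = cfg)
}
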