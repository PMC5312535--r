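#' Read a multi-sample VCF into a genotype panel
#'
#' Parses GT (and per-sample DP when present) from a VCF 4.x file, keeps
#' biallelic SNPs only, converts positions to the internal 0-based convention
#' and attaches population labels. Multi-allelic and non-SNP records are
#' dropped, not split, and their count is reported in a message: every
#' downstream statistic is defined on biallelic SNPs. Missing genotypes
#' (`./.`) become `NA`.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param pop_map named character vector mapping sample id to population name.
#' @param on_unmapped what to do with VCF samples absent from `pop_map`:
#'   `"fail"` (default) or `"drop"`.
#' @return a [genotype_panel] (with `depth` when the VCF carries DP).
#' @export
read_vcf <- function(path, pop_map, on_unmapped = c("fail", "drop")) {
  on_unmapped <- match.arg(on_unmapped)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!is_snp)
  if (n_drop > 0)
    message("read_vcf: dropped ", n_drop, " multi-allelic/non-SNP record(s)")
  v <- v[is_snp, ]
  fix <- fix[is_snp, , drop = FALSE]

  samples <- colnames(v@gt)[-1]
  unmapped <- setdiff(samples, names(pop_map))
  if (length(unmapped)) {
    if (on_unmapped == "fail")
      stop("samples absent from pop_map: ", paste(unmapped, collapse = ", "))
    samples <- setdiff(samples, unmapped)
    if (!length(samples)) stop("no samples left after dropping unmapped ones")
  }

  gt <- vcfR::extract.gt(v, element = "GT")[, samples, drop = FALSE]
  alt_count <- function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
    vapply(a, function(x) {
      if (any(x == "." | is.na(x))) return(NA_integer_)
      sum(as.integer(x))
    }, integer(1))
  }
  geno <- matrix(alt_count(as.vector(gt)), nrow = nrow(gt),
                 dimnames = list(NULL, colnames(gt)))

  depth <- NULL
  if (any(grepl("DP", v@gt[, "FORMAT"]))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    depth <- dp[, samples, drop = FALSE]
    dimnames(depth) <- list(NULL, samples)
  }

  genotype_panel(samples, pop_map[samples],
                 chrom = fix[, "CHROM"],
                 pos = as.integer(fix[, "POS"]) - 1L,
                 ref = fix[, "REF"], alt = fix[, "ALT"],
                 geno = geno, depth = depth)
}

#' Read an annotation track from BED or GFF3
#'
#' BED is 0-based half-open and taken as-is; GFF3 is 1-based inclusive and
#' converted at this boundary, so the same physical interval read from either
#' encoding compares equal. Overlapping intervals are merged within a track
#' unless ids are kept (e.g. for gene tracks).
#'
#' @param path file path.
#' @param format `"bed"` or `"gff3"` — declared explicitly, never guessed.
#' @param name track label (see [interval_set]).
#' @param keep_ids keep per-interval identifiers (BED column 4 / GFF3 `ID=` or
#'   `Name=` attribute) and skip merging. Defaults to `TRUE` for `"gene"`
#'   tracks.
#' @param feature_type for GFF3, restrict to this `type` column value
#'   (`NULL` = all rows).
#' @return an [interval_set].
#' @export
read_intervals <- function(path, format = c("bed", "gff3"), name = "custom",
                           keep_ids = identical(name, "gene"),
                           feature_type = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop("no intervals in ", path)
  if (format == "bed") {
    f <- strsplit(lines, "\t")
    chrom <- vapply(f, `[`, "", 1L)
    start <- as.numeric(vapply(f, `[`, "", 2L))
    end <- as.numeric(vapply(f, `[`, "", 3L))
    id <- if (keep_ids && all(lengths(f) >= 4L)) vapply(f, `[`, "", 4L)
  } else {
    f <- strsplit(lines, "\t")
    if (any(lengths(f) < 9L)) stop("malformed GFF3: fewer than 9 columns")
    type <- vapply(f, `[`, "", 3L)
    keep <- if (is.null(feature_type)) rep(TRUE, length(f))
            else type == feature_type
    f <- f[keep]
    if (!length(f)) stop("no GFF3 rows of type '", feature_type, "'")
    chrom <- vapply(f, `[`, "", 1L)
    start <- as.numeric(vapply(f, `[`, "", 4L)) - 1  # 1-based -> 0-based
    end <- as.numeric(vapply(f, `[`, "", 5L))        # inclusive -> half-open
    id <- if (keep_ids) {
      attr9 <- vapply(f, `[`, "", 9L)
      m <- regmatches(attr9, regexpr("(ID|Name)=[^;]+", attr9))
      gsub("^(ID|Name)=", "", m)
    }
  }
  if (any(start >= end))
    stop("interval with start >= end after coordinate conversion in ", path)
  interval_set(name, chrom, start, end,
               id = if (keep_ids) id, merge = !keep_ids)
}

#' Read a per-position sweep-score track
#'
#' Ingests the tab-delimited two-column dialect written by composite-likelihood
#' sweep scanners: a header line, a position column (`position` or
#' `location`), and a likelihood-ratio column (`LR`, `likelihood_ratio` or
#' `score`). Extra columns (e.g. `alpha`) are ignored. Rows are sorted by
#' position, with a warning if the input was unsorted.
#'
#' @param path file path.
#' @param chrom chromosome the track belongs to (single-chromosome files, as
#'   emitted by the scanner); recycled into the output.
#' @return a `score_track` data frame with columns `chrom`, `pos`, `score`
#'   and attribute `kind = "clr"`.
#' @export
read_score_track <- function(path, chrom = "chr1") {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(tab))
  pc <- which(nm %in% c("position", "location", "pos"))[1]
  sc <- which(nm %in% c("lr", "likelihood_ratio", "likelihood.ratio",
                        "score"))[1]
  if (is.na(pc) || is.na(sc))
    stop("score track needs a position and a likelihood-ratio column")
  pos <- tab[[pc]]; score <- tab[[sc]]
  if (!is.numeric(pos) || !is.numeric(score))
    stop("non-numeric position or score column")
  if (any(!is.finite(score))) stop("non-finite scores in ", path)
  if (is.unsorted(pos)) {
    warning("score track positions were unsorted; sorting")
    o <- order(pos); pos <- pos[o]; score <- score[o]
  }
  structure(data.frame(chrom = chrom, pos = pos, score = score,
                       stringsAsFactors = FALSE),
            kind = "clr", class = c("score_track", "data.frame"))
}

#' Read and pool coalescent-sampler MCMC trace files
#'
#' Reads one or more tab-delimited trace files (one row per retained MCMC
#' sample, one column per parameter, optionally a leading `Sample`/`Iter`
#' column), removes burn-in per replicate before pooling, and tags each row
#' with its replicate. Files may be pre-thinned (the usual sampler output,
#' one row every `thinning` iterations) or raw; in the raw case rows are
#' thinned on load.
#'
#' @param paths character vector of trace file paths (replicates).
#' @param burn_in number of MCMC *iterations* to discard from the start of
#'   each replicate.
#' @param thinning iterations per retained row.
#' @param prethinned are the files already thinned (default `TRUE`)?
#' @return an object of class `mcmc_trace`: list with `samples` (data frame,
#'   parameters plus `replicate`), `params`, `burn_in`, `thinning`.
#' @export
read_mcmc_trace <- function(paths, burn_in = 200000, thinning = 10,
                            prethinned = TRUE) {
  stopifnot(length(paths) >= 1, burn_in >= 0, thinning >= 1)
  reps <- lapply(seq_along(paths), function(i) {
    tab <- read.table(paths[i], header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    it_col <- which(tolower(names(tab)) %in% c("sample", "iter", "iteration"))
    if (length(it_col)) tab <- tab[, -it_col[1], drop = FALSE]
    if (!prethinned) tab <- tab[seq(1, nrow(tab)) %% thinning == 0, ,
                                drop = FALSE]
    drop_rows <- floor(burn_in / thinning)
    if (drop_rows >= nrow(tab))
      stop("burn-in removes every row of ", paths[i])
    tab <- tab[(drop_rows + 1):nrow(tab), , drop = FALSE]
    tab$replicate <- i
    tab
  })
  cols <- lapply(reps, function(r) setdiff(names(r), "replicate"))
  if (!all(vapply(cols, identical, logical(1), cols[[1]])))
    stop("replicate trace files have mismatched parameter columns")
  samples <- do.call(rbind, reps)
  params <- setdiff(names(samples), "replicate")
  if (!all(vapply(samples[params], is.numeric, logical(1))))
    stop("non-numeric parameter column in trace")
  if (any(!is.finite(as.matrix(samples[params]))))
    stop("non-finite values in trace")
  structure(list(samples = samples, params = params,
                 burn_in = burn_in, thinning = thinning),
            class = "mcmc_trace")
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat("mcmc_trace:", nrow(x$samples), "pooled samples,",
      length(unique(x$samples$replicate)), "replicate(s),",
      length(x$params), "parameters\n")
  cat("parameters:", paste(x$params, collapse = ", "), "\n")
  invisible(x)
}
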