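#' Named genomic interval track
#'
#' A light wrapper around [GenomicRanges::GRanges] holding one annotation
#' track (exons, CpG islands, repeats, assembly gaps, conserved noncoding
#' elements, genes, or a custom set). Coordinates are 0-based half-open in
#' every constructor and accessor; the `GRanges` inside uses the Bioconductor
#' 1-based closed convention and conversion happens only here.
#'
#' @param name track label, e.g. `"exon"`, `"cne"`, `"cpg"`, `"repeat"`,
#'   `"gap"`, `"gene"` or `"custom"`.
#' @param chrom,start,end interval coordinates, 0-based half-open
#'   (`start < end`).
#' @param id optional per-interval identifiers (required for gene overlap).
#' @param merge merge overlapping/adjacent intervals within the track
#'   (default `TRUE` when no ids are given; merging is refused when ids are
#'   present because it would destroy them).
#'
#' @return An object of class `interval_set` with fields `name`, `gr`
#'   (internal `GRanges`) and `merged`.
#' @export
interval_set <- function(name, chrom, start, end, id = NULL,
                         merge = is.null(id)) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end))
    stop("interval_set '", name, "': start must be < end (0-based half-open)")
  if (any(start < 0)) stop("negative interval start")
  gr <- GenomicRanges::GRanges(as.character(chrom),
                               IRanges::IRanges(start + 1, end))
  if (!is.null(id)) {
    if (isTRUE(merge)) stop("cannot merge an interval track that carries ids")
    S4Vectors::mcols(gr)$id <- as.character(id)
  }
  if (isTRUE(merge)) gr <- GenomicRanges::reduce(gr)
  gr <- GenomicRanges::sort(gr)
  structure(list(name = name, gr = gr, merged = isTRUE(merge)),
            class = "interval_set")
}

iset_from_granges <- function(name, gr, merged = FALSE) {
  structure(list(name = name, gr = GenomicRanges::sort(gr), merged = merged),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat("interval_set '", x$name, "': ", length(x$gr), " intervals, ",
      total_width(x), " bp", if (x$merged) " (merged)", "\n", sep = "")
  invisible(x)
}

#' @export
length.interval_set <- function(x) length(x$gr)

#' @rdname interval_set
#' @param x an `interval_set`.
#' @export
total_width <- function(x) sum(as.numeric(GenomicRanges::width(x$gr)))

#' Interval set as a 0-based half-open data frame
#'
#' @param x an `interval_set`.
#' @param ... unused.
#' @return data frame with columns `chrom`, `start`, `end` and, when present,
#'   `id`, in the package's 0-based half-open convention.
#' @export
as.data.frame.interval_set <- function(x, ...) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x$gr)),
                   start = GenomicRanges::start(x$gr) - 1,
                   end = GenomicRanges::end(x$gr),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(x$gr)
  if ("id" %in% colnames(mc)) df$id <- mc$id
  df
}

#' Write an interval set as BED
#'
#' BED3 (or BED4 when the track carries ids), 0-based half-open as in the BED
#' standard.
#'
#' @param x an `interval_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- as.data.frame(x)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
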