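#' Multi-population diploid genotype panel
#'
#' The central data container of the package: a sample-by-site matrix of
#' alternate-allele counts for biallelic SNPs, together with population labels
#' and genomic coordinates. All coordinates are stored 0-based; the VCF reader
#' converts at the boundary. Missing genotypes are `NA` and are propagated,
#' never imputed: every downstream statistic defines its own missing-data
#' handling.
#'
#' @param sample_ids character vector of sample names.
#' @param pop_labels named character vector mapping every sample to a
#'   population name.
#' @param chrom per-site chromosome identifier (character).
#' @param pos per-site 0-based position (integer).
#' @param ref,alt per-site reference / alternate allele (single characters).
#' @param geno integer matrix, sites x samples, values in `{0, 1, 2, NA}`
#'   (count of alternate alleles).
#' @param depth optional non-negative integer matrix of per-site per-sample
#'   read depth, same shape as `geno`.
#'
#' @return An object of class `genotype_panel`: a list with the fields above,
#'   sites sorted by `(chrom, pos)`.
#' @export
genotype_panel <- function(sample_ids, pop_labels, chrom, pos, ref, alt,
                           geno, depth = NULL) {
  sample_ids <- as.character(sample_ids)
  if (!all(sample_ids %in% names(pop_labels)))
    stop("every sample needs exactly one population label; missing: ",
         paste(setdiff(sample_ids, names(pop_labels)), collapse = ", "))
  pop_labels <- pop_labels[sample_ids]
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_sites <- length(pos)
  if (nrow(geno) != n_sites || ncol(geno) != length(sample_ids))
    stop("geno must be n_sites x n_samples")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotypes must be alternate-allele counts in {0, 1, 2} or NA")
  dimnames(geno) <- list(NULL, sample_ids)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!identical(dim(depth), dim(geno)))
      stop("depth must have the same shape as geno")
    dimnames(depth) <- list(NULL, sample_ids)
  }
  ord <- order(chrom, pos)
  structure(list(
    sample_ids = sample_ids,
    pop_labels = pop_labels,
    chrom = as.character(chrom)[ord],
    pos = as.integer(pos)[ord],
    ref = as.character(ref)[ord],
    alt = as.character(alt)[ord],
    geno = geno[ord, , drop = FALSE],
    depth = if (is.null(depth)) NULL else depth[ord, , drop = FALSE]
  ), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", n_sites(x), "biallelic sites x",
      n_samples(x), "samples\n")
  tab <- table(x$pop_labels)
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat("chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  if (!is.null(x$depth)) cat("per-sample depth: present\n")
  invisible(x)
}

#' @rdname genotype_panel
#' @param panel a `genotype_panel`.
#' @export
n_sites <- function(panel) length(panel$pos)

#' @rdname genotype_panel
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' Samples belonging to a population
#'
#' @param panel a `genotype_panel`.
#' @param pop population name as used in the panel's labels.
#' @return character vector of sample ids (error if the population is absent).
#' @export
pop_samples <- function(panel, pop) {
  s <- panel$sample_ids[panel$pop_labels == pop]
  if (!length(s)) stop("no samples with population label '", pop, "'")
  s
}

#' Subset a panel to a set of sites
#'
#' @param panel a `genotype_panel`.
#' @param idx logical or integer site index.
#' @return a `genotype_panel` with the selected sites.
#' @export
subset_sites <- function(panel, idx) {
  genotype_panel(panel$sample_ids, panel$pop_labels,
                 panel$chrom[idx], panel$pos[idx],
                 panel$ref[idx], panel$alt[idx],
                 panel$geno[idx, , drop = FALSE],
                 depth = if (is.null(panel$depth)) NULL
                         else panel$depth[idx, , drop = FALSE])
}

#' Write a panel to a VCF 4.2 file
#'
#' Minimal writer used for interoperability and round-trip checks: GT (and DP
#' when depth is present) per sample, positions converted back to 1-based.
#' Heterozygotes are written unphased as `0/1`.
#'
#' @param panel a `genotype_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", n_sites(panel), n_samples(panel))
  ok <- !is.na(panel$geno)
  gt[ok] <- gt_code[panel$geno[ok] + 1L]
  fmt <- "GT"
  if (!is.null(panel$depth)) {
    fmt <- "GT:DP"
    gt[] <- paste(gt, ifelse(is.na(panel$depth), ".", panel$depth), sep = ":")
  }
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (!is.null(panel$depth))
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$sample_ids), collapse = "\t"))
  body <- paste(panel$chrom, panel$pos + 1L, ".", panel$ref, panel$alt,
                ".", "PASS", ".", fmt,
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
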