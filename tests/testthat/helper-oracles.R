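# Independent oracles and fixture builders shared by the tests.

# Literal scalar transcription of the Weir & Cockerham (1984) variance
# components for one biallelic SNP and two populations, written directly
# from the published formulas (no shared code with the package's vectorised
# implementation).
wc_oracle_single <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  n1 <- length(gA); n2 <- length(gB)
  p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

wc_oracle_fst <- function(gA_mat, gB_mat) {
  # ratio of summed components over the SNPs (rows) of two genotype matrices
  comps <- t(vapply(seq_len(nrow(gA_mat)), function(i)
    wc_oracle_single(gA_mat[i, ], gB_mat[i, ]), numeric(3)))
  sum(comps[, 1]) / sum(rowSums(comps))
}

# quick panel builder: geno is a sites x samples matrix of alt-allele counts
make_test_panel <- function(geno, pops, pos = NULL, chrom = "chr1",
                            depth = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  ids <- paste0("s", seq_len(m))
  colnames(geno) <- ids
  genotype_panel(ids, setNames(pops, ids),
                 chrom = rep(chrom, length.out = n), pos = pos,
                 ref = rep("A", n), alt = rep("G", n),
                 geno = geno, depth = depth)
}

# write a small VCF fixture; gt is a character matrix of GT strings
write_test_vcf <- function(path, chrom, pos, ref, alt, gt, samples,
                           dp = NULL) {
  fmt <- if (is.null(dp)) "GT" else "GT:DP"
  body <- vapply(seq_along(pos), function(i) {
    cells <- gt[i, ]
    if (!is.null(dp)) cells <- paste(cells, dp[i, ], sep = ":")
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".",
            fmt, cells), collapse = "\t")
  }, character(1))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               if (!is.null(dp))
                 '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               body), path)
  path
}

# random sequence with the restriction motif at exactly the given 0-based
# positions (resamples until no spurious occurrence remains)
plant_motif <- function(len, at, seed = 1, motif = "ACTAGT") {
  set.seed(seed)
  repeat {
    sq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
    for (p in at) substr(sq, p + 1, p + nchar(motif)) <- motif
    occ <- gregexpr(motif, sq, fixed = TRUE)[[1]] - 1L
    if (identical(sort(occ[occ >= 0]), sort(as.integer(at)))) return(sq)
  }
}

# mcmc_trace object straight from a data frame (params + replicate column)
trace_from_df <- function(df, burn_in = 0, thinning = 10) {
  if (is.null(df$replicate)) df$replicate <- 1L
  structure(list(samples = df,
                 params = setdiff(names(df), "replicate"),
                 burn_in = burn_in, thinning = thinning),
            class = "mcmc_trace")
}
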