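#' Pairwise genotype-correlation r-squared
#'
#' Composite (Rogers-Huff style) linkage disequilibrium on unphased
#' genotypes: for every same-chromosome SNP pair with
#' `0 < distance <= max_dist`, the squared Pearson correlation of the two
#' alternate-allele-count vectors over the samples non-missing at both sites.
#' Pairs where either site is monomorphic in the used sample set have no
#' defined r-squared and are skipped.
#'
#' @param panel a [genotype_panel].
#' @param max_dist maximum pair distance in bp (default 500 kb, the range of
#'   the study's decay profile).
#' @param samples optional sample subset (e.g. the nine individuals drawn per
#'   population when comparing populations); default all samples.
#' @return data frame with columns `dist` (bp) and `r2`.
#' @export
pairwise_r2 <- function(panel, max_dist = 500000, samples = NULL) {
  if (is.null(samples)) samples <- panel$sample_ids
  if (!all(samples %in% panel$sample_ids))
    stop("unknown sample(s): ",
         paste(setdiff(samples, panel$sample_ids), collapse = ", "))
  res_d <- list(); res_r <- list(); k <- 0L
  for (ch in unique(panel$chrom)) {
    si <- which(panel$chrom == ch)
    if (length(si) < 2) next
    G <- t(panel$geno[si, samples, drop = FALSE])  # samples x sites
    C <- suppressWarnings(cor(G, use = "pairwise.complete.obs"))
    pos <- panel$pos[si]
    pr <- which(upper.tri(C), arr.ind = TRUE)
    d <- pos[pr[, 2]] - pos[pr[, 1]]
    keep <- d > 0 & d <= max_dist & !is.na(C[pr])
    k <- k + 1L
    res_d[[k]] <- d[keep]
    res_r[[k]] <- C[pr][keep]^2
  }
  data.frame(dist = unlist(res_d), r2 = unlist(res_r))
}

#' LD decay profile and H statistic
#'
#' Bins SNP-pair r-squared values into fixed-width distance bins and reports
#' the per-bin mean together with the scalar H statistic: the sum of the
#' per-bin mean r-squared over all bins — an area-under-the-curve analogue of
#' the decay profile that captures the overall level of linkage
#' disequilibrium in a population (elevated after a bottleneck, low in old
#' outbred populations). At the defaults (5 kb bins to 500 kb) there are
#' exactly `500/5 = 100` bins and `0 <= H <= 100`.
#'
#' Bin `k` covers distances `((k-1)*bin_width, k*bin_width]`, so a pair at
#' exactly 5 kb falls in bin 1. Empty bins contribute 0 to H and are flagged
#' by a zero pair count.
#'
#' @param pairs data frame from [pairwise_r2] (`dist`, `r2`).
#' @param bin_width bin width in bp (default 5 kb); must divide `max_dist`.
#' @param max_dist largest distance profiled (default 500 kb).
#' @return object of class `ld_profile`: list with `bins` (data frame
#'   `dist_lo`, `dist_hi`, `mean_r2`, `n_pairs`), `H`, `n_bins`,
#'   `bin_width`, `max_dist`.
#' @export
ld_profile <- function(pairs, bin_width = 5000, max_dist = 500000) {
  if (max_dist %% bin_width != 0)
    stop("bin_width must divide max_dist")
  n_bins <- max_dist %/% bin_width
  d <- pairs$dist; r2 <- pairs$r2
  keep <- d > 0 & d <= max_dist
  d <- d[keep]; r2 <- r2[keep]
  bin <- ceiling(d / bin_width)
  mean_r2 <- rep(0, n_bins)
  n_pairs <- tabulate(bin, nbins = n_bins)
  if (length(bin)) {
    sums <- vapply(split(r2, factor(bin, levels = seq_len(n_bins))),
                   sum, numeric(1))
    mean_r2[n_pairs > 0] <- sums[n_pairs > 0] / n_pairs[n_pairs > 0]
  }
  structure(list(
    bins = data.frame(dist_lo = (seq_len(n_bins) - 1) * bin_width,
                      dist_hi = seq_len(n_bins) * bin_width,
                      mean_r2 = mean_r2, n_pairs = n_pairs),
    H = sum(mean_r2), n_bins = n_bins,
    bin_width = bin_width, max_dist = max_dist
  ), class = "ld_profile")
}

#' @export
print.ld_profile <- function(x, ...) {
  cat("ld_profile:", x$n_bins, "bins of", x$bin_width, "bp up to",
      x$max_dist, "bp;", sum(x$bins$n_pairs > 0), "bins populated\n")
  cat("H statistic:", format(x$H, digits = 4), "\n")
  invisible(x)
}
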