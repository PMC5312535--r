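#' Per-SNP Weir-Cockerham variance components
#'
#' Computes the a (among-population), b (among-individual-within-population)
#' and c (within-individual) variance components of the Weir & Cockerham
#' (1984) F_ST estimator for two populations at every site of a panel, from
#' unphased diploid genotypes. Sites where either population has fewer than
#' two non-missing individuals, or where the pooled sample is monomorphic,
#' are flagged unusable (components `NA`).
#'
#' The windowed estimate is the "weighted" ratio of sums,
#' `sum(a) / sum(a + b + c)` over the usable SNPs of a window — the standard
#' windowed form and the behaviour of the windowed mode of the common VCF
#' toolkit.
#'
#' @param panel a [genotype_panel].
#' @param popA,popB population labels present in the panel.
#' @return data frame with per-site `a`, `b`, `c` and logical `usable`.
#' @export
wc_fst_components <- function(panel, popA, popB) {
  gA <- panel$geno[, pop_samples(panel, popA), drop = FALSE]
  gB <- panel$geno[, pop_samples(panel, popB), drop = FALSE]
  nA <- rowSums(!is.na(gA)); nB <- rowSums(!is.na(gB))
  pA <- rowSums(gA, na.rm = TRUE) / (2 * nA)
  pB <- rowSums(gB, na.rm = TRUE) / (2 * nB)
  hA <- rowSums(gA == 1L, na.rm = TRUE) / nA
  hB <- rowSums(gB == 1L, na.rm = TRUE) / nB

  r <- 2
  nbar <- (nA + nB) / r
  nsum <- nA + nB
  nc <- (nsum - (nA^2 + nB^2) / nsum) / (r - 1)
  pbar <- (nA * pA + nB * pB) / nsum
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / nsum

  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  usable <- nA >= 2 & nB >= 2 & pbar > 0 & pbar < 1
  a[!usable] <- b[!usable] <- cc[!usable] <- NA_real_
  data.frame(a = a, b = b, c = cc, usable = usable)
}

# clamp an F_ST estimate into [0, 1 - eps] for the -log(1 - F) transform
clamp_fst <- function(f, eps = 1e-9) pmin(pmax(f, 0), 1 - eps)

#' Genome-wide Weir-Cockerham F_ST
#'
#' Single ratio-of-sums estimate over all usable SNPs of the panel.
#'
#' @inheritParams wc_fst_components
#' @return named list: `fst_raw` (can be slightly negative), `fst` (clamped
#'   to `[0, 1 - 1e-9]`), `n_snps` used.
#' @export
wc_fst_global <- function(panel, popA, popB) {
  comp <- wc_fst_components(panel, popA, popB)
  use <- comp$usable
  if (!any(use)) stop("no usable SNPs for F_ST between ", popA, " and ", popB)
  raw <- sum(comp$a[use]) / sum(comp$a[use] + comp$b[use] + comp$c[use])
  list(fst_raw = raw, fst = clamp_fst(raw), n_snps = sum(use))
}

#' Windowed Weir-Cockerham F_ST
#'
#' Ratio-of-sums Weir-Cockerham (1984) estimate per sliding window. Windows
#' with fewer than `min_snps` usable SNPs are flagged undefined rather than
#' reported as a number; both the raw estimate and a copy clamped to
#' `[0, 1 - 1e-9]` (for downstream `-log(1 - F)` transforms) are stored.
#'
#' @inheritParams wc_fst_components
#' @param grid a [window_grid]; the selection scan of the study design uses
#'   100 kb windows stepped every 20 kb.
#' @param min_snps minimum usable SNPs per window (default 10); windows below
#'   it are undefined and excluded from quantile ranking downstream.
#' @return object of class `fst_track`: data frame `chrom`, `start`, `end`,
#'   `n_snps`, `fst_raw`, `fst`, `defined`.
#' @export
wc_fst_window <- function(panel, popA, popB, grid, min_snps = 10) {
  comp <- wc_fst_components(panel, popA, popB)
  wi <- window_site_index(panel, grid)
  out <- wi$windows
  nw <- nrow(out)
  out$n_snps <- 0L
  out$fst_raw <- NA_real_
  for (w in seq_len(nw)) {
    s <- wi$sites[[w]]
    s <- s[comp$usable[s]]
    out$n_snps[w] <- length(s)
    if (length(s) >= min_snps)
      out$fst_raw[w] <- sum(comp$a[s]) /
        sum(comp$a[s] + comp$b[s] + comp$c[s])
  }
  out$fst <- clamp_fst(out$fst_raw)
  out$defined <- !is.na(out$fst_raw)
  structure(out, class = c("fst_track", "data.frame"),
            popA = popA, popB = popB, min_snps = min_snps)
}
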