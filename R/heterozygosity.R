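#' Sliding-window heterozygosity per sample
#'
#' Genetic diversity of each individual as the fraction of heterozygous
#' genotypes among its usable sites in each window. A site is usable for a
#' sample if the genotype is non-missing and, when a depth filter is active
#' (as for restriction-site-associated sequencing data with non-uniform
#' coverage), its read depth in that sample is at least `min_depth`. Windows
#' with zero usable sites for a sample are undefined (`NA`), never zero.
#'
#' @param panel a [genotype_panel].
#' @param grid a [window_grid]; the study design uses 1 Mb windows stepped
#'   every 200 kb.
#' @param min_depth minimum per-sample read depth for a site to count
#'   (0 = no depth filtering). Requires the panel to carry depth when > 0;
#'   the depth rule is inclusive: depth 5 passes a `min_depth = 5` filter.
#' @return object of class `het_track`: list with `grid`, `windows` (data
#'   frame), `het` (windows x samples matrix of fractions in `[0, 1]` or
#'   `NA`), `n_usable` (windows x samples usable-site counts).
#' @export
window_heterozygosity <- function(panel, grid, min_depth = 0) {
  if (min_depth > 0 && is.null(panel$depth))
    stop("min_depth > 0 requires per-sample depth in the panel")
  wi <- window_site_index(panel, grid)
  ns <- n_samples(panel)
  usable <- !is.na(panel$geno)
  if (min_depth > 0)
    usable <- usable & !is.na(panel$depth) & panel$depth >= min_depth
  is_het <- usable & panel$geno == 1L
  het <- n_us <- matrix(NA_real_, nrow(wi$windows), ns,
                        dimnames = list(NULL, panel$sample_ids))
  for (w in seq_len(nrow(wi$windows))) {
    s <- wi$sites[[w]]
    u <- if (length(s)) colSums(usable[s, , drop = FALSE]) else rep(0, ns)
    h <- if (length(s)) colSums(is_het[s, , drop = FALSE]) else rep(0, ns)
    n_us[w, ] <- u
    het[w, ] <- ifelse(u > 0, h / u, NA_real_)
  }
  structure(list(grid = grid, windows = wi$windows,
                 het = het, n_usable = n_us),
            class = "het_track")
}

#' @export
print.het_track <- function(x, ...) {
  cat("het_track:", nrow(x$windows), "windows x", ncol(x$het), "samples;",
      sum(rowSums(!is.na(x$het)) > 0), "windows with data\n")
  invisible(x)
}

#' Long-format view of a heterozygosity track
#'
#' @param x a `het_track`.
#' @param ... unused.
#' @return data frame `chrom`, `start`, `end`, `sample`, `n_usable`, `het`.
#' @export
as.data.frame.het_track <- function(x, ...) {
  nw <- nrow(x$windows); ns <- ncol(x$het)
  data.frame(x$windows[rep(seq_len(nw), times = ns), ],
             sample = rep(colnames(x$het), each = nw),
             n_usable = as.vector(x$n_usable),
             het = as.vector(x$het),
             row.names = NULL, stringsAsFactors = FALSE)
}
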