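#' Population branch statistic
#'
#' Branch length of the focal population since its split from the sister,
#' in units of log-transformed differentiation:
#' `PBS = (T_fs + T_fo - T_so) / 2` with `T = -log(1 - F_ST)` (natural log),
#' where `f` is the focal population (here the breed under study), `s` its
#' sister population and `o` the outgroup. Large values mark windows whose
#' allele frequencies moved specifically along the focal branch — the
#' signature of recent positive selection.
#'
#' @param fst_fs F_ST between focal and sister populations.
#' @param fst_fo F_ST between focal population and outgroup.
#' @param fst_so F_ST between sister population and outgroup.
#' @param clamp clamp inputs into `[0, 1 - 1e-9]` before the log transform
#'   (default). With `clamp = FALSE` an input of 1 or more is an error
#'   (infinite branch length).
#' @return PBS value(s); vectorised over the three inputs.
#' @export
pbs <- function(fst_fs, fst_fo, fst_so, clamp = TRUE) {
  if (clamp) {
    fst_fs <- clamp_fst(fst_fs); fst_fo <- clamp_fst(fst_fo)
    fst_so <- clamp_fst(fst_so)
  } else if (any(c(fst_fs, fst_fo, fst_so) >= 1, na.rm = TRUE)) {
    stop("F_ST >= 1 gives an infinite branch length; enable clamping")
  }
  t_fs <- -log(1 - fst_fs)
  t_fo <- -log(1 - fst_fo)
  t_so <- -log(1 - fst_so)
  (t_fs + t_fo - t_so) / 2
}

#' Windowed PBS selection scan
#'
#' Computes the three pairwise windowed Weir-Cockerham F_ST tracks on a
#' shared grid and combines them into a per-window population branch
#' statistic for the focal population. A window is defined only where all
#' three pairwise F_ST values are defined.
#'
#' @param panel a [genotype_panel] containing the three populations.
#' @param focal,sister,outgroup population labels (e.g. the breed, its source
#'   population, and a more distant dog population).
#' @param grid a [window_grid] (100 kb / 20 kb in the study design).
#' @param min_snps minimum usable SNPs per window per population pair.
#' @return object of class `pbs_track`: data frame with window coordinates,
#'   the three clamped F_ST values, the three T branch lengths, `pbs`,
#'   `n_snps` (minimum over the three pairs) and `defined`.
#' @export
pbs_scan <- function(panel, focal, sister, outgroup, grid, min_snps = 10) {
  pops <- c(focal, sister, outgroup)
  if (anyDuplicated(pops)) stop("focal, sister and outgroup must be distinct")
  for (p in pops)
    if (length(pop_samples(panel, p)) < 2)
      stop("population '", p, "' has fewer than 2 samples")
  fs <- wc_fst_window(panel, focal, sister, grid, min_snps)
  fo <- wc_fst_window(panel, focal, outgroup, grid, min_snps)
  so <- wc_fst_window(panel, sister, outgroup, grid, min_snps)
  out <- fs[, c("chrom", "start", "end")]
  out$fst_fs <- fs$fst; out$fst_fo <- fo$fst; out$fst_so <- so$fst
  out$t_fs <- -log(1 - out$fst_fs)
  out$t_fo <- -log(1 - out$fst_fo)
  out$t_so <- -log(1 - out$fst_so)
  out$n_snps <- pmin(fs$n_snps, fo$n_snps, so$n_snps)
  out$defined <- fs$defined & fo$defined & so$defined
  out$pbs <- ifelse(out$defined,
                    (out$t_fs + out$t_fo - out$t_so) / 2, NA_real_)
  structure(out, class = c("pbs_track", "data.frame"),
            focal = focal, sister = sister, outgroup = outgroup)
}
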