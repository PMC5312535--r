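#' Simulation configuration for the three-population demography
#'
#' Parameterises the structured-coalescent generator after the demographic
#' model the package's inference stages target: dogs split from gray wolves
#' about 31,700 years ago, the breed (modelled on the Chow Chow) split from
#' the Chinese indigenous dogs about 8,300 years ago, the ancestral dog
#' population was small, the indigenous population expanded rapidly after
#' the breed split, the breed suffered a mild reduction, and migration
#' between neighbouring populations is low (2Nm of order 1 or below). The
#' absolute size values are plausible placeholders chosen to give realistic
#' dog-like nucleotide diversity (~1e-3/bp in the indigenous population);
#' graphical sources report no exact numbers.
#'
#' Recombination is approximated by independence between consecutive
#' `block_size` blocks and complete linkage within a block.
#'
#' @param seed RNG seed; every generator is a pure function of
#'   (config, seed).
#' @param samples named diploid sample counts per population
#'   (`wolf`, `indigenous`, `chow`).
#' @param split_wolf_years,split_chow_years split times in years
#'   (`split_wolf_years >= split_chow_years`).
#' @param N named effective sizes: `wolf`, `indigenous` (modern, expanded),
#'   `chow` (modern, mildly reduced), `ancestral_dog` (small, between the
#'   two splits), `root` (ancestral to all).
#' @param mig_2Nm named 2Nm migration intensities for the two bands
#'   (`wolf_indigenous`, `indigenous_chow`).
#' @param mu_year per-site per-year mutation rate.
#' @param gen_time generation time in years; also converts split times to
#'   generations, so simulation truth and [scale_estimates] conversions are
#'   mutually consistent.
#' @param seq_length total simulated sequence, bp.
#' @param n_chrom number of equal-length chromosomes.
#' @param block_size independently evolving block length, bp.
#' @param depth_mean optional mean per-site read depth; when set, a
#'   negative-binomial depth matrix is attached to the panel.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       samples = c(wolf = 4, indigenous = 13, chow = 10),
                       split_wolf_years = 31700,
                       split_chow_years = 8300,
                       N = c(wolf = 20000, indigenous = 30000, chow = 3000,
                             ancestral_dog = 4000, root = 20000),
                       mig_2Nm = c(wolf_indigenous = 0.5,
                                   indigenous_chow = 0.5),
                       mu_year = 2.2e-9, gen_time = 3,
                       seq_length = 1e7, n_chrom = 2, block_size = 1e4,
                       depth_mean = NA) {
  stopifnot(all(c("wolf", "indigenous", "chow") %in% names(samples)),
            all(c("wolf", "indigenous", "chow", "ancestral_dog", "root")
                %in% names(N)),
            all(N > 0), all(mig_2Nm >= 0),
            split_wolf_years >= split_chow_years,
            split_chow_years >= 0,
            mu_year > 0, gen_time > 0,
            seq_length >= block_size, n_chrom >= 1, block_size > 0)
  if (any(samples <= 0)) stop("zero samples in a population")
  structure(list(seed = seed, samples = samples,
                 split_wolf_years = split_wolf_years,
                 split_chow_years = split_chow_years,
                 N = N, mig_2Nm = mig_2Nm,
                 mu_year = mu_year, gen_time = gen_time,
                 seq_length = seq_length, n_chrom = n_chrom,
                 block_size = block_size, depth_mean = depth_mean),
            class = "sim_config")
}

#' Simulate a genotype panel under the three-population demography
#'
#' Runs the structured coalescent (with the configured sizes, split times
#' converted to generations, and symmetric low migration on the
#' wolf-indigenous and indigenous-breed bands) independently on consecutive
#' sequence blocks, drops infinite-sites mutations on each genealogy, and
#' assembles the biallelic SNPs into a [genotype_panel]. Deterministic under
#' the config seed.
#'
#' @param cfg a [sim_config].
#' @return a [genotype_panel] with populations `wolf`, `indigenous`, `chow`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pops <- c("wolf", "indigenous", "chow")
  ns <- cfg$samples[pops]
  sample_ids <- unlist(lapply(pops, function(p)
    paste0(p, "_", seq_len(ns[[p]]))))
  pop_labels <- setNames(rep(pops, ns), sample_ids)
  nlin <- setNames(2L * as.integer(ns), pops)
  t_chow <- cfg$split_chow_years / cfg$gen_time
  t_wolf <- cfg$split_wolf_years / cfg$gen_time
  mu_gen <- cfg$mu_year * cfg$gen_time
  chrom_len <- floor(cfg$seq_length / cfg$n_chrom)
  n_blocks <- max(1L, chrom_len %/% cfg$block_size)

  chroms <- list(); poss <- list(); genos <- list(); k <- 0L
  for (ci in seq_len(cfg$n_chrom)) {
    ch <- paste0("chr", ci)
    for (b in seq_len(n_blocks)) {
      blk <- sim_block_genotypes(nlin, t_chow, t_wolf, cfg$N, cfg$mig_2Nm,
                                 mu_gen, cfg$block_size)
      if (!length(blk$pos)) next
      k <- k + 1L
      chroms[[k]] <- rep(ch, length(blk$pos))
      poss[[k]] <- (b - 1L) * cfg$block_size + blk$pos
      genos[[k]] <- blk$geno
    }
  }
  if (k == 0L) stop("simulation produced no SNPs; increase seq_length or N")
  chrom <- unlist(chroms); pos <- unlist(poss)
  geno <- do.call(rbind, genos)
  colnames(geno) <- sample_ids
  n <- length(pos)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  depth <- NULL
  if (!is.na(cfg$depth_mean))
    depth <- matrix(rnbinom(n * length(sample_ids), size = 30,
                            mu = cfg$depth_mean),
                    n, length(sample_ids),
                    dimnames = list(NULL, sample_ids))
  genotype_panel(sample_ids, pop_labels, chrom, pos, ref, alt, geno,
                 depth = depth)
}

#' Chromosome lengths implied by a simulation config
#'
#' @param cfg a [sim_config].
#' @return named vector suitable for [window_grid].
#' @export
sim_chrom_lengths <- function(cfg) {
  setNames(rep(floor(cfg$seq_length / cfg$n_chrom), cfg$n_chrom),
           paste0("chr", seq_len(cfg$n_chrom)))
}

#' Plant a selective-sweep signature in one population
#'
#' Emulates a completed hard sweep as a deterministic-under-seed frequency
#' transform of neutral coalescent output rather than a forward selection
#' simulation. One "swept haplotype" is emulated by drawing, at every SNP
#' within `radius` of the sweep position, a swept allele with probability
#' equal to its current frequency in the target population (the allele a
#' hitchhiking haplotype would carry); each target-population genotype is
#' then replaced by the swept-allele homozygote with probability `w(d)`,
#' which equals `strength` up to `radius/2` from the sweep centre and decays
#' linearly to 0 at `radius`. Other populations are untouched;
#' `strength = 0` is the identity and `strength = 1` fixes the core.
#'
#' @param panel a [genotype_panel].
#' @param chrom,position sweep centre.
#' @param target_pop population carrying the sweep.
#' @param strength replacement probability at the core, in `[0, 1]`.
#' @param radius half-width of the affected region, bp.
#' @param seed RNG seed for the replacement draws.
#' @return the modified [genotype_panel].
#' @export
plant_sweep <- function(panel, chrom, position, target_pop,
                        strength = 1, radius = 1e5, seed = 1) {
  stopifnot(strength >= 0, strength <= 1, radius > 0)
  if (strength == 0) return(panel)
  set.seed(seed)
  tgt <- pop_samples(panel, target_pop)
  d <- abs(panel$pos - position)
  idx <- which(panel$chrom == chrom & d <= radius)
  if (!length(idx)) return(panel)
  w <- strength * pmin(1, pmax(0, 2 * (1 - d[idx] / radius)))
  g <- panel$geno[idx, tgt, drop = FALSE]
  freq <- rowMeans(g, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- 0
  swept <- ifelse(runif(length(idx)) < freq, 2L, 0L)
  repl <- matrix(runif(length(idx) * length(tgt)), length(idx)) < w
  g[repl] <- matrix(swept, length(idx), length(tgt))[repl]
  panel$geno[idx, tgt] <- g
  panel
}
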