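#' Generate a toy genome with planted cut sites and annotation tracks
#'
#' Builds a random genome in which the restriction motif occurs exactly at
#' the planted positions (spurious occurrences are destroyed by single-base
#' edits), together with randomly placed cpg/repeat/gap/exon/cne annotation
#' intervals and optional N runs, and returns the ground-truth expected
#' status of every planted locus computed by an independent brute-force
#' predicate evaluator (plain string and interval arithmetic, no shared code
#' with the pipeline). Used to validate the locus-selection cascade end to
#' end.
#'
#' @param seed RNG seed.
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length, bp.
#' @param n_sites planted cut sites per chromosome (placed anywhere,
#'   including near edges, with at least 20 bp separation).
#' @param tracks_spec named integer vector: number of random intervals per
#'   track for any of `cpg`, `repeat`, `gap`, `exon`, `cne`.
#' @param n_runs number of 20 bp N runs planted per chromosome.
#' @param cfg [digest_config] used by the ground-truth evaluator (use a
#'   small `spacing` at toy scale).
#' @return list with `genome` (a `DNAStringSet`), `tracks` (named list of
#'   [interval_set]), `sites` (data frame `chrom`, `pos`), `expected` (data
#'   frame `chrom`, `pos`, `status`, `reason`) and `cfg`.
#' @export
make_toy_genome <- function(seed, n_chrom = 2, chrom_length = 50000,
                            n_sites = 6,
                            tracks_spec = c(cpg = 2, "repeat" = 2, gap = 1,
                                            exon = 2, cne = 2),
                            n_runs = 1,
                            cfg = digest_config(spacing = 5000)) {
  set.seed(seed)
  motif <- cfg$motif
  ml <- nchar(motif)
  if (n_sites * (2 * cfg$flank + ml) > chrom_length / 2)
    stop("infeasible packing: too many sites for the chromosome length")
  bases <- c("A", "C", "G", "T")
  genome_chars <- list()
  sites <- list()
  for (ci in seq_len(n_chrom)) {
    # planted positions, min 20 bp apart so motif footprints never touch
    repeat {
      p <- sort(sample.int(chrom_length - ml, n_sites))
      if (n_sites < 2 || min(diff(p)) >= 20) break
    }
    p0 <- p - 1L                          # 0-based
    sq <- sample(bases, chrom_length, replace = TRUE)
    for (pp in p) sq[pp:(pp + ml - 1L)] <- strsplit(motif, "")[[1]]
    # destroy spurious motif occurrences by editing a base outside every
    # planted footprint
    planted_cover <- unlist(lapply(p, function(pp) pp:(pp + ml - 1L)))
    for (iter in 1:100) {
      s <- paste(sq, collapse = "")
      occ <- gregexpr(motif, s, fixed = TRUE)[[1]]
      occ <- occ[occ > 0]
      spurious <- setdiff(occ, p)
      if (!length(spurious)) break
      for (sp in spurious) {
        span <- sp:(sp + ml - 1L)
        editable <- span[!(span %in% planted_cover)]
        j <- editable[1]
        sq[j] <- sample(setdiff(bases, sq[j]), 1L)
      }
    }
    occ <- gregexpr(motif, paste(sq, collapse = ""), fixed = TRUE)[[1]]
    if (length(setdiff(occ[occ > 0], p)))
      stop("could not remove spurious motif occurrences")
    # N runs, never inside a motif
    for (r in seq_len(n_runs)) {
      repeat {
        ns <- sample.int(chrom_length - 20L, 1L)
        if (!any((ns:(ns + 19L)) %in% planted_cover)) break
      }
      sq[ns:(ns + 19L)] <- "N"
    }
    genome_chars[[ci]] <- paste(sq, collapse = "")
    sites[[ci]] <- data.frame(chrom = paste0("chr", ci), pos = p0,
                              stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(unlist(genome_chars))
  names(genome) <- paste0("chr", seq_len(n_chrom))
  sites <- do.call(rbind, sites)

  tracks <- list()
  widths <- c(cpg = 300, "repeat" = 400, gap = 500, exon = 600, cne = 80)
  for (nm in names(tracks_spec)) {
    n_iv <- tracks_spec[[nm]]
    if (n_iv == 0) next
    ch <- sample(paste0("chr", seq_len(n_chrom)), n_iv * n_chrom,
                 replace = TRUE)
    wmax <- widths[[nm]]
    w <- sample(seq(50, wmax), length(ch), replace = TRUE)
    st <- vapply(w, function(wi)
      sample.int(chrom_length - wi, 1L), integer(1))
    tracks[[nm]] <- interval_set(nm, ch, st, st + w)
  }

  expected <- rad_truth_bruteforce(genome_chars, sites, tracks, cfg)
  list(genome = genome, tracks = tracks, sites = sites,
       expected = expected, cfg = cfg)
}

# Independent brute-force evaluation of every locus-selection predicate:
# character-level string slicing and O(n^2) interval loops, no GRanges, no
# shared helpers with the pipeline. Order: edge/N, cpg, repeat, gap, exon,
# cne, (coverage), spacing.
rad_truth_bruteforce <- function(genome_chars, sites, tracks, cfg,
                                 depth_table = NULL, samples = NULL) {
  ml <- nchar(cfg$motif)
  track_df <- lapply(tracks, function(tr) as.data.frame(tr))
  n <- nrow(sites)
  status <- rep("pass", n); reason <- rep(NA_character_, n)
  gap_dist <- function(s1, e1, s2, e2) {  # 0-based half-open end gap
    if (s1 < e2 && s2 < e1) return(0)
    if (e1 <= s2) return(s2 - e1)
    s1 - e2
  }
  chrom_index <- as.integer(sub("chr", "", sites$chrom))
  for (i in seq_len(n)) {
    pos <- sites$pos[i]
    sq <- genome_chars[[chrom_index[i]]]
    fs <- pos - cfg$flank; fe <- pos + ml + cfg$flank
    if (fs < 0 || fe > nchar(sq)) {
      status[i] <- "rejected"; reason[i] <- "edge"; next
    }
    foot <- substr(sq, fs + 1, fe)
    if (grepl("[^ACGT]", foot)) {
      status[i] <- "rejected"; reason[i] <- "edge"; next
    }
    ls <- fs + cfg$trim; le <- fe - cfg$trim
    hit <- NA_character_
    for (nm in c("cpg", "repeat", "gap")) {
      df <- track_df[[nm]]
      if (is.null(df)) next
      for (r in seq_len(nrow(df))) {
        if (df$chrom[r] == sites$chrom[i] &&
            ls < df$end[r] && df$start[r] < le) { hit <- nm; break }
      }
      if (!is.na(hit)) break
    }
    if (is.na(hit) && !is.null(track_df$exon)) {
      df <- track_df$exon
      dmin <- Inf
      for (r in seq_len(nrow(df)))
        if (df$chrom[r] == sites$chrom[i])
          dmin <- min(dmin, gap_dist(ls, le, df$start[r], df$end[r]))
      if (dmin < cfg$exon_dist) hit <- "exon"
    }
    if (is.na(hit) && !is.null(track_df$cne)) {
      df <- track_df$cne
      dmin <- Inf
      for (r in seq_len(nrow(df)))
        if (df$chrom[r] == sites$chrom[i])
          dmin <- min(dmin, gap_dist(ls, le, df$start[r], df$end[r]))
      if (dmin <= cfg$cne_dist) hit <- "cne"
    }
    if (!is.na(hit)) { status[i] <- "rejected"; reason[i] <- hit }
  }
  if (!is.null(depth_table)) {
    for (i in seq_len(n)) {
      if (status[i] != "pass") next
      pos <- sites$pos[i]
      fp <- c(seq(pos - cfg$flank, pos - 1),
              seq(pos + ml, pos + ml + cfg$flank - 1))
      ok <- TRUE
      for (pp in fp) {
        row <- depth_table[depth_table$chrom == sites$chrom[i] &
                             depth_table$pos == pp, samples, drop = FALSE]
        if (nrow(row) == 0 || any(row < cfg$min_depth)) { ok <- FALSE; break }
      }
      if (!ok) { status[i] <- "rejected"; reason[i] <- "coverage" }
    }
  }
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    idx <- idx[order(sites$pos[idx])]
    last <- -Inf
    for (i in idx) {
      if (status[i] != "pass") next
      if (sites$pos[i] - last < cfg$spacing) {
        status[i] <- "rejected"; reason[i] <- "spacing"
      } else last <- sites$pos[i]
    }
  }
  data.frame(chrom = sites$chrom, pos = sites$pos,
             status = status, reason = reason, stringsAsFactors = FALSE)
}

#' Simulate a per-sample per-base RAD depth table
#'
#' Emulates the locus-level coverage structure of restriction-site-anchored
#' sequencing (roughly uniform within a locus, overdispersed between loci,
#' occasional allelic dropout): for each locus and sample, one
#' negative-binomial draw (`mu = mean_depth`, `size = size`) is used as the
#' depth of every base of both full flanks, zeroed with probability
#' `dropout`. Deterministic under the seed.
#'
#' @param loci a `rad_loci` data frame from [extract_loci] (non-edge loci
#'   get depth; edge-rejected loci are skipped).
#' @param samples character vector of sample names.
#' @param seed RNG seed.
#' @param mean_depth mean per-base depth (the study's RAD data averaged
#'   about 36-fold at the anchored end).
#' @param size negative-binomial dispersion.
#' @param dropout per-locus per-sample probability of zero coverage.
#' @param cfg a [digest_config].
#' @return data frame `chrom`, `pos` (0-based) plus one integer column per
#'   sample.
#' @export
make_depth_table <- function(loci, samples, seed = 1, mean_depth = 36,
                             size = 30, dropout = 0,
                             cfg = digest_config()) {
  stopifnot(mean_depth > 0, dropout >= 0, dropout < 1, length(samples) > 0)
  set.seed(seed)
  ml <- nchar(cfg$motif)
  use <- which(is.na(loci$reason) | loci$reason != "edge")
  rows <- list()
  for (k in seq_along(use)) {
    i <- use[k]
    pos <- loci$cut_site[i]
    fp <- c(seq(pos - cfg$flank, pos - 1),
            seq(pos + ml, pos + ml + cfg$flank - 1))
    d <- vapply(samples, function(s) {
      if (dropout > 0 && runif(1) < dropout) 0
      else rnbinom(1, size = size, mu = mean_depth)
    }, numeric(1))
    d <- as.integer(d)
    names(d) <- samples
    block <- data.frame(chrom = loci$chrom[i], pos = fp,
                        stringsAsFactors = FALSE)
    for (s in samples) block[[s]] <- d[[s]]
    rows[[k]] <- block
  }
  out <- do.call(rbind, rows)
  # overlapping footprints: keep the higher depth per (chrom, pos, sample)
  key <- paste(out$chrom, out$pos)
  if (anyDuplicated(key)) {
    tot <- rowSums(out[, samples, drop = FALSE])
    out <- out[order(key, -tot), ]
    out <- out[!duplicated(paste(out$chrom, out$pos)), ]
  }
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Simulate replicate MCMC trace files
#'
#' Writes tab-delimited trace files in the dialect [read_mcmc_trace] reads:
#' a `Sample` column plus one column per parameter, one row per `thinning`
#' iterations. Post-burn-in rows are stationary AR(1) deviations around the
#' truth (`x = truth * (1 + dev)`, `dev` mean-zero with marginal standard
#' deviation `noise`); with `noise = 0` every sample equals the truth.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @param truth named numeric vector of parameter truths (all positive),
#'   e.g. `c(theta_indigenous = 8e-4, tau_chow = 1.826e-5)`.
#' @param n_iter total MCMC iterations represented per replicate.
#' @param thinning iterations per written row.
#' @param noise relative marginal standard deviation of the deviations.
#' @param rho AR(1) autocorrelation between consecutive rows.
#' @param n_replicates number of replicate files.
#' @return character vector of file paths.
#' @export
make_trace <- function(dir, seed = 1, truth, n_iter = 52000, thinning = 10,
                       noise = 0.05, rho = 0.9, n_replicates = 5) {
  stopifnot(all(truth > 0), !is.null(names(truth)), n_iter >= thinning,
            rho >= 0, rho < 1, noise >= 0)
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_rows <- n_iter %/% thinning
  paths <- character(n_replicates)
  for (r in seq_len(n_replicates)) {
    tab <- data.frame(Sample = seq_len(n_rows) * thinning)
    for (p in names(truth)) {
      dev <- numeric(n_rows)
      if (noise > 0) {
        dev[1] <- rnorm(1, 0, noise)
        innov <- rnorm(n_rows, 0, noise * sqrt(1 - rho^2))
        for (i in seq_len(n_rows - 1))
          dev[i + 1] <- rho * dev[i] + innov[i]
      }
      tab[[p]] <- truth[[p]] * pmax(1 + dev, 0)
    }
    paths[r] <- file.path(dir, sprintf("trace_rep%d.tsv", r))
    write.table(tab, paths[r], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths
}
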