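# Structured-coalescent engine for the three-population demography
# (wolf / indigenous dog / derived breed). One genealogy per independently
# evolving sequence block; infinite-sites mutations dropped on the tree.
# Time runs pastward in generations; population sizes are constant within
# the epochs delimited by the two split times.

# Simulate one block: returns a list with `geno` (n_mut x n_samples matrix
# of alternate-allele counts) and `pos` (0-based positions within the block,
# sorted). nlin = named lineage counts c(wolf=, indigenous=, chow=),
# mig = per-lineage backward migration rates list(wi=, ic=) already divided
# by 2N of the source population at phase-1 sizes.
sim_block_genotypes <- function(nlin, t_chow, t_wolf, N, mig_2Nm,
                                mu_site_gen, block_len) {
  ntot <- sum(nlin)
  nnodes <- 2L * ntot - 1L
  parent <- integer(nnodes)
  tm <- numeric(nnodes)
  # leaves: wolf block, then indigenous, then chow
  lin_id <- seq_len(ntot)
  lin_pop <- rep.int(1:3, nlin[c("wolf", "indigenous", "chow")])
  nxt <- ntot
  t <- 0
  phase <- 1L
  g_wi <- mig_2Nm[["wolf_indigenous"]]
  g_ic <- mig_2Nm[["indigenous_chow"]]

  advance_phase <- function() {
    if (phase == 1L && t >= t_chow) {
      lin_pop[lin_pop == 3L] <<- 2L      # breed merges into indigenous
      phase <<- 2L
    }
    if (phase == 2L && t >= t_wolf) {
      lin_pop[lin_pop == 2L] <<- 1L      # dogs merge into wolf
      phase <<- 3L
    }
  }
  advance_phase()

  while (length(lin_id) > 1L) {
    cnt <- tabulate(lin_pop, 3L)
    if (phase == 1L) {
      Ns <- c(N[["wolf"]], N[["indigenous"]], N[["chow"]])
      rates <- c(cnt * (cnt - 1) / 2 / (2 * Ns),
                 cnt[1] * g_wi / (2 * Ns[1]),   # wolf -> indigenous
                 cnt[2] * g_wi / (2 * Ns[2]),   # indigenous -> wolf
                 cnt[2] * g_ic / (2 * Ns[2]),   # indigenous -> chow
                 cnt[3] * g_ic / (2 * Ns[3]))   # chow -> indigenous
      boundary <- t_chow
    } else if (phase == 2L) {
      Ns <- c(N[["wolf"]], N[["ancestral_dog"]], Inf)
      rates <- c(cnt * (cnt - 1) / 2 / (2 * Ns),
                 cnt[1] * g_wi / (2 * Ns[1]),
                 cnt[2] * g_wi / (2 * Ns[2]), 0, 0)
      boundary <- t_wolf
    } else {
      Ns <- c(N[["root"]], Inf, Inf)
      rates <- c(cnt * (cnt - 1) / 2 / (2 * Ns), 0, 0, 0, 0)
      boundary <- Inf
    }
    R <- sum(rates)
    if (R == 0) {
      if (!is.finite(boundary)) stop("coalescent cannot complete")
      t <- boundary; advance_phase(); next
    }
    dt <- rexp(1L, R)
    if (t + dt >= boundary) {
      t <- boundary; advance_phase(); next
    }
    t <- t + dt
    ev <- sample.int(7L, 1L, prob = rates)
    if (ev <= 3L) {                       # coalescence in population ev
      idx <- which(lin_pop == ev)
      pair <- idx[sample.int(length(idx), 2L)]
      nxt <- nxt + 1L
      parent[lin_id[pair]] <- nxt
      tm[nxt] <- t
      lin_id <- c(lin_id[-pair], nxt)
      lin_pop <- c(lin_pop[-pair], ev)
    } else {                              # migration of one lineage
      from <- c(1L, 2L, 2L, 3L)[ev - 3L]
      to   <- c(2L, 1L, 3L, 2L)[ev - 3L]
      idx <- which(lin_pop == from)
      lin_pop[idx[sample.int(length(idx), 1L)]] <- to
    }
  }

  # infinite-sites mutations proportional to branch length (generations)
  blen <- numeric(nnodes)
  has_parent <- parent > 0L
  blen[has_parent] <- tm[parent[has_parent]] - tm[which(has_parent)]
  n_mut <- rpois(1L, sum(blen) * mu_site_gen * block_len)
  n_samples <- ntot %/% 2L
  if (n_mut == 0L)
    return(list(geno = matrix(integer(0), 0L, n_samples),
                pos = integer(0)))
  n_mut <- min(n_mut, block_len)          # infinite-sites at integer positions
  branch <- sample.int(nnodes, n_mut, replace = TRUE, prob = blen)

  # descendant leaf sets; children always have smaller ids than parents
  desc <- vector("list", nnodes)
  desc[seq_len(ntot)] <- as.list(seq_len(ntot))
  kids <- split(which(has_parent), parent[has_parent])
  for (id in (ntot + 1L):nnodes) {
    k <- kids[[as.character(id)]]
    desc[[id]] <- c(desc[[k[1L]]], desc[[k[2L]]])
  }

  geno <- matrix(0L, n_mut, n_samples)
  for (m in seq_len(n_mut)) {
    carriers <- desc[[branch[m]]]
    geno[m, ] <- tabulate((carriers + 1L) %/% 2L, nbins = n_samples)
  }
  pos <- sort(sample.int(block_len, n_mut)) - 1L
  list(geno = geno, pos = pos)
}
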