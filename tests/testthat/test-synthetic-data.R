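test_that("every generator is deterministic under its seed", {
  cfg <- sim_config(seed = 99, seq_length = 2e5, n_chrom = 1,
                    samples = c(wolf = 2, indigenous = 3, chow = 3))
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$geno, p2$geno)
  expect_identical(p1$pos, p2$pos)
  expect_identical(p1$ref, p2$ref)

  toy1 <- make_toy_genome(seed = 5)
  toy2 <- make_toy_genome(seed = 5)
  expect_identical(as.character(toy1$genome), as.character(toy2$genome))
  expect_identical(toy1$expected, toy2$expected)

  loci <- extract_loci(toy1$genome, toy1$sites, toy1$cfg)
  d1 <- make_depth_table(loci, c("a", "b"), seed = 2, cfg = toy1$cfg)
  d2 <- make_depth_table(loci, c("a", "b"), seed = 2, cfg = toy1$cfg)
  expect_identical(d1, d2)

  dirx <- tempfile(); t1 <- make_trace(dirx, seed = 8,
                                       truth = c(tau = 1e-5), n_iter = 5000)
  diry <- tempfile(); t2 <- make_trace(diry, seed = 8,
                                       truth = c(tau = 1e-5), n_iter = 5000)
  expect_identical(readLines(t1[1]), readLines(t2[1]))
})

test_that("zero split times give a panmictic panel with near-zero F_ST", {
  fsts <- vapply(1:4, function(s) {
    cfg <- sim_config(seed = 300 + s, split_wolf_years = 0,
                      split_chow_years = 0,
                      samples = c(wolf = 8, indigenous = 8, chow = 8),
                      seq_length = 1e6, n_chrom = 1)
    wc_fst_global(simulate_panel(cfg), "indigenous", "chow")$fst_raw
  }, numeric(1))
  se <- sd(fsts) / sqrt(length(fsts))
  expect_lt(abs(mean(fsts)), 2 * se + 0.005)
})

test_that("genome-wide F_ST grows with split time", {
  mean_fst <- function(years, seeds) {
    vapply(seeds, function(s) {
      cfg <- sim_config(seed = s, split_wolf_years = 60000,
                        split_chow_years = years,
                        samples = c(wolf = 4, indigenous = 8, chow = 8),
                        seq_length = 1e6, n_chrom = 1)
      wc_fst_global(simulate_panel(cfg), "indigenous", "chow")$fst_raw
    }, numeric(1))
  }
  f1 <- mean_fst(1000, 401:404)
  f2 <- mean_fst(10000, 401:404)
  f3 <- mean_fst(50000, 401:404)
  expect_gt(mean(f2), mean(f1))
  expect_gt(mean(f3), mean(f2))
})

test_that("sweep planting is an identity at strength 0 and fixes the core", {
  cfg <- sim_config(seed = 55, seq_length = 5e5, n_chrom = 1,
                    samples = c(wolf = 4, indigenous = 6, chow = 6))
  p <- simulate_panel(cfg)
  p0 <- plant_sweep(p, "chr1", 2.5e5, "chow", strength = 0)
  expect_identical(p0$geno, p$geno)

  p1 <- plant_sweep(p, "chr1", 2.5e5, "chow", strength = 1, radius = 1e5)
  core <- which(p1$chrom == "chr1" & abs(p1$pos - 2.5e5) <= 5e4)
  tgt <- pop_samples(p1, "chow")
  core_geno <- p1$geno[core, tgt]
  expect_true(all(apply(core_geno, 1, function(g)
    length(unique(g[!is.na(g)])) == 1)))
  # other populations untouched
  rest <- setdiff(p1$sample_ids, tgt)
  expect_identical(p1$geno[, rest], p$geno[, rest])
})

test_that("toy genomes plant sites and annotation with known ground truth", {
  toy <- make_toy_genome(seed = 77, n_chrom = 1, n_sites = 3,
                         tracks_spec = c(cpg = 0),
                         n_runs = 0)
  sites <- find_cut_sites(toy$genome, toy$cfg$motif)
  expect_equal(sites$pos, sort(toy$sites$pos))

  # a locus planted inside a repeat is expected rejected with that reason
  toy2 <- make_toy_genome(seed = 78)
  loci <- extract_loci(toy2$genome, toy2$sites, toy2$cfg)
  interior <- which(loci$status == "pass")[1]
  tr <- list("repeat" = interval_set("repeat", loci$chrom[interior],
                                     loci$locus_start[interior],
                                     loci$locus_end[interior]))
  expect_equal(
    filter_by_annotation(loci, tr, toy2$cfg)$reason[interior], "repeat")
})

test_that("depth tables at RAD-like coverage pass the depth filter", {
  toy <- make_toy_genome(seed = 91, tracks_spec = c(cpg = 0), n_runs = 0)
  loci <- extract_loci(toy$genome, toy$sites, toy$cfg)
  smp <- paste0("chow", 1:9)
  for (s in 1:10) {
    dt <- make_depth_table(loci, smp, seed = s, mean_depth = 36,
                           dropout = 0, cfg = toy$cfg)
    out <- filter_by_coverage(loci, dt, smp, toy$cfg)
    expect_equal(sum(out$reason == "coverage", na.rm = TRUE), 0)
  }
  # total dropout in one sample fails every locus
  dt0 <- make_depth_table(loci, "only", seed = 1, mean_depth = 36,
                          dropout = 0.999999, cfg = toy$cfg)
  dt0$only <- 0L
  out0 <- filter_by_coverage(loci, dt0, "only", toy$cfg)
  expect_true(all(out0$status[loci$status == "pass"] == "rejected"))
})

test_that("noise-free traces recover the truth exactly and pool consistently", {
  dirx <- tempfile()
  truth <- c(theta_chow = 2e-4, tau_chow = 1.826e-5)
  paths <- make_trace(dirx, seed = 10, truth = truth, n_iter = 20000,
                      noise = 0, n_replicates = 5)
  tr <- read_mcmc_trace(paths, burn_in = 2000, thinning = 10)
  s <- summarize_trace(tr)
  expect_equal(s$summary$mean, unname(truth))
  expect_equal(s$summary$q025, unname(truth))

  # pooled summary equals the summary of the concatenation
  one <- read_mcmc_trace(paths[1], burn_in = 2000, thinning = 10)
  expect_equal(summarize_trace(one)$summary$mean, s$summary$mean)
})
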