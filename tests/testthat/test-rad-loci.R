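test_that("the digest finds exactly the planted forward-strand motifs", {
  g <- Biostrings::DNAStringSet(c(chrA = plant_motif(1000, c(100, 400, 850))))
  sites <- find_cut_sites(g)
  expect_equal(sites$pos, c(100, 400, 850))
  expect_equal(sites$chrom, rep("chrA", 3))

  none <- Biostrings::DNAStringSet(c(c1 = strrep("AC", 500)))
  expect_equal(nrow(find_cut_sites(none)), 0)

  # ambiguity codes never match
  g_n <- Biostrings::DNAStringSet(c(c1 = paste0(strrep("G", 50), "ACTNGT",
                                                strrep("G", 50))))
  expect_equal(nrow(find_cut_sites(g_n)), 0)
})

test_that("the motif is its own reverse complement, so one strand suffices", {
  sq <- plant_motif(2000, c(300, 1200), seed = 4)
  g <- Biostrings::DNAStringSet(c(x = sq))
  rc <- Biostrings::reverseComplement(g[[1]])
  g_rc <- Biostrings::DNAStringSet(c(x = as.character(rc)))
  fwd <- find_cut_sites(g)$pos
  rev <- find_cut_sites(g_rc)$pos
  expect_equal(sort(nchar(sq) - 6 - rev), sort(fwd))
})

test_that("locus extraction joins flanks, trims ends and rejects edges", {
  cfg <- digest_config()
  sq <- plant_motif(1500, c(700, 50), seed = 7)
  g <- Biostrings::DNAStringSet(c(chr1 = sq))
  sites <- find_cut_sites(g)
  loci <- extract_loci(g, sites, cfg)

  edge <- loci[loci$cut_site == 50, ]
  expect_equal(edge$status, "rejected")
  expect_equal(edge$reason, "edge")

  ok <- loci[loci$cut_site == 700, ]
  expect_equal(ok$status, "pass")
  expect_equal(nchar(ok$sequence), 200)
  # direct slicing oracle: [pos - 100 + 3, pos + 6 + 100 - 3), 0-based
  expect_equal(ok$sequence, substr(sq, 700 - 100 + 3 + 1, 700 + 6 + 100 - 3))
  expect_equal(c(ok$locus_start, ok$locus_end), c(700 - 97, 700 + 103))

  # an N run inside the flank rejects the locus
  sq_n <- sq
  substr(sq_n, 651, 655) <- "NNNNN"
  g_n <- Biostrings::DNAStringSet(c(chr1 = sq_n))
  loci_n <- extract_loci(g_n, data.frame(chrom = "chr1", pos = 700), cfg)
  expect_equal(loci_n$reason, "edge")
})

test_that("annotation filters apply the distance rules literally", {
  cfg <- digest_config()
  loci <- data.frame(chrom = "chr1", cut_site = 500,
                     locus_start = 403, locus_end = 603,
                     sequence = "x", status = "pass",
                     reason = NA_character_, stringsAsFactors = FALSE)

  # empty tracks: everything passes
  expect_equal(filter_by_annotation(loci, list(), cfg)$status, "pass")

  # 1 bp of repeat overlap rejects
  rep1 <- list("repeat" = interval_set("repeat", "chr1", 602, 700))
  expect_equal(filter_by_annotation(loci, rep1, cfg)$reason, "repeat")
  rep0 <- list("repeat" = interval_set("repeat", "chr1", 603, 700))
  expect_equal(filter_by_annotation(loci, rep0, cfg)$status, "pass")

  # exons: >= 10 kb passes, 9,999 bp is rejected
  ex_ok <- list(exon = interval_set("exon", "chr1", 603 + 10000, 603 + 10100))
  expect_equal(filter_by_annotation(loci, ex_ok, cfg)$status, "pass")
  ex_no <- list(exon = interval_set("exon", "chr1", 603 + 9999, 603 + 10100))
  expect_equal(filter_by_annotation(loci, ex_no, cfg)$reason, "exon")

  # CNEs: exactly 100 bp is rejected, 101 bp passes
  cne_no <- list(cne = interval_set("cne", "chr1", 603 + 100, 603 + 180))
  expect_equal(filter_by_annotation(loci, cne_no, cfg)$reason, "cne")
  cne_ok <- list(cne = interval_set("cne", "chr1", 603 + 101, 603 + 180))
  expect_equal(filter_by_annotation(loci, cne_ok, cfg)$status, "pass")

  expect_error(filter_by_annotation(loci, list(bogus = cne_ok$cne), cfg),
               "unknown track")
})

test_that("thinning walks greedily and enforces the spacing", {
  mk <- function(pos, chrom = "chr1")
    data.frame(chrom = chrom, cut_site = pos, locus_start = pos - 97,
               locus_end = pos + 103, sequence = "x", status = "pass",
               reason = NA_character_, stringsAsFactors = FALSE)
  one <- thin_loci(mk(5000), spacing = 100000)
  expect_equal(one$status, "pass")

  three <- thin_loci(mk(c(0, 50000, 120000)), spacing = 100000)
  expect_equal(three$status, c("pass", "rejected", "pass"))
  expect_equal(three$reason[2], "spacing")

  set.seed(23)
  many <- thin_loci(mk(sort(sample.int(1e6, 60))), spacing = 100000)
  kept <- many$cut_site[many$status == "pass"]
  expect_true(all(diff(kept) >= 100000))
  # chromosomes thin independently
  two_chr <- thin_loci(rbind(mk(1000), mk(2000, "chr2")), spacing = 100000)
  expect_equal(two_chr$status, c("pass", "pass"))
})

test_that("coverage requires every flank base at depth in every sample", {
  cfg <- digest_config(flank = 3, trim = 1, min_depth = 5)
  loci <- data.frame(chrom = "chr1", cut_site = 10,
                     locus_start = 8, locus_end = 18,
                     sequence = "x", status = "pass",
                     reason = NA_character_, stringsAsFactors = FALSE)
  fp <- c(7:9, 16:18)
  dt <- data.frame(chrom = "chr1", pos = fp, s1 = 5L, s2 = 9L)
  expect_equal(filter_by_coverage(loci, dt, c("s1", "s2"), cfg)$status,
               "pass")  # bound is inclusive
  dt2 <- dt; dt2$s1[4] <- 4L
  expect_equal(filter_by_coverage(loci, dt2, c("s1", "s2"), cfg)$reason,
               "coverage")
  expect_error(filter_by_coverage(loci, dt, c("s1", "s3"), cfg), "missing")
})

test_that("export writes FASTA for passers and a complete audit", {
  toy <- make_toy_genome(seed = 21)
  loci <- rad_pipeline(toy$genome, toy$tracks, cfg = toy$cfg)
  prefix <- tempfile("loci")
  out <- suppressMessages(export_loci(loci, prefix))
  fa <- readLines(out$fasta)
  n_pass <- sum(loci$status == "pass")
  expect_equal(sum(grepl("^>", fa)), n_pass)
  audit <- read.table(out$audit, header = TRUE, sep = "\t")
  expect_equal(nrow(audit), nrow(loci))
  expect_equal(sum(out$counts), nrow(loci))   # reasons partition the loci

  empty <- loci; empty$status <- "rejected"; empty$reason <- "edge"
  out2 <- suppressMessages(export_loci(empty, tempfile("loci0")))
  expect_equal(length(readLines(out2$fasta)), 0)
  expect_equal(nrow(read.table(out2$audit, header = TRUE, sep = "\t")),
               nrow(loci))
})

test_that("the cascade agrees with the brute-force predicate evaluator", {
  for (s in c(101, 102, 103, 104, 105)) {
    toy <- make_toy_genome(seed = s)
    loci <- rad_pipeline(toy$genome, toy$tracks, cfg = toy$cfg)
    expect_equal(loci$cut_site, toy$expected$pos)   # conservation: one row
    expect_equal(loci$status, toy$expected$status)  # per digested site
    expect_equal(loci$reason, toy$expected$reason)
  }
})

test_that("coverage-rejected loci cannot shadow a passing neighbour", {
  # two sites closer than the spacing: the first fails coverage, so the
  # second must be kept (thinning runs after the coverage filter)
  cfg <- digest_config(flank = 3, trim = 1, min_depth = 5, spacing = 50)
  mk <- function(pos)
    data.frame(chrom = "chr1", cut_site = pos, locus_start = pos - 2,
               locus_end = pos + 8, sequence = "x", status = "pass",
               reason = NA_character_, stringsAsFactors = FALSE)
  loci <- rbind(mk(10), mk(40))
  fp <- function(pos) c((pos - 3):(pos - 1), (pos + 6):(pos + 8))
  dt <- data.frame(chrom = "chr1", pos = c(fp(10), fp(40)),
                   s1 = c(rep(2L, 6), rep(9L, 6)))
  out <- thin_loci(filter_by_coverage(loci, dt, "s1", cfg), cfg$spacing)
  expect_equal(out$status, c("rejected", "pass"))
  expect_equal(out$reason[1], "coverage")
})
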