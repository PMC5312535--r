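test_that("read_vcf parses genotypes, drops non-biallelic records, maps missing", {
  f <- tempfile(fileext = ".vcf")
  gt <- rbind(c("0/0", "0/1", "1/1"),
              c("0/1", "0/1", "0/0"),
              c("1/1", "./.", "0/0"),
              c("0|1", "1|1", "0|0"),
              c("0/0", "0/0", "0/1"))
  write_test_vcf(f, chrom = rep("chr1", 5), pos = c(10, 25, 40, 41, 90),
                 ref = rep("A", 5), alt = rep("T", 5), gt = gt,
                 samples = c("a", "b", "c"))
  pm <- c(a = "pop1", b = "pop1", c = "pop2")
  p <- read_vcf(f, pm)
  expect_equal(n_sites(p), 5L)
  expect_equal(dim(p$geno), c(5L, 3L))
  expect_equal(p$pos, c(10, 25, 40, 41, 90) - 1L)  # 0-based internally
  expect_equal(unname(p$geno[1, ]), c(0L, 1L, 2L))
  expect_true(is.na(p$geno[3, "b"]))
  expect_equal(unname(p$geno[4, ]), c(1L, 2L, 0L))  # phased bars accepted

  # tri-allelic and indel records are absent, with a reported drop count
  f2 <- tempfile(fileext = ".vcf")
  write_test_vcf(f2, chrom = rep("chr1", 3), pos = c(5, 6, 7),
                 ref = c("A", "C", "CT"), alt = c("G", "G,T", "C"),
                 gt = matrix("0/1", 3, 3), samples = c("a", "b", "c"))
  expect_message(p2 <- read_vcf(f2, pm), "dropped 2")
  expect_equal(n_sites(p2), 1L)
  expect_equal(p2$pos, 4L)

  # samples missing from the population map
  expect_error(read_vcf(f, c(a = "pop1", b = "pop1")), "absent")
  p3 <- read_vcf(f, c(a = "pop1", b = "pop1"), on_unmapped = "drop")
  expect_equal(p3$sample_ids, c("a", "b"))
})

test_that("a panel round-trips through VCF exactly", {
  cfg <- sim_config(seed = 11, seq_length = 1e5, n_chrom = 1,
                    samples = c(wolf = 2, indigenous = 3, chow = 3),
                    depth_mean = 20)
  p <- simulate_panel(cfg)
  f <- tempfile(fileext = ".vcf")
  write_vcf(p, f)
  p2 <- read_vcf(f, p$pop_labels)
  expect_identical(p2$geno, p$geno)
  expect_identical(p2$pos, p$pos)
  expect_identical(p2$ref, p$ref)
  expect_identical(p2$alt, p$alt)
  expect_equal(unname(p2$depth), unname(p$depth))
})

test_that("read_intervals normalises BED and GFF3 to the same 0-based intervals", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", bed)
  x <- read_intervals(bed, "bed", name = "custom")
  expect_equal(as.data.frame(x),
               data.frame(chrom = "chr1", start = 10, end = 20))

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\texon\t11\t20\t.\t+\t.\tID=e1"), gff)
  y <- read_intervals(gff, "gff3", name = "exon")
  # the same physical interval encoded both ways compares equal
  expect_equal(as.data.frame(y), as.data.frame(x))

  # overlapping intervals merge within a track
  bed2 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t15\t30"), bed2)
  z <- read_intervals(bed2, "bed", name = "repeat")
  expect_equal(as.data.frame(z),
               data.frame(chrom = "chr1", start = 10, end = 30))

  # gene tracks keep ids and skip merging
  bed3 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tgeneA", "chr1\t15\t30\tgeneB"), bed3)
  g <- read_intervals(bed3, "bed", name = "gene")
  expect_equal(as.data.frame(g)$id, c("geneA", "geneB"))
  expect_equal(length(g), 2L)
})

test_that("interval reading is idempotent through a write/read cycle", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr2\t5\t50", "chr1\t10\t20", "chr1\t18\t40"), bed)
  x <- read_intervals(bed, "bed", name = "cpg")
  out <- tempfile(fileext = ".bed")
  write_bed(x, out)
  y <- read_intervals(out, "bed", name = "cpg")
  expect_equal(as.data.frame(y), as.data.frame(x))
})

test_that("read_score_track keeps scores, ignores extras, sorts on demand", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("position\tLR\talpha",
               "100\t1.5\t0.1", "200\t2.5\t0.2", "300\t0.5\t0.3"), f)
  st <- read_score_track(f)
  expect_equal(st$pos, c(100, 200, 300))
  expect_equal(st$score, c(1.5, 2.5, 0.5))
  expect_equal(attr(st, "kind"), "clr")

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("position\tLR", "300\t0.5", "100\t1.5", "200\t2.5"), f2)
  expect_warning(st2 <- read_score_track(f2), "unsorted")
  expect_equal(st2$pos, c(100, 200, 300))
  expect_equal(st2$score, c(1.5, 2.5, 0.5))

  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("position\tLR", "100\tnot_a_number"), f3)
  expect_error(read_score_track(f3))
})

test_that("read_mcmc_trace removes burn-in per replicate before pooling", {
  dirx <- tempfile(); dir.create(dirx)
  mk <- function(path, n, start = 0) {
    write.table(data.frame(Sample = seq_len(n) * 10,
                           theta = start + seq_len(n),
                           tau = 2 * seq_len(n)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  f1 <- file.path(dirx, "r1.tsv"); mk(f1, 1000)
  tr <- read_mcmc_trace(f1, burn_in = 1000, thinning = 10)
  expect_equal(nrow(tr$samples), 900)           # 100 rows of burn-in removed
  expect_equal(tr$samples$theta[1], 101)

  fs <- file.path(dirx, paste0("rep", 1:5, ".tsv"))
  for (i in 1:5) mk(fs[i], 200, start = i * 1000)
  tr5 <- read_mcmc_trace(fs, burn_in = 500, thinning = 10)
  expect_equal(nrow(tr5$samples), 5 * (200 - 50))
  expect_equal(sort(unique(tr5$samples$replicate)), 1:5)

  bad <- file.path(dirx, "bad.tsv")
  write.table(data.frame(Sample = 1:10 * 10, other = 1:10), bad,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mcmc_trace(c(f1, bad), burn_in = 0), "mismatched")
})
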