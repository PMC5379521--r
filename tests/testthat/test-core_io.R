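test_that("read_fasta normalizes, preserves order, and rejects duplicates", {
  f <- withr::local_tempfile(lines = c(">a extra words", "acgu", ">b", "TT"))
  recs <- read_fasta(f)
  expect_equal(unname(recs["a"]), "ACGT")
  expect_equal(names(recs), c("a", "b"))
  expect_equal(unname(attr(recs, "alphabet")["a"]), "RNA")
  expect_equal(unname(attr(recs, "alphabet")["b"]), "DNA")

  dup <- withr::local_tempfile(lines = c(">a", "ACGT", ">a", "TT"))
  expect_error(read_fasta(dup), "duplicate.*a")
  empty <- withr::local_tempfile(lines = character(0))
  expect_error(read_fasta(empty))
})

test_that("fasta round trip is the identity on normalized records", {
  set.seed(11)
  seqs <- stats::setNames(vapply(1:5, function(i) rand_dna(30), ""),
                          paste0("s", 1:5))
  f <- withr::local_tempfile()
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(as.vector(unname(back)), as.vector(unname(seqs)))
  expect_equal(names(back), names(seqs))
  # RNA records round trip through U
  attr(seqs, "alphabet") <- stats::setNames(rep("RNA", 5), names(seqs))
  write_fasta(seqs, f)
  expect_true(grepl("U", readLines(f)[2]))
  expect_equal(as.vector(unname(read_fasta(f))), as.vector(unname(seqs)))
})

test_that("collapsed reads parse in all three dialects and reject bad counts", {
  f1 <- withr::local_tempfile(lines = c(">r1_x57", "TGACAGAAGAGAGTGAGCAC"))
  r1 <- read_collapsed_reads(f1, "header_xN")
  expect_equal(r1$count, 57L)
  expect_equal(r1$seq, "TGACAGAAGAGAGTGAGCAC")

  f2 <- withr::local_tempfile(lines = c(">r1 count=12", "ACGTACGTACGT"))
  expect_equal(read_collapsed_reads(f2, "header_count")$count, 12L)

  f3 <- withr::local_tempfile(lines = "TGACAGAAGAGAGTGAGCAC\t12")
  expect_equal(read_collapsed_reads(f3, "tsv")$count, 12L)

  f4 <- withr::local_tempfile(lines = c(">r1_x0", "ACGTACGTACGT"))
  expect_error(read_collapsed_reads(f4, "header_xN"), "non-positive")
  f5 <- withr::local_tempfile(lines = c(">r1", "ACGTACGTACGT"))
  expect_error(read_collapsed_reads(f5, "header_xN"), "record 1")
})

write_test_vcf <- function(path, rows,
                           samples = c("s1", "s2", "s3", "s4")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), path)
}

test_that("read_variants computes per-group frequencies from genotypes", {
  f <- withr::local_tempfile()
  write_test_vcf(f, paste(c("chr1", "100", ".", "C", "G", ".", "PASS", ".",
                            "GT", "0/0", "0/1", "1/1", "1/1"),
                          collapse = "\t"))
  gm <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  v <- read_variants(f, gm)
  expect_equal(nrow(v), 1L)
  expect_equal(v$freqs[[1]]$A[["C"]], 0.75)
  expect_equal(v$freqs[[1]]$A[["G"]], 0.25)
  expect_equal(v$freqs[[1]]$B[["G"]], 1.0)
  expect_equal(v$an, 8)
  expect_error(read_variants(f, c(sX = "A")), "sX")
})

test_that("read_variants skips indels, handles missing calls and degenerate alleles", {
  f <- withr::local_tempfile()
  write_test_vcf(f, c(
    paste(c("chr1", "10", ".", "C", "CA", ".", "PASS", ".", "GT",
            "0/0", "0/1", "0/0", "0/0"), collapse = "\t"),
    paste(c("chr1", "20", ".", "A", "G", ".", "PASS", ".", "GT",
            "./.", "./.", "0/1", "0/0"), collapse = "\t"),
    paste(c("chr1", "30", ".", "A", "R", ".", "PASS", ".", "GT",
            "0/0", "0/0", "1/1", "0/0"), collapse = "\t")))
  gm <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  v <- read_variants(f, gm)
  expect_equal(attr(v, "n_indels_skipped"), 1L)
  expect_equal(nrow(v), 2L)
  # all group-A calls missing at pos 20: empty freqs, record retained
  expect_length(v$freqs[[1]]$A, 0)
  expect_equal(v$freqs[[1]]$B[["G"]], 0.25)
  # degenerate R expands to half A / half G
  expect_equal(unname(v$counts[[2]][c("A", "G")]), c(7, 1))
})

test_that("allele frequencies are invariant under sample order permutation", {
  row <- paste(c("chr1", "100", ".", "C", "G", ".", "PASS", ".", "GT",
                 "0/0", "0/1", "1/1", "1/1"), collapse = "\t")
  f <- withr::local_tempfile()
  write_test_vcf(f, row)
  gm <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  v1 <- read_variants(f, gm)
  v2 <- read_variants(f, gm[c(3, 1, 4, 2)])
  expect_identical(v1$freqs[[1]], v2$freqs[[1]][names(v1$freqs[[1]])])
})

test_that("extract_interval honors strand and bounds", {
  genome <- c(chrA = "AACCGGTT")
  expect_equal(extract_interval(genome, "chrA", 0, 4, "+"), "AACC")
  expect_equal(extract_interval(genome, "chrA", 0, 4, "-"), "GGTT")
  expect_error(extract_interval(genome, "chrA", 6, 10), "out of bounds")
  # plus-strand extraction is the reverse complement of minus-strand
  set.seed(3)
  g2 <- c(c1 = rand_dna(100))
  for (i in 1:10) {
    s <- sample(0:80, 1); e <- s + sample(5:20, 1)
    expect_equal(extract_interval(g2, "c1", s, e, "+"),
                 revcomp(extract_interval(g2, "c1", s, e, "-")))
  }
})
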