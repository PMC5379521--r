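test_that("pi_from_haplotypes matches its definition on forced cases", {
  expect_equal(pi_from_haplotypes(c("ACGT", "ACGT")), 0)
  expect_equal(pi_from_haplotypes(c("ACGT", "ACGA")), 0.25)
  expect_error(pi_from_haplotypes("ACGT"), "at least 2")
  expect_error(pi_from_haplotypes(c("ACGT", "ACG")), "length")
  # N columns excluded from numerator and denominator
  expect_equal(pi_from_haplotypes(c("ACNT", "ACNA")), 1 / 3)
})

test_that("pi_from_haplotypes equals the pairwise double-loop oracle", {
  set.seed(31)
  for (case in 1:25) {
    n <- sample(3:8, 1)
    L <- sample(20:60, 1)
    seqs <- vapply(seq_len(n), function(i) rand_dna(L), "")
    expect_equal(pi_from_haplotypes(seqs), oracle_pi(seqs),
                 tolerance = 1e-12)
  }
})

test_that("pi is invariant under haplotype order and allele relabeling", {
  set.seed(32)
  seqs <- vapply(1:6, function(i) rand_dna(50), "")
  expect_equal(pi_from_haplotypes(seqs), pi_from_haplotypes(rev(seqs)))
  relabeled <- chartr("ACGT", "GTAC", seqs)
  expect_equal(pi_from_haplotypes(seqs), pi_from_haplotypes(relabeled))
})

test_that("pi_from_variants applies the unbiased per-site estimator", {
  v <- make_variant_df("chr1", 50L,
                       list(c(A = 2, C = 0, G = 2, T = 0)))
  iv <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  expect_equal(pi_from_variants(v, iv), (4 / 3 * 0.5) / 100,
               tolerance = 1e-12)
  # no variants inside the interval
  expect_equal(pi_from_variants(v[0, ], iv), 0)
  # all calls missing: contributes zero
  v0 <- make_variant_df("chr1", 50L, list(c(A = 0, C = 0, G = 0, T = 0)),
                        an = 0)
  expect_equal(pi_from_variants(v0, iv, n_haplotypes = 4), 0)
  expect_error(pi_from_variants(v, iv[0, ]), "length")
})

test_that("variant-based pi equals haplotype-based pi on complete matrices", {
  set.seed(33)
  for (case in 1:25) {
    n <- sample(4:10, 1)
    L <- sample(50:200, 1)
    haps <- vapply(seq_len(n), function(i) rand_dna(L), "")
    mat <- do.call(rbind, strsplit(haps, ""))
    segregating <- which(apply(mat, 2, function(cl) length(unique(cl)) > 1))
    counts <- lapply(segregating, function(p) {
      cnt <- stats::setNames(numeric(4), c("A", "C", "G", "T"))
      tb <- table(mat[, p])
      cnt[names(tb)] <- as.numeric(tb)
      cnt
    })
    v <- make_variant_df("c", as.integer(segregating), counts)
    iv <- data.frame(chrom = "c", start = 0L, end = L)
    expect_equal(pi_from_variants(v, iv), pi_from_haplotypes(haps),
                 tolerance = 1e-12)
  }
})

test_that("classify_loci clips flanks, merges overlaps and splits by class", {
  loci <- data.frame(
    id = c("m1", "m2"), chrom = c("chr1", "chr1"),
    start = c(5000L, 5050L), end = c(5100L, 5150L), strand = c("+", "+"),
    mature_seq = c(strrep("A", 21), strrep("C", 21)),
    class_label = c("conserved", "specific_candidate"),
    mature_offset = c(0L, 0L), stringsAsFactors = FALSE)
  cls <- classify_loci(loci, genome_lengths = c(chr1 = 6000L), flank = 2000L)
  fl <- cls[cls$class_name == "flank_2kb" & cls$group == "conserved_known", ]
  expect_equal(fl$start, c(3000L, 5100L))
  expect_equal(fl$end, c(5000L, 6000L))   # clipped at the chromosome end
  expect_true("genome_background" %in% cls$class_name)
  expect_setequal(unique(cls$group[cls$class_name == "precursor"]),
                  c("conserved_known", "specific"))
  # overlapping intervals within one class merge
  loci2 <- loci
  loci2$class_label <- c("conserved", "known")
  cls2 <- classify_loci(loci2, genome_lengths = c(chr1 = 6000L))
  prec <- cls2[cls2$class_name == "precursor", ]
  expect_equal(nrow(prec), 1L)
  expect_equal(prec$start, 5000L)
  expect_equal(prec$end, 5150L)
})

test_that("binding sites lift through gene models strand-aware", {
  loci <- data.frame(id = "m1", chrom = "chr1", start = 10L, end = 80L,
                     strand = "+", mature_seq = strrep("A", 21),
                     class_label = "conserved", mature_offset = 0L,
                     stringsAsFactors = FALSE)
  interactions <- data.frame(mirna_id = "m1",
                             transcript_id = c("t_plus", "t_minus", "t_none"),
                             site_start = 11L, site_end = 20L,
                             stringsAsFactors = FALSE)
  gm <- data.frame(transcript_id = c("t_plus", "t_minus"),
                   chrom = "chr1", start = c(1000L, 2000L),
                   end = c(1500L, 2500L), strand = c("+", "-"),
                   stringsAsFactors = FALSE)
  cls <- classify_loci(loci, interactions, gm,
                       genome_lengths = c(chr1 = 6000L))
  bs <- cls[cls$class_name == "binding_site", ]
  expect_equal(sort(bs$start), c(1010L, 2480L))
  expect_equal(sort(bs$end), c(1020L, 2490L))
  expect_equal(attr(cls, "n_sites_unliftable"), 1L)
})

test_that("permutation p-value follows the add-one formula", {
  # a class interval with no variants against a variant-dense background:
  # every null draw has pi >= 0, observed is 0 and ties count as <=
  set.seed(34)
  pos <- seq(10L, 4990L, by = 10L)
  v <- make_variant_df("chr1", pos,
                       replicate(length(pos),
                                 c(A = 5, C = 5, G = 0, T = 0),
                                 simplify = FALSE))
  # exclude exactly the class window from the variant set
  v <- v[v$pos <= 4100L | v$pos > 4900L, , drop = FALSE]
  cls <- data.frame(chrom = "chr1", start = 4100L, end = 4900L)
  res <- permutation_test_pi(cls, v, c(chr1 = 5000L), n_perm = 99L,
                             seed = 5L)
  expect_equal(res$observed_pi, 0)
  expect_true(all(res$null_pi > 0))
  expect_equal(res$p, 1 / 100)
  expect_error(permutation_test_pi(cls, v, c(chr1 = 5000L), n_perm = 0L),
               "n_perm")
})

test_that("diversity_table reports a row per class with seeds recorded", {
  set.seed(35)
  loci <- data.frame(id = "m1", chrom = "chr1", start = 500L, end = 560L,
                     strand = "+", mature_seq = strrep("A", 21),
                     class_label = "conserved", mature_offset = 0L,
                     stringsAsFactors = FALSE)
  pos <- sort(sample(1:5000, 80))
  v <- make_variant_df("chr1", as.integer(pos),
                       replicate(80, c(A = 7, C = 3, G = 0, T = 0),
                                 simplify = FALSE))
  cls <- classify_loci(loci, genome_lengths = c(chr1 = 5000L), flank = 300L)
  dt <- diversity_table(cls, v, c(chr1 = 5000L), n_perm = 49L, seed = 9L)
  expect_true(all(dt$pi >= 0 & dt$pi <= 1))
  expect_true(all(is.na(dt$perm_p) | dt$perm_p > 0))
  expect_true("genome_background" %in% dt$class_name)
  expect_equal(unique(dt$seed), 9L)
  # determinism
  dt2 <- diversity_table(cls, v, c(chr1 = 5000L), n_perm = 49L, seed = 9L)
  expect_identical(dt, dt2)
})
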