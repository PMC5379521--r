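test_that("apply_variants substitutes, validates, and is invertible", {
  out <- apply_variants("AAAA", data.frame(pos = 2L, ref = "A", alt = "G"))
  expect_equal(out$variant_seq, "AGAA")
  out0 <- apply_variants("AAAA", data.frame(pos = integer(0),
                                            ref = character(0),
                                            alt = character(0)))
  expect_equal(out0$variant_seq, "AAAA")
  expect_error(apply_variants("AAAA", data.frame(pos = 2L, ref = "C",
                                                 alt = "G")),
               "mismatch at position 2")
  expect_error(apply_variants("AAAA", data.frame(pos = 9L, ref = "A",
                                                 alt = "G")),
               "outside")
  # applying the inverse recovers the original
  set.seed(51)
  for (case in 1:10) {
    s <- rand_dna(40)
    pos <- sort(sample(40, 3))
    refs <- substring(s, pos, pos)
    alts <- vapply(refs, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                            1), "")
    fwd <- apply_variants(s, data.frame(pos = pos, ref = refs, alt = alts))
    back <- apply_variants(fwd$variant_seq,
                           data.frame(pos = pos, ref = alts, alt = refs))
    expect_equal(back$variant_seq, s)
  }
})

test_that("build_snp_mirna lifts genomic SNPs strand-aware", {
  mature <- "TGACAGAAGAGAGTGAGCACA"
  # plus strand: mature occupies genome [100, 121); SNP at genomic 113
  # maps to mature-local 13
  v <- make_variant_df("chr1", 113L, list(c(A = 0, C = 2, G = 8, T = 0)))
  v$freqs <- list(list(A = c(G = 0.2, C = 0.8), B = c(C = 1.0)))
  got <- build_snp_mirna(mature, "chr1", 100L, 121L, "+", v, "B")
  expect_length(got, 1L)
  expect_equal(got[[1]]$applied$pos, 13L)
  expect_equal(substr(got[[1]]$variant_seq, 13, 13), "C")

  # minus strand: genomic allele complements into mature space
  # local = mature_end - pos + 1 = 121 - 113 + 1 = 9; mature base 9 is G,
  # genomic plus-strand base is its complement C; group-B major T -> local A
  vm <- make_variant_df("chr1", 113L, list(c(A = 0, C = 2, G = 0, T = 8)))
  vm$freqs <- list(list(A = c(C = 1.0), B = c(T = 1.0)))
  gotm <- build_snp_mirna(mature, "chr1", 100L, 121L, "-", vm, "B")
  expect_equal(gotm[[1]]$applied$pos, 9L)
  expect_equal(gotm[[1]]$applied$alt, "A")

  # group carrying only the reference allele yields no snp-miRNA
  vr <- make_variant_df("chr1", 113L, list(c(A = 0, C = 0, G = 10, T = 0)))
  vr$freqs <- list(list(A = c(G = 1.0), B = c(G = 1.0)))
  expect_length(build_snp_mirna(mature, "chr1", 100L, 121L, "+", vr, "B"), 0L)
})

test_that("mature position 14 C->G SNP yields a snp-miRNA differing only there", {
  set.seed(52)
  mature <- paste0(rand_dna(13), "C", rand_dna(7))
  v <- make_variant_df("chr2", 214L, list(c(A = 0, C = 4, G = 6, T = 0)))
  v$freqs <- list(list(china = c(G = 0.56, C = 0.40), india = c(C = 1.0)))
  got <- build_snp_mirna(mature, "chr2", 200L, 221L, "+", v, "china")
  expect_length(got, 1L)
  expect_equal(got[[1]]$applied$pos, 14L)
  same <- mapply(function(a, b) a == b,
                 strsplit(mature, "")[[1]],
                 strsplit(got[[1]]$variant_seq, "")[[1]])
  expect_equal(unname(which(!same)), 14L)
})

test_that("diff_targets classifies conserved, disrupted and created sites", {
  a <- find_sites("TGACAGAAGAGAGTGAGCACA",
                  plant_binding_site(rand_dna(200), "TGACAGAAGAGAGTGAGCACA",
                                     0, 100)$transcript,
                  transcript_id = "T1")
  expect_equal(diff_targets(a, a)$status, "conserved")
  d1 <- diff_targets(a, a[0, ])
  expect_equal(d1$status, "disrupted")
  d2 <- diff_targets(a[0, ], a)
  expect_equal(d2$status, "created")
  expect_equal(nrow(diff_targets(a[0, ], a[0, ])), 0L)
})

test_that("align_global identity matches hand values and the DP oracle", {
  set.seed(53)
  s <- rand_dna(10)
  expect_equal(align_global(s, s)$identity, 1.0)
  s2 <- strsplit(s, "")[[1]]
  s2[4] <- setdiff(c("A", "C", "G", "T"), s2[4])[1]
  expect_equal(align_global(s, paste(s2, collapse = ""))$identity, 0.9)
  expect_error(align_global("", s), "empty")
  for (case in 1:15) {
    a <- rand_dna(sample(6:12, 1))
    b <- rand_dna(sample(6:12, 1))
    expect_equal(align_global(a, b)$score, oracle_nw_score(a, b),
                 info = paste(a, b))
  }
})

test_that("ortholog validation needs >90% identity plus site containment", {
  set.seed(54)
  mir <- "TGACAGAAGAGAGTGAGCACA"
  base <- plant_binding_site(rand_dna(200), mir, 0, 90)
  snp_mrna <- base$transcript
  # verbatim orthologue: accepted
  ov <- ortholog_validate(snp_mrna, c(o1 = snp_mrna), mir, 90, 110)
  expect_true(ov$accepted)
  expect_equal(ov$identity, 1.0)
  # identity exactly 0.90 is rejected (rule is strictly greater)
  ov90 <- ortholog_validate(snp_mrna, c(o1 = snp_mrna), mir, 90, 110,
                            min_identity = 1.0)
  expect_false(ov90$accepted)
  # heavily diverged orthologue: rejected on identity
  div <- strsplit(snp_mrna, "")[[1]]
  idx <- setdiff(seq_along(div), 90:110)
  flip <- sample(idx, 60)
  for (i in flip) div[i] <- sample(setdiff(c("A", "C", "G", "T"), div[i]), 1)
  ovd <- ortholog_validate(snp_mrna, c(o1 = paste(div, collapse = "")),
                           mir, 90, 110)
  expect_false(ovd$accepted)
  expect_lt(ovd$identity, 0.90)
  # high identity but site region destroyed: rejected on containment
  nosite <- strsplit(snp_mrna, "")[[1]]
  for (i in seq(92, 108, by = 2)) {
    nosite[i] <- sample(setdiff(c("A", "C", "G", "T"), nosite[i]), 1)
  }
  ovn <- ortholog_validate(snp_mrna, c(o1 = paste(nosite, collapse = "")),
                           mir, 90, 110)
  expect_false(ovn$site_contained)
  expect_false(ovn$accepted)
  expect_error(ortholog_validate(snp_mrna, character(0), mir, 90, 110),
               "empty")
})

test_that("the identity threshold is exclusive at 0.90", {
  # 1000-column alignments engineered to sit exactly at and just above 0.90
  a <- strrep("A", 1000)
  mk <- function(n_diff) {
    ch <- strsplit(a, "")[[1]]
    ch[seq_len(n_diff)] <- "C"
    paste(ch, collapse = "")
  }
  al900 <- align_global(a, mk(100))
  expect_equal(al900$identity, 0.900)
  al901 <- align_global(a, mk(99))
  expect_equal(al901$identity, 0.901)
  expect_false(al900$identity > 0.90)
  expect_true(al901$identity > 0.90)
})

test_that("group-unique calls count disrupted as A-unique and created as B-unique", {
  deltas <- data.frame(
    mirna_id = paste0("m", 1:6), transcript_id = paste0("t", 1:6),
    status = c("disrupted", "disrupted", "disrupted", "created", "created",
               "conserved"),
    cause = "target_snp", ref_score = 1, alt_score = 2,
    ref_start = 1L, ref_end = 21L, alt_start = 1L, alt_end = 21L,
    stringsAsFactors = FALSE)
  res <- call_group_unique_targets(deltas, "9930", "hardwickii")
  expect_equal(res$counts$n_unique, c(3L, 2L))
  # swapping the labels swaps the columns exactly
  res2 <- call_group_unique_targets(deltas, "hardwickii", "9930")
  expect_equal(res2$counts$n_unique, c(3L, 2L))
  expect_equal(res2$counts$group, c("hardwickii", "9930"))
  expect_error(call_group_unique_targets(deltas, NA_character_, "x"),
               "group")
  none <- call_group_unique_targets(deltas[deltas$status == "conserved", ])
  expect_equal(none$counts$n_unique, c(0L, 0L))
})

test_that("delta scores are reproducible from the allele sequences", {
  set.seed(55)
  cfg <- scenario_config(seed = 404, n_mirnas = 3L, n_transcripts = 7L,
                         n_planted_sites = 3L, n_a_unique = 1L,
                         n_b_unique = 1L, n_neutral = 0L,
                         chrom_length = 6000L)
  b <- make_scenario(cfg)
  res <- snp_impact_analysis(b$hairpins, b$transcripts_a, b$gene_models,
                             b$variants, ortholog_seqs = b$transcripts_b)
  mir_a <- stats::setNames(b$hairpins$mature_seq, b$hairpins$id)
  for (r in seq_len(nrow(res$deltas))) {
    d <- res$deltas[r, ]
    if (!is.na(d$ref_score)) {
      expect_equal(score_duplex(mir_a[[d$mirna_id]],
                                substr(b$transcripts_a[[d$transcript_id]],
                                       d$ref_start, d$ref_end))$score,
                   d$ref_score)
    }
    if (!is.na(d$alt_score)) {
      expect_equal(score_duplex(res$mirnas_b[[d$mirna_id]],
                                substr(res$transcripts_b[[d$transcript_id]],
                                       d$alt_start, d$alt_end))$score,
                   d$alt_score)
    }
  }
  # planted events recovered exactly
  expect_equal(res$unique_targets$counts$n_unique, c(1L, 1L))
})
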