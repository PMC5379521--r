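test_that("filter_reads applies the 16-30 nt window and exclusion sets", {
  set.seed(21)
  reads <- data.frame(
    seq = c(rand_dna(15), rand_dna(16), rand_dna(30), rand_dna(31),
            "TGACAGAAGAGAGTGAGCAC", rand_dna(24)),
    count = c(5L, 5L, 5L, 5L, 5L, 5L), library_id = "lib1",
    stringsAsFactors = FALSE)
  excl <- list(rrna = paste0("GGG", "TGACAGAAGAGAGTGAGCAC", "CCC"))
  out <- filter_reads(reads, 16, 30, excl)
  expect_equal(nrow(out$kept), 3L)
  expect_setequal(out$rejected$reason[c(1, 2)], "length")
  expect_equal(out$rejected$reason[3], "contaminant:rrna")
  expect_error(filter_reads(reads, 30, 16), "min_len")
})

test_that("match_conserved enforces the two-mismatch rule with Hamming only", {
  refs <- c(miR156 = "TGACAGAAGAGAGTGAGCAC", miR159 = "TTTGGATTGAAGGGAGCTCT")
  expect_equal(match_conserved("TGACAGAAGAGAGTGAGCAC", refs)$ref_id, "miR156")
  expect_equal(match_conserved("TGACAGAAGAGAGTGAGCAC", refs)$mismatches, 0L)
  two <- "TAACAGAAGAGAGTGAGCAT"      # distance 2
  expect_equal(match_conserved(two, refs)$mismatches, 2L)
  three <- "TAACAGAAGAGAGTGAGCTT"    # distance 3
  expect_null(match_conserved(three, refs))
  # length difference: no assignment even if a prefix matches
  expect_null(match_conserved("TGACAGAAGAGAGTGAGCA", refs))
  # tie goes to the first reference in file order
  refs2 <- c(a = "AAAA", b = "AAAA")
  expect_equal(match_conserved("AAAT", refs2, 2)$ref_id, "a")
  expect_error(match_conserved("AAAA", character(0)), "empty")
})

test_that("count_genome_matches counts both strands, overlapping, and errors on short reads", {
  set.seed(22)
  read <- rand_dna(21)
  genome <- c(chr1 = paste0(rand_dna(50), read, rand_dna(50)),
              chr2 = paste0(rand_dna(30), revcomp(read), rand_dna(30),
                            revcomp(read), rand_dna(30)))
  expect_equal(count_genome_matches(read, genome), 3L)
  # homopolymer: overlapping occurrences all count (11 forward, none on
  # the reverse complement strand)
  expect_equal(count_genome_matches(strrep("A", 10),
                                    c(c = strrep("A", 20))), 11L)
  expect_error(count_genome_matches("ACGTACGTA", genome), "shorter")
  hits <- locate_genome_matches(read, genome)
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$strand, c("+", "-", "-"))
})

test_that("evaluate_hairpin passes perfect stems and fails broken ones", {
  set.seed(23)
  hp <- make_hairpin(21, 15, star_mismatches = 0)
  ev <- evaluate_hairpin(hp$precursor, hp$mature)
  expect_true(ev$pass)
  expect_equal(ev$diagnostics$unpaired_mature, 0L)

  hp5 <- make_hairpin(21, 15, star_mismatches = 5)
  ev5 <- evaluate_hairpin(hp5$precursor, hp5$mature)
  expect_false(ev5$pass)
  expect_gte(ev5$diagnostics$unpaired_mature, 5L)

  # a mature straddling the loop midpoint fails with spans-loop
  mid <- substr(hp$precursor, 15, 35)
  evm <- evaluate_hairpin(hp$precursor, mid)
  expect_false(evm$pass)
  expect_true(evm$diagnostics$spans_loop)

  expect_error(evaluate_hairpin(hp$precursor, "NOTINPRECURSOR"), "not found")
})

test_that("evaluate_hairpin is invariant under precursor reverse complement", {
  set.seed(24)
  for (case in 1:5) {
    hp <- make_hairpin(21, 12, star_mismatches = sample(0:2, 1))
    fwd <- evaluate_hairpin(hp$precursor, hp$mature)
    # on the reverse complement the mature maps to the other arm
    rc <- revcomp(hp$precursor)
    rc_mature <- revcomp(hp$mature)
    bwd <- evaluate_hairpin(rc, rc_mature)
    expect_equal(fwd$pass, bwd$pass)
  }
})

test_that("find_star demands an observed read equal to the 2-nt-overhang star", {
  set.seed(25)
  hp <- make_hairpin(21, 15, 0)
  got <- find_star(hp$precursor, hp$mature,
                   observed_reads = c(hp$star, "ACGTACGT"))
  expect_equal(got, hp$star)
  expect_null(find_star(hp$precursor, hp$mature,
                        observed_reads = c("ACGTACGT")))
  # a star read with mismatches is not accepted in exact mode
  bad <- hp$star
  substr(bad, 5, 7) <- "NNN"
  expect_null(find_star(hp$precursor, hp$mature, observed_reads = bad))
})

test_that("compute_rpm scales to reads per million", {
  expect_equal(compute_rpm(50, 1e6), 50)
  expect_equal(compute_rpm(0, 1e7), 0)
  expect_equal(compute_rpm(114, 114), 1e6)
  expect_error(compute_rpm(1, 0), "positive")
  # RPM over a whole library sums to one million
  counts <- c(10, 25, 65)
  expect_equal(sum(compute_rpm(counts, sum(counts))), 1e6)
})

test_that("discovery excludes reads beyond the genome-match cap", {
  set.seed(26)
  read <- strrep("AT", 8)              # 16-nt repeat; matches everywhere
  genome <- c(chr1 = paste0(strrep("AT", 40), rand_dna(100)))
  expect_gt(count_genome_matches(read, genome), 15L)
  reads <- data.frame(seq = read, count = 50L, library_id = "lib1",
                      stringsAsFactors = FALSE)
  disc <- discover_mirnas(reads, genome,
                          reference_mirnas = c(ref1 = rand_dna(21)))
  expect_equal(nrow(disc$loci), 0L)
  expect_match(disc$candidate_report$detail[1], "cap")
})
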