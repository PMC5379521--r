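test_that("make_hairpin realizes the requested star-arm state", {
  set.seed(71)
  hp <- make_hairpin(21, 15, 0)
  expect_true(evaluate_hairpin(hp$precursor, hp$mature)$pass)
  expect_equal(nchar(hp$star), 21L)
  hp5 <- make_hairpin(21, 15, 5)
  expect_false(evaluate_hairpin(hp5$precursor, hp5$mature)$pass)
  expect_error(make_hairpin(21, 15, 22), "star_mismatches")
  # determinism under a fixed stream
  set.seed(99); h1 <- make_hairpin(21, 15, 1)
  set.seed(99); h2 <- make_hairpin(21, 15, 1)
  expect_identical(h1, h2)
})

test_that("plant_binding_site hits requested scores exactly", {
  set.seed(72)
  mir <- rand_dna(21)
  tx <- rand_dna(300)
  for (target in c(0, 0.5, 1.5, 3.5)) {
    pl <- plant_binding_site(tx, mir, target, 120)
    expect_equal(score_duplex(mir, substr(pl$transcript, 120, 140))$score,
                 target)
  }
  expect_error(plant_binding_site(tx, mir, 0.25, 120), "unreachable")
  expect_error(plant_binding_site(tx, mir, 0, 295), "fit")
})

test_that("plant_impact_event crosses the cutoff by the margin in both directions", {
  set.seed(73)
  params <- score_params()
  for (case in 1:5) {
    mir <- rand_dna(21)
    tx <- plant_binding_site(rand_dna(300), mir, 3.0, 100, params)$transcript
    a <- plant_impact_event(tx, mir, 100, "a_unique", params, 1.0)
    expect_equal(a$ref_score, 3.0)
    expect_gte(a$alt_score, 5.0)
    b <- plant_impact_event(tx, mir, 100, "b_unique", params, 1.0)
    expect_gte(b$ref_score, 5.0)
    expect_equal(b$alt_score, 3.0)
    # the b_unique reference transcript really lacks a reported site
    expect_equal(nrow(find_sites(mir, b$transcript, params)), 0L)
    n <- plant_impact_event(tx, mir, 100, "neutral", params, 1.0)
    expect_lte(n$alt_score, params$cutoff)
  }
})

test_that("make_degradome concentrates tags at the cleavage position", {
  set.seed(74)
  tx <- rand_dna(300)
  tags <- make_degradome(tx, 150, total_tags = 10, peak_fraction = 1.0)
  expect_equal(sum(tags$count), 10L)
  expect_equal(nrow(tags), 1L)
  expect_equal(tags$seq, substr(tx, 150, 169))
  prof <- map_tags(tags, c(t = tx))$t
  expect_equal(classify_site(prof, 150), 0L)
  expect_error(make_degradome(tx, 150, 10, peak_fraction = 0), "peak_fraction")
  expect_error(make_degradome(substr(tx, 1, 10), 1, 10, 1), "shorter")
  set.seed(5); t1 <- make_degradome(tx, 150, 30, 0.5)
  set.seed(5); t2 <- make_degradome(tx, 150, 30, 0.5)
  expect_identical(t1, t2)
})

test_that("identical config and seed give identical bundles and files", {
  cfg <- scenario_config(seed = 202, n_mirnas = 2L, n_transcripts = 4L,
                         n_planted_sites = 2L, n_a_unique = 1L,
                         n_b_unique = 1L, n_neutral = 0L,
                         chrom_length = 5000L)
  b1 <- make_scenario(cfg)
  b2 <- make_scenario(cfg)
  expect_identical(b1, b2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(b1, d1)
  write_scenario(b2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("planted truths verify against the analysis modules", {
  cfg <- scenario_config(seed = 303, n_mirnas = 3L, n_transcripts = 8L,
                         n_planted_sites = 3L, n_a_unique = 2L,
                         n_b_unique = 1L, n_neutral = 1L,
                         chrom_length = 8000L)
  b <- make_scenario(cfg)
  # every planted site re-scores to its recorded penalty
  mir <- stats::setNames(b$hairpins$mature_seq, b$hairpins$id)
  for (r in seq_len(nrow(b$truth$sites))) {
    s <- b$truth$sites[r, ]
    expect_equal(score_duplex(mir[[s$mirna_id]],
                              substr(b$transcripts_a[[s$transcript_id]],
                                     s$site_start, s$site_end))$score,
                 s$score)
  }
  # hairpins pass, and reads contain each mature
  for (r in seq_len(nrow(b$hairpins))) {
    expect_true(evaluate_hairpin(b$hairpins$precursor[r],
                                 b$hairpins$mature_seq[r])$pass)
    expect_true(b$hairpins$mature_seq[r] %in% b$reads$seq)
  }
  # group-B transcripts differ from A exactly at B-major alleles
  ev <- b$truth$events[b$truth$events$kind != "neutral", ]
  for (r in seq_len(nrow(ev))) {
    gm <- b$gene_models[b$gene_models$transcript_id == ev$transcript_id[r], ]
    lp <- ev$pos[r] - gm$start
    expect_equal(substr(b$transcripts_a[[ev$transcript_id[r]]], lp, lp),
                 ev$ref[r])
    expect_equal(substr(b$transcripts_b[[ev$transcript_id[r]]], lp, lp),
                 ev$alt[r])
  }
})

test_that("a null scenario yields no deltas", {
  cfg <- scenario_config(seed = 404, n_mirnas = 2L, n_transcripts = 3L,
                         n_planted_sites = 1L, n_a_unique = 0L,
                         n_b_unique = 0L, n_neutral = 0L,
                         background_snp_rate = 0, chrom_length = 5000L)
  b <- make_scenario(cfg)
  res <- snp_impact_analysis(b$hairpins, b$transcripts_a, b$gene_models,
                             b$variants, ortholog_seqs = b$transcripts_b)
  expect_equal(sum(res$deltas$status != "conserved"), 0L)
  expect_equal(res$unique_targets$counts$n_unique, c(0L, 0L))
})

test_that("infeasible configs error out early", {
  expect_error(scenario_config(n_planted_sites = 20L, n_transcripts = 5L),
               "more planted")
  expect_error(scenario_config(cutoff_margin = 1.5), "infeasible")
  expect_error(scenario_config(peak_fraction = 0), "peak_fraction")
})
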