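# Seeded generator of a complete two-genotype-group dataset with planted
# ground truth for every pipeline stage: a genome carrying hairpin loci and
# transcribed genes, collapsed sRNA reads drawn from the hairpins, planted
# miRNA binding sites with exact scores, group-differentiated SNPs that
# create or destroy sites across the scoring cutoff, degradome tags peaked
# at the predicted cleavage positions, and background SNPs.
#
# The generator verifies every planted artifact against the analysis
# modules at build time, so generation bugs surface as errors rather than
# as test noise. All randomness flows from one root seed through labelled
# child streams.

#' Scenario configuration
#'
#' Defaults describe the study design emulated throughout: two genotype
#' groups sharing a genome, a handful of miRNA hairpins expressed as
#' collapsed reads, transcripts carrying planted binding sites, fixed
#' group-differentiated SNPs inside a subset of sites, and a degradome
#' library peaked at cleavage positions.
#'
#' @param seed root RNG seed.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_mirnas,mature_len,loop_len hairpin counts and geometry.
#' @param n_transcripts,transcript_len transcript set shape.
#' @param n_planted_sites baseline (group-shared) binding sites.
#' @param n_a_unique,n_b_unique,n_neutral planted SNP impact events.
#' @param cutoff_margin score distance on both sides of the cutoff for
#'   impact events (must be <= 1: a single base edit changes the penalty by
#'   at most 2).
#' @param n_samples_per_group diploid samples genotyped per group.
#' @param background_snp_rate per-bp background SNP probability.
#' @param peak_fraction,total_tags,tag_len degradome controls.
#' @param params [score_params()] used for all planting and verification.
#' @return list of class "scenario_config".
#' @export
scenario_config <- function(seed = 1L, n_chromosomes = 2L,
                            chrom_length = 12000L, n_mirnas = 6L,
                            mature_len = 21L, loop_len = 15L,
                            n_transcripts = 12L, transcript_len = 500L,
                            n_planted_sites = 6L, n_a_unique = 3L,
                            n_b_unique = 2L, n_neutral = 1L,
                            cutoff_margin = 1.0, n_samples_per_group = 5L,
                            background_snp_rate = 0.001,
                            peak_fraction = 0.5, total_tags = 40L,
                            tag_len = 20L, params = score_params()) {
  stopifnot(n_chromosomes >= 1, n_mirnas >= 0, n_transcripts >= 1,
            cutoff_margin > 0, peak_fraction > 0, peak_fraction <= 1,
            n_samples_per_group >= 1)
  if (cutoff_margin > 1) {
    stop("cutoff_margin > 1 is infeasible: one SNP changes the score by ",
         "at most 2")
  }
  n_events <- n_a_unique + n_b_unique + n_neutral
  if (n_planted_sites + n_events > n_transcripts) {
    stop("more planted sites + events than transcripts")
  }
  structure(as.list(environment()), class = "scenario_config")
}

#' Construct a synthetic miRNA hairpin
#'
#' precursor = mature + loop + reverse complement of the mature (with
#' `star_mismatches` substitutions on the star arm) + 2 trailing bases, so
#' the mature/star duplex has the canonical 2-nt 3' overhang geometry. The
#' construction is verified against [evaluate_hairpin()] (and regenerated
#' on the rare failure) whenever `star_mismatches` is within the unpaired
#' tolerance.
#'
#' @param mature_len,loop_len geometry.
#' @param star_mismatches substitutions planted opposite the mature.
#' @param criteria hairpin criteria used for self-verification.
#' @return list(precursor, mature, star).
#' @export
make_hairpin <- function(mature_len = 21L, loop_len = 15L,
                         star_mismatches = 0L, criteria = list()) {
  if (star_mismatches > mature_len) stop("star_mismatches > mature_len")
  crit <- utils::modifyList(list(max_unpaired_mature = 4L,
                                 min_paired_fraction = 0.5), criteria)
  # the construction is checked both ways: within the unpaired tolerance
  # the hairpin must pass, beyond it the fold must actually leave the
  # mature under-paired (maximum pairing can scavenge alternatives, so
  # draws that do not realize the intent are rejected)
  want_pass <- star_mismatches <= crit$max_unpaired_mature
  for (attempt in seq_len(50L)) {
    mature <- random_seq(mature_len)
    loop <- random_seq(loop_len)
    arm <- seq_chars(revcomp(mature))
    if (star_mismatches > 0L) {
      # substitute opposite mature interior positions (arm index j pairs
      # mature position m+1-j); avoid the duplex ends
      js <- sample(3:(mature_len - 2L), star_mismatches)
      for (j in js) {
        mate <- substr(mature, mature_len + 1L - j, mature_len + 1L - j)
        ok <- BASES[vapply(BASES, function(b) {
          !pairable_matrix()[b, mate] && b != arm[j]
        }, logical(1))]
        arm[j] <- ok[1]
      }
    }
    precursor <- paste0(mature, loop, paste(arm, collapse = ""),
                        random_seq(2L))
    m <- mature_len
    star <- substr(precursor, m + loop_len + 3L, 2L * m + loop_len + 2L)
    ev <- evaluate_hairpin(precursor, mature, criteria = criteria)
    if (ev$pass == want_pass) {
      return(list(precursor = precursor, mature = mature, star = star))
    }
  }
  stop("failed to build a hairpin realizing star_mismatches = ",
       star_mismatches, " in 50 attempts")
}

# Decompose a target penalty into planted edits. Returns a data.frame
# (mirna_pos, type) with type "mismatch"/"gu", or errors listing the
# nearest achievable scores. Edits are placed outside the core, from the
# miRNA 3' end inward, spilling into the core only when the outside
# positions run out.
compose_penalty <- function(target, mirna_seq, params, jitter = FALSE) {
  m <- nchar(mirna_seq)
  if (target %% params$gu_penalty > 1e-9 && params$gu_penalty > 0) {
    lo <- floor(target / params$gu_penalty) * params$gu_penalty
    stop("target score ", target, " unreachable; nearest achievable: ",
         lo, " or ", lo + params$gu_penalty)
  }
  core_set <- params$core_start:min(params$core_end, m)
  outside_all <- setdiff(seq_len(m), core_set)
  # keep the duplex ends clean: edits at terminal positions invite
  # equal-scoring bulged alignments that shift the reported window
  interior <- rev(outside_all[outside_all > 1L & outside_all < m - 1L])
  if (jitter && length(interior) > 1L) interior <- sample(interior)
  mir <- seq_chars(mirna_seq)
  edits <- list()
  remaining <- target
  # a fractional half-unit needs one G:U wobble: reserve a G/T position
  # for it up front (interior first, duplex ends as fallback)
  gu_pos <- NA_integer_
  if (params$gu_penalty > 0 && remaining %% params$mismatch_penalty > 1e-9) {
    cand <- c(interior, rev(setdiff(outside_all, interior)))
    cand <- cand[mir[cand] %in% c("G", "T")]
    if (!length(cand)) {
      stop("target score ", target, " unreachable with available positions")
    }
    gu_pos <- cand[1]
    edits[[length(edits) + 1L]] <- data.frame(mirna_pos = gu_pos, type = "gu")
    remaining <- remaining - params$gu_penalty
  }
  for (i in setdiff(interior, gu_pos)) {
    if (remaining <= 1e-9) break
    if (remaining >= params$mismatch_penalty) {
      edits[[length(edits) + 1L]] <- data.frame(mirna_pos = i,
                                                type = "mismatch")
      remaining <- remaining - params$mismatch_penalty
    } else if (remaining >= params$gu_penalty && mir[i] %in% c("G", "T")) {
      edits[[length(edits) + 1L]] <- data.frame(mirna_pos = i, type = "gu")
      remaining <- remaining - params$gu_penalty
    }
  }
  # spill into the core (doubled penalties) if needed
  core <- rev(intersect(params$core_start:params$core_end, seq_len(m)))
  for (i in core) {
    if (remaining <= 0) break
    if (remaining >= 2 * params$mismatch_penalty) {
      edits[[length(edits) + 1L]] <- data.frame(mirna_pos = i,
                                                type = "mismatch")
      remaining <- remaining - 2 * params$mismatch_penalty
    } else if (remaining >= 2 * params$gu_penalty && mir[i] %in% c("G", "T")) {
      edits[[length(edits) + 1L]] <- data.frame(mirna_pos = i, type = "gu")
      remaining <- remaining - 2 * params$gu_penalty
    }
  }
  if (remaining > 1e-9) {
    stop("target score ", target, " unreachable with available positions")
  }
  if (length(edits)) do.call(rbind, edits) else
    data.frame(mirna_pos = integer(0), type = character(0))
}

# The site base opposite miRNA position i, for a bulge-free site ending at
# transcript position e: e - i + 1.
site_base_for <- function(mir_base, type) {
  if (type == "match") return(chartr("ACGT", "TGCA", mir_base))
  if (type == "gu") {
    if (mir_base == "G") return("T")
    if (mir_base == "T") return("G")
    stop("G:U edit needs a G or T miRNA base")
  }
  # mismatch: first base that neither complements nor wobbles
  P <- pairable_matrix()
  BASES[!P[, mir_base]][1]
}

#' Plant a binding site with an exact penalty score
#'
#' Writes a site for `mirna_seq` into the transcript at `position` whose
#' [score_duplex()] penalty equals `target_score` exactly: the reverse
#' complement of the miRNA plus a deterministic composition of mismatch and
#' G:U edits (outside the core first). The planted window is re-scored
#' before returning.
#'
#' @param transcript_seq transcript to modify.
#' @param mirna_seq miRNA.
#' @param target_score exact penalty to plant (multiple of the G:U penalty).
#' @param position 1-based start of the site on the transcript.
#' @param params [score_params()].
#' @return list(transcript, site_start, site_end, score, edits).
#' @export
plant_binding_site <- function(transcript_seq, mirna_seq, target_score,
                               position, params = score_params()) {
  m <- nchar(mirna_seq)
  e <- position + m - 1L
  if (position < 1L || e > nchar(transcript_seq)) {
    stop("site does not fit the transcript at position ", position)
  }
  mir <- seq_chars(mirna_seq)
  # Edit placements are re-drawn until the planted window is also locally
  # optimal: a bulged alignment of a neighbouring window must not undercut
  # the intended penalty, or downstream site reports would disagree with
  # the recorded truth.
  for (attempt in seq_len(25L)) {
    edits <- compose_penalty(target_score, mirna_seq, params,
                             jitter = attempt > 1L)
    site <- seq_chars(revcomp(mirna_seq))       # perfect site, 5'->3'
    for (r in seq_len(nrow(edits))) {
      i <- edits$mirna_pos[r]
      site[m - i + 1L] <- site_base_for(mir[i], edits$type[r])
    }
    site <- paste(site, collapse = "")
    tx <- paste0(substr(transcript_seq, 1L, position - 1L), site,
                 substr(transcript_seq, e + 1L, nchar(transcript_seq)))
    got <- score_duplex(mirna_seq, site, params)$score
    if (abs(got - target_score) > 1e-9) {
      stop("planted site re-scored to ", got, ", expected ", target_score)
    }
    best <- local_best_score(mirna_seq, tx, position, e, params)
    if (is.finite(best) && abs(best - target_score) < 1e-9 ||
        (!is.finite(best) && target_score > params$cutoff)) {
      return(list(transcript = tx, site_start = position, site_end = e,
                  score = got, edits = edits))
    }
  }
  stop("no locally optimal edit placement found for target score ",
       target_score, " at position ", position)
}

# Scan a neighbourhood of a planted site and return the best reported
# score overlapping it (Inf if none reported under the cutoff).
local_best_score <- function(mirna_seq, transcript_seq, s, e, params) {
  m <- nchar(mirna_seq)
  lo <- max(1L, s - m)
  hi <- min(nchar(transcript_seq), e + m)
  sites <- find_sites(mirna_seq, substr(transcript_seq, lo, hi), params)
  sites <- sites[sites$site_start + lo - 1L <= e + 2L &
                   sites$site_end + lo - 1L >= s - 2L, , drop = FALSE]
  if (!nrow(sites)) Inf else min(sites$score)
}

#' Plant a group-differentiating SNP inside a binding site
#'
#' Starting from a planted site with penalty `cutoff - margin`, chooses a
#' single-base substitution whose alternative allele moves the penalty to
#' at least `cutoff + margin` (kind "a_unique": the site exists under the
#' reference/group-A allele only), or edits the reference so the site only
#' forms under the alternative/group-B allele (kind "b_unique"), or leaves
#' the score on the same side of the cutoff (kind "neutral"). All outcomes
#' are verified by re-scanning; an error asks the caller to retry at a
#' different site.
#'
#' @param transcript_seq transcript carrying the planted site.
#' @param mirna_seq miRNA of the site.
#' @param site_start 1-based site start.
#' @param kind "a_unique", "b_unique" or "neutral".
#' @param params [score_params()].
#' @param margin score margin on both sides of the cutoff (default 1).
#' @return list(transcript (reference sequence, edited for b_unique),
#'   pos (transcript-local SNP position), ref, alt, ref_score, alt_score).
#' @export
plant_impact_event <- function(transcript_seq, mirna_seq, site_start,
                               kind = c("a_unique", "b_unique", "neutral"),
                               params = score_params(), margin = 1.0) {
  kind <- match.arg(kind)
  m <- nchar(mirna_seq)
  e <- site_start + m - 1L
  mir <- seq_chars(mirna_seq)
  site <- seq_chars(substr(transcript_seq, site_start, e))
  base_score <- score_duplex(mirna_seq, paste(site, collapse = ""), params)$score
  if (base_score > params$cutoff - margin + 1e-9) {
    stop("site score ", base_score, " not below cutoff - margin")
  }
  with_tx <- function(pos_local, b) {
    tx <- transcript_seq
    substr(tx, pos_local, pos_local) <- b
    tx
  }
  core <- intersect(params$core_start:params$core_end, seq_len(m))
  if (kind %in% c("a_unique", "b_unique")) {
    for (i in core) {
      sp <- e - i + 1L                       # transcript pos opposite miRNA i
      cur <- substr(transcript_seq, sp, sp)
      if (cur != site_base_for(mir[i], "match")) next
      alt_base <- site_base_for(mir[i], "mismatch")
      broken_tx <- with_tx(sp, alt_base)
      broken_score <- local_best_score(mirna_seq, broken_tx, site_start, e,
                                       params)
      if (broken_score < params$cutoff + margin - 1e-9) next
      if (kind == "a_unique") {
        return(list(transcript = transcript_seq, pos = sp, ref = cur,
                    alt = alt_base, ref_score = base_score,
                    alt_score = broken_score))
      } else {
        # reference carries the broken site; the alternative restores it
        return(list(transcript = broken_tx, pos = sp, ref = alt_base,
                    alt = cur, ref_score = broken_score,
                    alt_score = base_score))
      }
    }
    stop("no single-base edit achieves the requested margin; retry elsewhere")
  }
  # neutral: convert one non-core match to a G:U wobble
  outside <- setdiff(seq_len(m), core)
  for (i in outside) {
    if (!mir[i] %in% c("G", "T")) next
    sp <- e - i + 1L
    cur <- substr(transcript_seq, sp, sp)
    if (cur != site_base_for(mir[i], "match")) next
    alt_base <- site_base_for(mir[i], "gu")
    alt_score <- score_duplex(
      mirna_seq, substr(with_tx(sp, alt_base), site_start, e), params)$score
    if (alt_score <= params$cutoff + 1e-9) {
      return(list(transcript = transcript_seq, pos = sp, ref = cur,
                  alt = alt_base, ref_score = base_score,
                  alt_score = alt_score))
    }
  }
  stop("no neutral single-base edit available; retry elsewhere")
}

#' Generate degradome tags for one interaction
#'
#' round(peak_fraction * total_tags) tags start exactly at the cleavage
#' position; the remainder start uniformly at other positions. All tags are
#' verbatim transcript substrings of length `tag_len`.
#'
#' @param transcript_seq transcript.
#' @param cleavage_pos 1-based predicted cleavage position.
#' @param total_tags,peak_fraction,tag_len controls.
#' @return data.frame(seq, count).
#' @export
make_degradome <- function(transcript_seq, cleavage_pos, total_tags = 40L,
                           peak_fraction = 0.5, tag_len = 20L) {
  if (peak_fraction <= 0 || peak_fraction > 1) {
    stop("peak_fraction must be in (0, 1]")
  }
  if (total_tags < 1L) stop("total_tags must be >= 1")
  L <- nchar(transcript_seq)
  if (L < tag_len) stop("transcript shorter than tag length")
  eff <- L - tag_len + 1L
  if (cleavage_pos < 1L || cleavage_pos > eff) {
    stop("cleavage position leaves no room for a full tag")
  }
  n_peak <- round(peak_fraction * total_tags)
  others <- setdiff(seq_len(eff), cleavage_pos)
  n_noise <- total_tags - n_peak
  pos <- c(rep(cleavage_pos, n_peak),
           if (n_noise > 0) sample(others, n_noise, replace = TRUE))
  seqs <- substring(transcript_seq, pos, pos + tag_len - 1L)
  agg <- table(seqs)
  data.frame(seq = names(agg), count = as.integer(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a complete two-group scenario with planted truth
#'
#' Builds the genome, hairpin loci, collapsed reads, transcripts with
#' planted binding sites and impact events, per-sample genotypes, and
#' degradome tags, and records every planted truth in machine-readable
#' tables. Identical config + seed gives an identical bundle.
#'
#' @param config a [scenario_config()].
#' @return list (class "scenario_bundle") with elements genome,
#'   transcripts_a, transcripts_b, gene_models, hairpins, reads,
#'   reference_mirnas, family_classes, exclusion_sets, variants (in
#'   [read_variants()] layout), genotypes, samples, degradome_tags, truth
#'   (list of data.frames: hairpins, sites, events, degradome), config.
#' @export
make_scenario <- function(config = scenario_config()) {
  cfg <- config
  params <- cfg$params
  m <- cfg$mature_len
  prec_len <- 2L * m + cfg$loop_len + 2L

  genome <- with_seed(child_seed(cfg$seed, "genome"), {
    g <- vapply(seq_len(cfg$n_chromosomes), function(i)
      random_seq(cfg$chrom_length), character(1))
    names(g) <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
    g
  })

  # --- layout: alternate hairpin and transcript slots along chromosomes ---
  slots <- with_seed(child_seed(cfg$seed, "layout"), {
    feats <- c(rep("hairpin", cfg$n_mirnas), rep("transcript", cfg$n_transcripts))
    lens <- ifelse(feats == "hairpin", prec_len, cfg$transcript_len)
    ord <- sample(length(feats))       # interleave feature kinds
    feats <- feats[ord]; lens <- lens[ord]
    chrom_i <- 1L
    cursor <- stats::setNames(rep(0L, cfg$n_chromosomes), names(genome))
    out <- list()
    for (k in seq_along(feats)) {
      gap <- sample(100:300, 1L)
      placed <- FALSE
      for (tries in seq_len(cfg$n_chromosomes)) {
        chrom <- names(genome)[chrom_i]
        s0 <- cursor[[chrom]] + gap
        if (s0 + lens[k] <= cfg$chrom_length - 50L) {
          out[[k]] <- data.frame(kind = feats[k], chrom = chrom, start = s0,
                                 end = s0 + lens[k], stringsAsFactors = FALSE)
          cursor[[chrom]] <- s0 + lens[k]
          placed <- TRUE
          chrom_i <- chrom_i %% cfg$n_chromosomes + 1L
          break
        }
        chrom_i <- chrom_i %% cfg$n_chromosomes + 1L
      }
      if (!placed) stop("genome too small for the requested features")
    }
    do.call(rbind, out)
  })
  hp_slots <- slots[slots$kind == "hairpin", , drop = FALSE]
  tx_slots <- slots[slots$kind == "transcript", , drop = FALSE]

  # --- hairpins, written into the genome ---
  hairpins <- with_seed(child_seed(cfg$seed, "hairpins"), {
    out <- list()
    for (i in seq_len(cfg$n_mirnas)) {
      strand <- if (i %% 2L == 0L) "-" else "+"
      hp <- make_hairpin(m, cfg$loop_len, star_mismatches = 0L)
      sl <- hp_slots[i, ]
      gseq <- if (strand == "+") hp$precursor else revcomp(hp$precursor)
      substr(genome[[sl$chrom]], sl$start + 1L, sl$end) <- gseq
      out[[i]] <- data.frame(
        id = sprintf("mir_%02d", i), chrom = sl$chrom, start = sl$start,
        end = sl$end, strand = strand, precursor = hp$precursor,
        mature_seq = hp$mature, star_seq = hp$star, mature_offset = 0L,
        has_star_read = i <= ceiling(cfg$n_mirnas / 2),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })

  # reference mature set: the first two hairpins pose as database entries
  reference_mirnas <- character(0)
  family_classes <- character(0)
  if (cfg$n_mirnas >= 1L) {
    reference_mirnas["refmir_conserved_1"] <- hairpins$mature_seq[1]
    family_classes["refmir_conserved_1"] <- "conserved"
  }
  if (cfg$n_mirnas >= 2L) {
    reference_mirnas["refmir_known_1"] <- hairpins$mature_seq[2]
    family_classes["refmir_known_1"] <- "known"
  }

  exclusion_sets <- with_seed(child_seed(cfg$seed, "exclusion"), {
    list(rrna = stats::setNames(random_seq(80L), "rrna_1"))
  })

  reads <- with_seed(child_seed(cfg$seed, "reads"), {
    rows <- list()
    for (i in seq_len(cfg$n_mirnas)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seq = hairpins$mature_seq[i], count = sample(30:300, 1L),
        library_id = "lib1", stringsAsFactors = FALSE)
      if (hairpins$has_star_read[i]) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq = hairpins$star_seq[i], count = sample(5:30, 1L),
          library_id = "lib1", stringsAsFactors = FALSE)
      }
    }
    # noise: too short, too long, contaminant, unmapped
    rows[[length(rows) + 1L]] <- data.frame(
      seq = random_seq(15L), count = 11L, library_id = "lib1",
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seq = random_seq(31L), count = 7L, library_id = "lib1",
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seq = substr(exclusion_sets$rrna[[1]], 11L, 31L), count = 23L,
      library_id = "lib1", stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seq = random_seq(21L), count = 3L, library_id = "lib1",
      stringsAsFactors = FALSE)
    do.call(rbind, rows)
  })

  # --- binding sites and impact events, edited into the genome ---
  gene_models <- data.frame(
    transcript_id = sprintf("tx_%02d", seq_len(cfg$n_transcripts)),
    chrom = tx_slots$chrom, start = tx_slots$start, end = tx_slots$end,
    strand = "+", stringsAsFactors = FALSE)
  get_tx <- function(tid) {
    gm <- gene_models[gene_models$transcript_id == tid, ]
    extract_interval(genome, gm$chrom, gm$start, gm$end, "+")
  }
  set_tx <- function(tid, seqval) {
    gm <- gene_models[gene_models$transcript_id == tid, ]
    substr(genome[[gm$chrom]], gm$start + 1L, gm$end) <<- seqval
  }
  truth_sites <- list()
  truth_events <- list()
  event_variants <- list()
  with_seed(child_seed(cfg$seed, "sites"), {
    achievable <- seq(0, params$cutoff - cfg$cutoff_margin, by = 0.5)
    tx_i <- 0L
    mir_pick <- function() sample(cfg$n_mirnas, 1L)
    next_tx <- function() {
      tx_i <<- tx_i + 1L
      gene_models$transcript_id[tx_i]
    }
    for (s in seq_len(cfg$n_planted_sites)) {
      tid <- next_tx()
      mi <- mir_pick()
      pos <- sample(50:(cfg$transcript_len - m - 50L), 1L)
      sc <- sample(achievable, 1L)
      pl <- plant_binding_site(get_tx(tid), hairpins$mature_seq[mi], sc,
                               pos, params)
      set_tx(tid, pl$transcript)
      truth_sites[[length(truth_sites) + 1L]] <- data.frame(
        mirna_id = hairpins$id[mi], transcript_id = tid,
        site_start = pl$site_start, site_end = pl$site_end, score = sc,
        kind = "baseline", stringsAsFactors = FALSE)
    }
    plant_event <- function(kind) {
      tid <- next_tx()
      base <- params$cutoff - cfg$cutoff_margin
      ev <- NULL
      for (attempt in seq_len(40L)) {
        mi <- mir_pick()
        pos <- sample(50:(cfg$transcript_len - m - 50L), 1L)
        pl <- plant_binding_site(get_tx(tid), hairpins$mature_seq[mi], base,
                                 pos, params)
        ev <- tryCatch(
          plant_impact_event(pl$transcript, hairpins$mature_seq[mi], pos,
                             kind, params, cfg$cutoff_margin),
          error = function(e) NULL)
        if (!is.null(ev)) break
      }
      if (is.null(ev)) stop("could not plant a ", kind, " event in 40 tries")
      set_tx(tid, ev$transcript)
      gm <- gene_models[gene_models$transcript_id == tid, ]
      gpos <- gm$start + ev$pos          # 1-based genome position (+ strand)
      truth_events[[length(truth_events) + 1L]] <<- data.frame(
        kind = kind, mirna_id = hairpins$id[mi], transcript_id = tid,
        site_start = pl$site_start, site_end = pl$site_end,
        ref_score = ev$ref_score, alt_score = ev$alt_score,
        chrom = gm$chrom, pos = gpos, ref = ev$ref, alt = ev$alt,
        stringsAsFactors = FALSE)
      event_variants[[length(event_variants) + 1L]] <<- data.frame(
        chrom = gm$chrom, pos = gpos, ref = ev$ref, alt = ev$alt,
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(cfg$n_a_unique)) plant_event("a_unique")
    for (k in seq_len(cfg$n_b_unique)) plant_event("b_unique")
    for (k in seq_len(cfg$n_neutral)) plant_event("neutral")
  })
  truth_sites <- if (length(truth_sites)) do.call(rbind, truth_sites) else
    data.frame(mirna_id = character(0), transcript_id = character(0),
               site_start = integer(0), site_end = integer(0),
               score = numeric(0), kind = character(0),
               stringsAsFactors = FALSE)
  truth_events <- if (length(truth_events)) do.call(rbind, truth_events) else
    data.frame(kind = character(0), mirna_id = character(0),
               transcript_id = character(0), site_start = integer(0),
               site_end = integer(0), ref_score = numeric(0),
               alt_score = numeric(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               stringsAsFactors = FALSE)

  # --- genotypes: planted events are fixed differences; background SNPs
  # are shared low-frequency polymorphism placed outside planted features --
  samples <- data.frame(
    sample = c(sprintf("A%d", seq_len(cfg$n_samples_per_group)),
               sprintf("B%d", seq_len(cfg$n_samples_per_group))),
    group = rep(c("A", "B"), each = cfg$n_samples_per_group),
    stringsAsFactors = FALSE)
  forbidden <- list()
  mark <- function(chrom, start, end) {
    forbidden[[length(forbidden) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(hairpins))) {
    mark(hairpins$chrom[r], hairpins$start[r], hairpins$end[r])
  }
  for (r in seq_len(nrow(truth_sites))) {
    gm <- gene_models[gene_models$transcript_id == truth_sites$transcript_id[r], ]
    mark(gm$chrom, gm$start + truth_sites$site_start[r] - 3L,
         gm$start + truth_sites$site_end[r] + 2L)
  }
  for (r in seq_len(nrow(truth_events))) {
    gm <- gene_models[gene_models$transcript_id == truth_events$transcript_id[r], ]
    mark(gm$chrom, gm$start + truth_events$site_start[r] - 3L,
         gm$start + truth_events$site_end[r] + 2L)
  }
  forbidden <- do.call(rbind, forbidden)
  in_forbidden <- function(chrom, pos) {
    any(forbidden$chrom == chrom & pos > forbidden$start &
          pos <= forbidden$end)
  }
  n_hap <- cfg$n_samples_per_group * 2L
  var_rows <- list()
  gt_rows <- list()
  add_variant <- function(chrom, pos, ref, alt, gtA, gtB) {
    var_rows[[length(var_rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      stringsAsFactors = FALSE)
    gt_rows[[length(gt_rows) + 1L]] <<- c(gtA, gtB)
  }
  with_seed(child_seed(cfg$seed, "variants"), {
    for (r in seq_len(nrow(truth_events))) {
      add_variant(truth_events$chrom[r], truth_events$pos[r],
                  truth_events$ref[r], truth_events$alt[r],
                  rep("0/0", cfg$n_samples_per_group),
                  rep("1/1", cfg$n_samples_per_group))
    }
    for (chrom in names(genome)) {
      n_bg <- stats::rbinom(1L, cfg$chrom_length, cfg$background_snp_rate)
      if (n_bg == 0L) next
      poss <- sort(sample.int(cfg$chrom_length, n_bg))
      for (p in poss) {
        if (in_forbidden(chrom, p)) next
        ref <- substr(genome[[chrom]], p, p)
        alt <- sample(setdiff(BASES, ref), 1L)
        af <- stats::runif(1L, 0.05, 0.40)
        gt <- vapply(seq_len(2L * cfg$n_samples_per_group), function(s) {
          paste(sort(stats::rbinom(2L, 1L, af)), collapse = "/")
        }, character(1))
        add_variant(chrom, p, ref, alt, gt[seq_len(cfg$n_samples_per_group)],
                    gt[-seq_len(cfg$n_samples_per_group)])
      }
    }
  })
  if (length(var_rows)) {
    var_df <- do.call(rbind, var_rows)
    gt_mat <- do.call(rbind, gt_rows)
    colnames(gt_mat) <- samples$sample
    ord <- order(var_df$chrom, var_df$pos)
    var_df <- var_df[ord, , drop = FALSE]
    gt_mat <- gt_mat[ord, , drop = FALSE]
    rownames(var_df) <- NULL
  } else {
    var_df <- data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         stringsAsFactors = FALSE)
    gt_mat <- matrix(character(0), nrow = 0, ncol = nrow(samples),
                     dimnames = list(NULL, samples$sample))
  }
  variants <- variants_from_genotypes(var_df, gt_mat, samples)

  # --- transcript sets per group ---
  transcripts_a <- stats::setNames(
    vapply(gene_models$transcript_id, get_tx, character(1)),
    gene_models$transcript_id)
  transcripts_b <- transcripts_a
  for (tid in names(transcripts_a)) {
    gm <- gene_models[gene_models$transcript_id == tid, ]
    sel <- which(variants$chrom == gm$chrom & variants$pos > gm$start &
                   variants$pos <= gm$end)
    for (i in sel) {
      maj <- group_major_alleles(variants[i, , drop = FALSE], "B")
      if (length(maj) != 1L) next
      lp <- variants$pos[i] - gm$start
      if (substr(transcripts_b[[tid]], lp, lp) != maj) {
        substr(transcripts_b[[tid]], lp, lp) <- maj
      }
    }
  }

  # --- degradome: peaks at the cleavage positions of group-A sites ---
  deg_truth <- list()
  degradome_tags <- with_seed(child_seed(cfg$seed, "degradome"), {
    rows <- list()
    covered <- rbind(
      truth_sites[, c("mirna_id", "transcript_id", "site_end")],
      truth_events[truth_events$kind == "a_unique",
                   c("mirna_id", "transcript_id", "site_end")])
    for (r in seq_len(nrow(covered))) {
      tid <- covered$transcript_id[r]
      cpos <- covered$site_end[r] - 9L
      rows[[length(rows) + 1L]] <- make_degradome(
        transcripts_a[[tid]], cpos, cfg$total_tags, cfg$peak_fraction,
        cfg$tag_len)
      deg_truth[[length(deg_truth) + 1L]] <- data.frame(
        mirna_id = covered$mirna_id[r], transcript_id = tid,
        cleavage_pos = cpos, stringsAsFactors = FALSE)
    }
    if (!length(rows)) {
      data.frame(seq = character(0), count = integer(0),
                 stringsAsFactors = FALSE)
    } else {
      tags <- do.call(rbind, rows)
      agg <- stats::aggregate(count ~ seq, tags, sum)
      agg[order(agg$seq), , drop = FALSE]
    }
  })
  deg_truth <- if (length(deg_truth)) do.call(rbind, deg_truth) else
    data.frame(mirna_id = character(0), transcript_id = character(0),
               cleavage_pos = integer(0), stringsAsFactors = FALSE)

  # --- build-time verification against the analysis modules ---
  for (r in seq_len(nrow(truth_sites))) {
    got <- score_duplex(
      hairpins$mature_seq[match(truth_sites$mirna_id[r], hairpins$id)],
      substr(transcripts_a[[truth_sites$transcript_id[r]]],
             truth_sites$site_start[r], truth_sites$site_end[r]),
      params)$score
    if (abs(got - truth_sites$score[r]) > 1e-9) {
      stop("generator self-check failed: planted site re-scored to ", got)
    }
  }

  structure(list(genome = genome, transcripts_a = transcripts_a,
                 transcripts_b = transcripts_b, gene_models = gene_models,
                 hairpins = hairpins, reads = reads,
                 reference_mirnas = reference_mirnas,
                 family_classes = family_classes,
                 exclusion_sets = exclusion_sets, variants = variants,
                 genotypes = gt_mat, variant_positions = var_df,
                 samples = samples, degradome_tags = degradome_tags,
                 truth = list(hairpins = hairpins, sites = truth_sites,
                              events = truth_events, degradome = deg_truth),
                 config = cfg),
            class = "scenario_bundle")
}

# Assemble a read_variants()-layout data.frame from simple biallelic
# genotype calls (the scenario's in-memory mirror of its VCF).
variants_from_genotypes <- function(var_df, gt_mat, samples) {
  n <- nrow(var_df)
  counts_list <- vector("list", n)
  freqs_list <- vector("list", n)
  an <- numeric(n)
  groups <- unique(samples$group)
  for (i in seq_len(n)) {
    alleles <- c(var_df$ref[i], var_df$alt[i])
    tally <- function(cols) {
      cnt <- stats::setNames(numeric(4), BASES)
      for (g in gt_mat[i, cols]) {
        for (a in strsplit(g, "/", fixed = TRUE)[[1]]) {
          if (a == ".") next
          b <- alleles[as.integer(a) + 1L]
          cnt[b] <- cnt[b] + 1
        }
      }
      cnt
    }
    all_cnt <- tally(samples$sample)
    an[i] <- sum(all_cnt)
    counts_list[[i]] <- all_cnt
    gf <- lapply(groups, function(g) {
      cnt <- tally(samples$sample[samples$group == g])
      tot <- sum(cnt)
      if (tot == 0) return(stats::setNames(numeric(0), character(0)))
      cnt[cnt > 0] / tot
    })
    names(gf) <- groups
    freqs_list[[i]] <- gf
  }
  out <- var_df
  out$an <- an
  out$counts <- counts_list
  out$freqs <- freqs_list
  out
}
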