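# The core inference: apply group-specific SNP alleles to mature miRNAs and
# target mRNAs, re-run the target search, classify conserved / disrupted /
# created interactions, validate created sites against the second group's
# transcripts, and call group-unique targets.

#' Apply single-base variants to a sequence
#'
#' @param seq base sequence.
#' @param local_variants data.frame(pos, ref, alt) with 1-based local
#'   positions; `ref` must match the sequence at `pos`.
#' @return list (class "snp_sequence"): base_seq, variant_seq, applied
#'   (the input data.frame), group (attached by callers).
#' @export
apply_variants <- function(seq, local_variants, group = NA_character_,
                           base_id = NA_character_) {
  s <- seq
  if (nrow(local_variants)) {
    for (i in seq_len(nrow(local_variants))) {
      p <- local_variants$pos[i]
      if (p < 1L || p > nchar(seq)) {
        stop("variant position ", p, " outside sequence (length ",
             nchar(seq), ")")
      }
      have <- substr(seq, p, p)
      if (have != local_variants$ref[i]) {
        stop("ref allele mismatch at position ", p, ": sequence has ", have,
             ", variant says ", local_variants$ref[i])
      }
      substr(s, p, p) <- local_variants$alt[i]
    }
  }
  structure(list(base_id = base_id, base_seq = seq, variant_seq = s,
                 applied = local_variants, group = group),
            class = "snp_sequence")
}

# Group-major allele at a variant: the base with within-group frequency
# > 0.5; ties return all tied bases; empty if the group has no calls.
group_major_alleles <- function(variant_row, group) {
  f <- variant_row$freqs[[1]][[group]]
  if (is.null(f) || !length(f)) return(character(0))
  mx <- max(f)
  if (mx > 0.5) return(names(f)[f == mx][1])
  names(f)[f == mx]
}

#' Build group-specific snp-miRNA sequences
#'
#' Lifts genomic SNPs inside the mature interval to mature-local 1-based
#' coordinates (strand-aware: minus-strand alleles are complemented), takes
#' each variant's group-major allele, and enumerates haplotypes (capped).
#'
#' @param mature_seq mature sequence (precursor-strand orientation).
#' @param mature_chrom,mature_start,mature_end genomic interval of the
#'   mature (0-based half-open), `strand` its strand.
#' @param variants data.frame from [read_variants()].
#' @param group group label whose major alleles define the snp-miRNA.
#' @param strand "+" or "-".
#' @param cap maximum number of haplotype sequences enumerated (default 8).
#' @return list of "snp_sequence" objects (possibly empty if the group
#'   carries only reference alleles). Variants lying outside the mature are
#'   ignored.
#' @export
build_snp_mirna <- function(mature_seq, mature_chrom, mature_start,
                            mature_end, strand, variants, group, cap = 8L,
                            base_id = NA_character_) {
  m <- nchar(mature_seq)
  sel <- variants$chrom == mature_chrom & variants$pos > mature_start &
    variants$pos <= mature_end
  vv <- variants[sel, , drop = FALSE]
  per_site <- list()
  for (i in seq_len(nrow(vv))) {
    g_pos <- vv$pos[i]
    local <- if (strand == "+") g_pos - mature_start else
      mature_end - g_pos + 1L
    alleles <- group_major_alleles(vv[i, , drop = FALSE], group)
    if (!length(alleles)) next
    if (strand == "-") alleles <- chartr("ACGT", "TGCA", alleles)
    ref_local <- substr(mature_seq, local, local)
    alt <- setdiff(alleles, ref_local)
    if (!length(alt)) next
    per_site[[length(per_site) + 1L]] <- list(pos = local, ref = ref_local,
                                              alts = alt)
  }
  if (!length(per_site)) return(list())
  # joint enumeration over per-site alternatives, capped
  combos <- list(data.frame(pos = integer(0), ref = character(0),
                            alt = character(0), stringsAsFactors = FALSE))
  for (site in per_site) {
    new <- list()
    for (cb in combos) {
      for (a in site$alts) {
        new[[length(new) + 1L]] <- rbind(cb, data.frame(
          pos = site$pos, ref = site$ref, alt = a, stringsAsFactors = FALSE))
      }
    }
    combos <- new
    if (length(combos) > cap) {
      combos <- combos[seq_len(cap)]
      warning("haplotype enumeration capped at ", cap, " sequences")
      break
    }
  }
  lapply(combos, function(cb) {
    cb <- cb[order(cb$pos), , drop = FALSE]
    apply_variants(mature_seq, cb, group = group, base_id = base_id)
  })
}

#' Compare two interaction sets and classify deltas
#'
#' Interactions are matched when their (mirna_id, transcript_id) agree and
#' their site intervals overlap. Matched pairs are `conserved`, ref-only
#' sites are `disrupted`, alt-only sites are `created`.
#'
#' @param interactions_ref,interactions_alt data.frames from [find_sites()].
#' @param cause label recorded on every delta ("mirna_snp"/"target_snp"/NA).
#' @return data.frame(mirna_id, transcript_id, status, cause, ref_score,
#'   alt_score, ref_start, ref_end, alt_start, alt_end).
#' @export
diff_targets <- function(interactions_ref, interactions_alt,
                         cause = NA_character_) {
  out <- list()
  used_alt <- rep(FALSE, nrow(interactions_alt))
  for (r in seq_len(nrow(interactions_ref))) {
    ri <- interactions_ref[r, ]
    hit <- which(!used_alt &
                   interactions_alt$mirna_id == ri$mirna_id &
                   interactions_alt$transcript_id == ri$transcript_id &
                   interactions_alt$site_start <= ri$site_end &
                   interactions_alt$site_end >= ri$site_start)
    if (length(hit)) {
      h <- hit[1]
      used_alt[h] <- TRUE
      ai <- interactions_alt[h, ]
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = ri$mirna_id, transcript_id = ri$transcript_id,
        status = "conserved", cause = cause, ref_score = ri$score,
        alt_score = ai$score, ref_start = ri$site_start,
        ref_end = ri$site_end, alt_start = ai$site_start,
        alt_end = ai$site_end, stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = ri$mirna_id, transcript_id = ri$transcript_id,
        status = "disrupted", cause = cause, ref_score = ri$score,
        alt_score = NA_real_, ref_start = ri$site_start,
        ref_end = ri$site_end, alt_start = NA_integer_,
        alt_end = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  for (h in which(!used_alt)) {
    ai <- interactions_alt[h, ]
    out[[length(out) + 1L]] <- data.frame(
      mirna_id = ai$mirna_id, transcript_id = ai$transcript_id,
      status = "created", cause = cause, ref_score = NA_real_,
      alt_score = ai$score, ref_start = NA_integer_, ref_end = NA_integer_,
      alt_start = ai$site_start, alt_end = ai$site_end,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      status = character(0), cause = character(0),
                      ref_score = numeric(0), alt_score = numeric(0),
                      ref_start = integer(0), ref_end = integer(0),
                      alt_start = integer(0), alt_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Global alignment and percent identity
#'
#' Needleman-Wunsch global alignment (via Biostrings) with linear gap cost.
#' Identity is matched columns over total alignment columns.
#'
#' @param a,b sequences.
#' @param match,mismatch,gap scores (defaults 1, -1, -2 per gapped base).
#' @return list(score, identity, aligned_a, aligned_b).
#' @export
align_global <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nchar(a) || !nchar(b)) stop("empty sequence in align_global")
  mat <- matrix(mismatch, 4, 4, dimnames = list(BASES, BASES))
  diag(mat) <- match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- seq_chars(pa)
  cb <- seq_chars(pb)
  identity <- sum(ca == cb & ca != "-") / length(ca)
  list(score = Biostrings::score(aln), identity = identity,
       aligned_a = pa, aligned_b = pb)
}

#' Validate a created site against the other group's transcripts
#'
#' The snp-mRNA is matched to its best orthologue (shared 12-mer prescreen,
#' then global alignment identity); the match is accepted when identity is
#' strictly above `min_identity` and the orthologue carries a site for the
#' same miRNA (score <= cutoff) overlapping the alignment-lifted site
#' region.
#'
#' @param snp_mrna_seq the reconstructed snp-mRNA sequence.
#' @param ortholog_seqs named character vector of candidate orthologue
#'   transcripts (must be non-empty).
#' @param mirna_seq the miRNA whose created site is being validated.
#' @param site_start,site_end site coordinates on the snp-mRNA (1-based).
#' @param params [score_params()].
#' @param min_identity acceptance threshold, exclusive (default 0.90).
#' @param k prescreen k-mer size (default 12).
#' @return list(ortholog_id, identity, site_contained, accepted).
#' @export
ortholog_validate <- function(snp_mrna_seq, ortholog_seqs, mirna_seq,
                              site_start, site_end, params = score_params(),
                              min_identity = 0.90, k = 12L) {
  if (!length(ortholog_seqs)) stop("empty orthologue set")
  kmers <- unique(substring(snp_mrna_seq, seq_len(nchar(snp_mrna_seq) - k + 1L),
                            seq_len(nchar(snp_mrna_seq) - k + 1L) + k - 1L))
  shares <- vapply(ortholog_seqs, function(o) {
    any(vapply(kmers[seq(1L, length(kmers), by = 7L)], grepl, logical(1),
               x = o, fixed = TRUE))
  }, logical(1))
  pool <- if (any(shares)) ortholog_seqs[shares] else ortholog_seqs
  ids <- names(pool)
  alns <- lapply(pool, align_global, a = snp_mrna_seq)
  identities <- vapply(alns, `[[`, numeric(1), "identity")
  bi <- which.max(identities)
  best_id <- ids[bi]
  identity <- identities[[bi]]
  aln <- alns[[bi]]
  # lift site coords through the alignment columns
  ca <- seq_chars(aln$aligned_a)
  cb <- seq_chars(aln$aligned_b)
  a_pos <- cumsum(ca != "-")
  b_pos <- cumsum(cb != "-")
  cols <- which(a_pos >= site_start & a_pos <= site_end & ca != "-")
  lifted <- range(b_pos[cols][b_pos[cols] > 0])
  sites <- find_sites(mirna_seq, pool[[bi]], params)
  contained <- FALSE
  if (nrow(sites) && all(is.finite(lifted))) {
    contained <- any(sites$site_start <= lifted[2] &
                       sites$site_end >= lifted[1])
  }
  list(ortholog_id = best_id, identity = identity,
       site_contained = contained,
       accepted = identity > min_identity && contained)
}

#' Call group-unique targets from interaction deltas
#'
#' Deltas must be computed with group A alleles as the reference and group B
#' alleles as the alternative: A-unique targets are `disrupted` deltas
#' (present under A, absent under B) and B-unique targets are `created`
#' deltas.
#'
#' @param deltas data.frame from [diff_targets()].
#' @param group_a,group_b group labels for the output.
#' @return list(`table` = per-interaction rows with a `unique_to` column,
#'   `counts` = data.frame(group, n_unique)).
#' @export
call_group_unique_targets <- function(deltas, group_a = "A", group_b = "B") {
  if (!is.character(group_a) || !is.character(group_b) ||
      is.na(group_a) || is.na(group_b)) {
    stop("unknown group label")
  }
  tab <- deltas[deltas$status %in% c("disrupted", "created"), , drop = FALSE]
  tab$unique_to <- ifelse(tab$status == "disrupted", group_a, group_b)
  counts <- data.frame(group = c(group_a, group_b),
                       n_unique = c(sum(tab$unique_to == group_a),
                                    sum(tab$unique_to == group_b)),
                       stringsAsFactors = FALSE)
  list(table = tab, counts = counts)
}

#' Full SNP-impact analysis over two genotype groups
#'
#' Reconstructs group-B snp-mRNAs (and snp-miRNAs, for SNPs falling in
#' mature sequences) from the VCF-derived variants, scans targets under
#' both allele sets, diffs the interaction sets per (miRNA, transcript) and
#' validates created sites against `ortholog_seqs`.
#'
#' @param mirna_loci loci data.frame (chrom, start, end, strand, mature_seq,
#'   mature_offset, id).
#' @param transcripts_a named character vector of group-A transcripts.
#' @param gene_models data.frame(transcript_id, chrom, start, end, strand).
#' @param variants variants data.frame from [read_variants()].
#' @param group_a,group_b group labels in the variant table.
#' @param params [score_params()].
#' @param ortholog_seqs transcripts of group B used for validation (default:
#'   reconstructed snp-mRNAs themselves are not re-used; pass the observed
#'   group-B transcript set).
#' @param min_identity orthologue identity threshold (exclusive).
#' @return list(deltas, unique_targets, interactions_a, interactions_b).
#' @export
snp_impact_analysis <- function(mirna_loci, transcripts_a, gene_models,
                                variants, group_a = "A", group_b = "B",
                                params = score_params(),
                                ortholog_seqs = NULL, min_identity = 0.90) {
  # group-B miRNA set: apply B-major alleles inside each mature
  mirnas_a <- stats::setNames(mirna_loci$mature_seq, mirna_loci$id)
  mirnas_b <- mirnas_a
  for (r in seq_len(nrow(mirna_loci))) {
    loc <- mirna_loci[r, ]
    if (is.na(loc$mature_offset)) next
    if (loc$strand == "+") {
      ms <- loc$start + loc$mature_offset
      me <- ms + nchar(loc$mature_seq)
    } else {
      me <- loc$end - loc$mature_offset
      ms <- me - nchar(loc$mature_seq)
    }
    snp <- build_snp_mirna(loc$mature_seq, loc$chrom, ms, me, loc$strand,
                           variants, group_b, base_id = loc$id)
    if (length(snp)) mirnas_b[[loc$id]] <- snp[[1]]$variant_seq
  }
  # group-B transcript set: apply B-major alleles inside each gene model
  transcripts_b <- transcripts_a
  snp_mrna_variants <- list()
  for (tid in names(transcripts_a)) {
    gm <- gene_models[gene_models$transcript_id == tid, , drop = FALSE]
    if (!nrow(gm)) next
    gm <- gm[1, ]
    sel <- variants$chrom == gm$chrom & variants$pos > gm$start &
      variants$pos <= gm$end
    vv <- variants[sel, , drop = FALSE]
    if (!nrow(vv)) next
    loc_rows <- list()
    for (i in seq_len(nrow(vv))) {
      alleles <- group_major_alleles(vv[i, , drop = FALSE], group_b)
      if (length(alleles) != 1L) next    # no calls or 50/50 tie: keep ref
      allele <- alleles[1]
      if (gm$strand == "+") {
        pos <- vv$pos[i] - gm$start
      } else {
        pos <- gm$end - vv$pos[i] + 1L
        allele <- chartr("ACGT", "TGCA", allele)
      }
      ref_local <- substr(transcripts_a[[tid]], pos, pos)
      if (allele == ref_local) next
      loc_rows[[length(loc_rows) + 1L]] <- data.frame(
        pos = pos, ref = ref_local, alt = allele, stringsAsFactors = FALSE)
    }
    if (length(loc_rows)) {
      lv <- do.call(rbind, loc_rows)
      lv <- lv[order(lv$pos), , drop = FALSE]
      ss <- apply_variants(transcripts_a[[tid]], lv, group = group_b,
                           base_id = tid)
      transcripts_b[[tid]] <- ss$variant_seq
      snp_mrna_variants[[tid]] <- lv
    }
  }
  scan_all <- function(mirnas, transcripts) {
    res <- list()
    for (mid in names(mirnas)) {
      for (tid in names(transcripts)) {
        s <- find_sites(mirnas[[mid]], transcripts[[tid]], params,
                        mirna_id = mid, transcript_id = tid)
        if (nrow(s)) res[[length(res) + 1L]] <- s
      }
    }
    if (!length(res)) return(empty_interactions())
    do.call(rbind, res)
  }
  ia <- scan_all(mirnas_a, transcripts_a)
  ib <- scan_all(mirnas_b, transcripts_b)
  deltas <- list()
  keys <- unique(rbind(ia[, c("mirna_id", "transcript_id")],
                       ib[, c("mirna_id", "transcript_id")]))
  for (r in seq_len(nrow(keys))) {
    mid <- keys$mirna_id[r]; tid <- keys$transcript_id[r]
    cause <- if (!identical(mirnas_a[[mid]], mirnas_b[[mid]])) "mirna_snp"
      else if (!identical(transcripts_a[[tid]], transcripts_b[[tid]]))
        "target_snp" else NA_character_
    d <- diff_targets(ia[ia$mirna_id == mid & ia$transcript_id == tid, ],
                      ib[ib$mirna_id == mid & ib$transcript_id == tid, ],
                      cause = cause)
    if (nrow(d)) deltas[[length(deltas) + 1L]] <- d
  }
  deltas <- if (length(deltas)) do.call(rbind, deltas) else
    diff_targets(ia[0, ], ib[0, ])
  # orthologue validation of created sites
  deltas$ortholog_id <- NA_character_
  deltas$ortholog_identity <- NA_real_
  deltas$ortholog_accepted <- NA
  if (!is.null(ortholog_seqs)) {
    for (r in which(deltas$status == "created")) {
      ov <- ortholog_validate(transcripts_b[[deltas$transcript_id[r]]],
                              ortholog_seqs,
                              mirnas_b[[deltas$mirna_id[r]]],
                              deltas$alt_start[r], deltas$alt_end[r],
                              params, min_identity)
      deltas$ortholog_id[r] <- ov$ortholog_id
      deltas$ortholog_identity[r] <- ov$identity
      deltas$ortholog_accepted[r] <- ov$accepted
    }
  }
  uniq <- call_group_unique_targets(deltas, group_a, group_b)
  list(deltas = deltas, unique_targets = uniq,
       interactions_a = ia, interactions_b = ib,
       mirnas_b = mirnas_b, transcripts_b = transcripts_b)
}
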