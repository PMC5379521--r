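# Annotation of miRNA loci from collapsed small-RNA reads: length and
# contaminant filtering, conserved matching against a reference mature set,
# genome-match capping, hairpin evaluation against community precursor
# criteria, miRNA* detection, and RPM expression.

#' Filter collapsed reads by length and exclusion sets
#'
#' @param reads data.frame (seq, count, library_id) as from
#'   [read_collapsed_reads()].
#' @param min_len,max_len inclusive length bounds (defaults 16 and 30 nt).
#' @param exclusion_sets named list of character vectors of sequences
#'   (mRNA / rRNA / repeat proxies); a read is rejected when it occurs as an
#'   exact substring of any sequence in a set.
#' @return list with `kept` (data.frame), `rejected` (data.frame with a
#'   `reason` column) and `report` (counts per rejection reason).
#' @export
filter_reads <- function(reads, min_len = 16L, max_len = 30L,
                         exclusion_sets = list()) {
  if (min_len > max_len) stop("min_len > max_len")
  len <- nchar(reads$seq)
  reason <- rep(NA_character_, nrow(reads))
  reason[len < min_len | len > max_len] <- "length"
  blobs <- lapply(exclusion_sets, paste, collapse = "\n")
  for (i in which(is.na(reason))) {
    for (nm in names(blobs)) {
      if (grepl(reads$seq[i], blobs[[nm]], fixed = TRUE)) {
        reason[i] <- paste0("contaminant:", nm)
        break
      }
    }
  }
  kept <- reads[is.na(reason), , drop = FALSE]
  rejected <- reads[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  tab <- table(reason[!is.na(reason)])
  report <- data.frame(reason = names(tab), n = as.integer(tab),
                       stringsAsFactors = FALSE)
  list(kept = kept, rejected = rejected, report = report)
}

#' Match a read against reference mature miRNAs
#'
#' Hamming comparison against equal-length references only (no indels);
#' returns the reference with the fewest mismatches if that count is within
#' `max_mismatch`, ties broken by reference file order.
#'
#' @param read_seq read sequence.
#' @param reference_mirnas named character vector of reference matures.
#' @param max_mismatch maximum allowed mismatches (default 2).
#' @return list(ref_id, mismatches) or NULL if unassigned.
#' @export
match_conserved <- function(read_seq, reference_mirnas, max_mismatch = 2L) {
  if (!length(reference_mirnas)) stop("empty reference miRNA set")
  rc <- seq_chars(read_seq)
  n <- nchar(read_seq)
  best_id <- NULL
  best_mm <- Inf
  for (id in names(reference_mirnas)) {
    ref <- reference_mirnas[[id]]
    if (nchar(ref) != n) next
    mm <- sum(seq_chars(ref) != rc)
    if (mm < best_mm) {
      best_mm <- mm
      best_id <- id
    }
  }
  if (is.null(best_id) || best_mm > max_mismatch) return(NULL)
  list(ref_id = best_id, mismatches = as.integer(best_mm))
}

#' Count exact genome occurrences of a read (both strands)
#'
#' @param read_seq read sequence (at least 10 nt).
#' @param genome named character vector of chromosomes.
#' @return integer: forward plus reverse-complement occurrences (overlapping
#'   occurrences counted).
#' @export
count_genome_matches <- function(read_seq, genome) {
  if (nchar(read_seq) < 10L) stop("read shorter than 10 nt: matching ambiguous")
  fwd <- Biostrings::DNAString(read_seq)
  rev <- Biostrings::DNAString(revcomp(read_seq))
  total <- 0L
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chrom]])
    total <- total + Biostrings::countPattern(fwd, subj) +
      Biostrings::countPattern(rev, subj)
  }
  total
}

#' Locate exact genome occurrences of a read
#'
#' @inheritParams count_genome_matches
#' @return data.frame(chrom, start, strand) with 0-based starts.
#' @export
locate_genome_matches <- function(read_seq, genome) {
  if (nchar(read_seq) < 10L) stop("read shorter than 10 nt: matching ambiguous")
  out <- list()
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chrom]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read_seq else revcomp(read_seq)
      hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj)
      if (length(hits)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = Biostrings::start(hits) - 1L,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Evaluate a precursor hairpin against community criteria
#'
#' Pass requires: the mature lies entirely on one arm (no pairing internal
#' to the mature, all pairing partners on one side), at most
#' `max_unpaired_mature` of its bases unpaired, and at least
#' `min_paired_fraction` of precursor bases paired.
#'
#' @param precursor_seq precursor sequence.
#' @param mature_seq mature sequence (must occur in the precursor).
#' @param structure a "hairpin_structure" for the precursor (default: fold).
#' @param criteria list(max_unpaired_mature = 4, min_paired_fraction = 0.5).
#' @return list(pass, diagnostics) where diagnostics holds each criterion's
#'   value and reason strings for failures.
#' @export
evaluate_hairpin <- function(precursor_seq, mature_seq,
                             structure = fold_nussinov(precursor_seq),
                             criteria = list()) {
  crit <- utils::modifyList(list(max_unpaired_mature = 4L,
                                 min_paired_fraction = 0.5), criteria)
  a <- regexpr(mature_seq, precursor_seq, fixed = TRUE)
  if (a < 0) stop("mature sequence not found in precursor")
  a <- as.integer(a)
  b <- a + nchar(mature_seq) - 1L
  partner <- structure$partner
  idx <- a:b
  internal <- any(!is.na(partner[idx]) & partner[idx] >= a & partner[idx] <= b)
  outside <- partner[idx][!is.na(partner[idx])]
  outside <- outside[outside < a | outside > b]
  both_sides <- length(outside) && any(outside < a) && any(outside > b)
  spans_loop <- internal || both_sides
  unpaired <- sum(is.na(partner[idx]))
  paired_fraction <- 2 * structure$n_pairs / nchar(precursor_seq)
  reasons <- character(0)
  if (spans_loop) reasons <- c(reasons, "spans-loop")
  if (unpaired > crit$max_unpaired_mature) {
    reasons <- c(reasons, sprintf("unpaired-mature %d > %d", unpaired,
                                  crit$max_unpaired_mature))
  }
  if (paired_fraction < crit$min_paired_fraction) {
    reasons <- c(reasons, sprintf("paired-fraction %.3f < %.2f",
                                  paired_fraction, crit$min_paired_fraction))
  }
  list(pass = !length(reasons),
       diagnostics = list(mature_start = a, mature_end = b,
                          unpaired_mature = unpaired,
                          paired_fraction = paired_fraction,
                          spans_loop = spans_loop, reasons = reasons))
}

#' Predict and confirm the miRNA* sequence of a hairpin
#'
#' The predicted star is the precursor segment pairing the mature, shifted
#' so both duplex ends carry 2-nt 3' overhangs. It is returned only if an
#' observed read matches it exactly (or within `end_slop` nt at either end).
#'
#' @param precursor_seq,mature_seq sequences; the hairpin must have passed
#'   [evaluate_hairpin()].
#' @param structure precursor structure (default: fold).
#' @param observed_reads character vector of read sequences from the same
#'   library.
#' @param end_slop allowed shift of either star end (0 = exact).
#' @return the star sequence, or NULL if absent/unsupported.
#' @export
find_star <- function(precursor_seq, mature_seq,
                      structure = fold_nussinov(precursor_seq),
                      observed_reads = character(0), end_slop = 0L) {
  a <- regexpr(mature_seq, precursor_seq, fixed = TRUE)
  if (a < 0) stop("mature sequence not found in precursor")
  a <- as.integer(a)
  m <- nchar(mature_seq)
  partner <- structure$partner
  rel_paired <- which(!is.na(partner[a:(a + m - 1L)]))
  if (!length(rel_paired)) return(NULL)
  # Each paired mature base anchors an extrapolated (bulge-free) duplex;
  # folds of windows with flanking context can misassign a few partners,
  # so every anchor proposes a candidate star interval and the first one
  # supported by an observed read wins.
  all_partners <- partner[a:(a + m - 1L)]
  all_partners <- all_partners[!is.na(all_partners)]
  for (j in rel_paired) {
    p <- partner[a + j - 1L]
    star_start <- p - ((m - 2L) - j)
    star_end <- p + (j - 1L) + 2L
    if (star_start > star_end) {
      tmp <- star_start; star_start <- star_end; star_end <- tmp
    }
    # a credible proposal must hold the bulk of the mature's partners;
    # isolated misassigned pairs would otherwise nominate far-away
    # intervals that can collide with unrelated observed reads
    inside <- sum(all_partners >= star_start - 2L &
                    all_partners <= star_end + 2L)
    if (inside < ceiling(length(all_partners) / 2)) next
    for (ds in (-end_slop):end_slop) {
      for (de in (-end_slop):end_slop) {
        s0 <- star_start + ds
        e0 <- star_end + de
        if (s0 < 1L || e0 > nchar(precursor_seq) || s0 >= e0) next
        cand <- substr(precursor_seq, s0, e0)
        if (cand %in% observed_reads) return(cand)
      }
    }
  }
  NULL
}

#' Reads-per-million normalization
#'
#' @param raw_count raw read count (vectorized).
#' @param library_total total reads in the library (> 0).
#' @return raw_count * 1e6 / library_total.
#' @export
compute_rpm <- function(raw_count, library_total) {
  if (length(library_total) != 1L || library_total <= 0) {
    stop("library_total must be a single positive number")
  }
  raw_count * 1e6 / library_total
}

#' Discover miRNA loci from collapsed reads
#'
#' Runs the annotation chain: length/contaminant filter, conserved matching
#' (Hamming <= `max_mismatch` against `reference_mirnas`), genome-match cap,
#' hairpin folding of both flanking windows at every genomic match,
#' precursor criteria, and miRNA* confirmation. Reads assigned to a
#' reference are labelled by `family_classes` ("conserved" unless the
#' family is listed as "known"); unassigned reads passing the hairpin
#' criteria become "specific_with_star" or "specific_candidate".
#'
#' @param reads collapsed reads data.frame.
#' @param genome named character vector of chromosomes.
#' @param reference_mirnas named character vector of reference matures.
#' @param exclusion_sets named list for [filter_reads()].
#' @param family_classes optional named character vector reference_id ->
#'   "conserved"/"known".
#' @param max_mismatch conserved-matching mismatch cap (default 2).
#' @param genome_match_cap maximum genomic matches (default 15).
#' @param window flanking window folded on each side of a match (default 200).
#' @param min_len,max_len read length bounds.
#' @param criteria hairpin criteria for [evaluate_hairpin()].
#' @param star_end_slop end slop for [find_star()].
#' @return list with `loci` (one row per annotated locus: id, chrom, start,
#'   end, strand, mature_seq, star_seq, arm, class_label, n_pairs,
#'   unpaired_mature), `expression` (per library RPM), `filter_report` and
#'   `candidate_report` (per-read diagnostics).
#' @export
discover_mirnas <- function(reads, genome, reference_mirnas,
                            exclusion_sets = list(), family_classes = NULL,
                            max_mismatch = 2L, genome_match_cap = 15L,
                            window = 200L, min_len = 16L, max_len = 30L,
                            criteria = list(), star_end_slop = 0L) {
  filt <- filter_reads(reads, min_len, max_len, exclusion_sets)
  kept <- filt$kept
  # unique sequences across libraries, keeping per-library counts
  useqs <- unique(kept$seq)
  all_read_seqs <- useqs
  loci <- list()
  cand_rows <- list()
  for (rs in useqs) {
    assignment <- match_conserved(rs, reference_mirnas, max_mismatch)
    nmatch <- count_genome_matches(rs, genome)
    note <- NULL
    if (nmatch == 0L) {
      note <- "no-genome-match"
    } else if (nmatch > genome_match_cap) {
      note <- sprintf("genome-matches %d > cap %d", nmatch, genome_match_cap)
    }
    if (!is.null(note)) {
      cand_rows[[length(cand_rows) + 1L]] <- data.frame(
        seq = rs, status = "excluded", detail = note, stringsAsFactors = FALSE)
      next
    }
    hits <- locate_genome_matches(rs, genome)
    best <- NULL
    better_than <- function(cand, best) {
      if (is.null(best)) return(TRUE)
      # miRNA* support dominates (it disambiguates the two fold
      # orientations of a hairpin), then fewer unpaired mature bases,
      # then total pairing
      if (cand$has_star != best$has_star) return(cand$has_star)
      if (cand$unpaired != best$unpaired) return(cand$unpaired < best$unpaired)
      cand$n_pairs > best$n_pairs
    }
    for (h in seq_len(nrow(hits))) {
      chrom <- hits$chrom[h]; s0 <- hits$start[h]; strand <- hits$strand[h]
      L <- nchar(rs)
      clen <- nchar(genome[[chrom]])
      wins <- list(c(max(0L, s0 - window), min(clen, s0 + L)),
                   c(max(0L, s0), min(clen, s0 + L + window)))
      for (wi in wins) {
        if (wi[2] - wi[1] < L + 10L) next
        prec <- extract_interval(genome, chrom, wi[1], wi[2], strand)
        if (!grepl(rs, prec, fixed = TRUE)) next
        st <- fold_nussinov(prec)
        ev <- evaluate_hairpin(prec, rs, st, criteria)
        if (!ev$pass) next
        star <- find_star(prec, rs, st, all_read_seqs, star_end_slop)
        cand <- list(chrom = chrom, start = wi[1], end = wi[2],
                     strand = strand, prec = prec, st = st, ev = ev,
                     n_pairs = st$n_pairs, star = star,
                     has_star = !is.null(star),
                     unpaired = ev$diagnostics$unpaired_mature)
        if (better_than(cand, best)) best <- cand
      }
    }
    if (is.null(best)) {
      cand_rows[[length(cand_rows) + 1L]] <- data.frame(
        seq = rs, status = "excluded", detail = "no-passing-hairpin",
        stringsAsFactors = FALSE)
      next
    }
    star <- best$star
    if (!is.null(assignment)) {
      fam_class <- "conserved"
      if (!is.null(family_classes) &&
          assignment$ref_id %in% names(family_classes)) {
        fam_class <- unname(family_classes[[assignment$ref_id]])
      }
      class_label <- fam_class
    } else {
      class_label <- if (!is.null(star)) "specific_with_star" else
        "specific_candidate"
    }
    mpos <- as.integer(regexpr(rs, best$prec, fixed = TRUE))
    arm <- if (mpos - 1L < nchar(best$prec) - (mpos + nchar(rs) - 1L)) "5p"
      else "3p"
    loci[[length(loci) + 1L]] <- data.frame(
      id = sprintf("mirlocus_%03d", length(loci) + 1L),
      chrom = best$chrom, start = best$start, end = best$end,
      strand = best$strand, mature_seq = rs,
      star_seq = if (is.null(star)) NA_character_ else star,
      arm = arm, class_label = class_label,
      mature_offset = mpos - 1L,
      ref_id = if (is.null(assignment)) NA_character_ else assignment$ref_id,
      n_pairs = best$n_pairs,
      unpaired_mature = best$ev$diagnostics$unpaired_mature,
      stringsAsFactors = FALSE)
    cand_rows[[length(cand_rows) + 1L]] <- data.frame(
      seq = rs, status = "locus", detail = class_label,
      stringsAsFactors = FALSE)
  }
  loci_df <- if (length(loci)) do.call(rbind, loci) else
    data.frame(id = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               mature_seq = character(0), star_seq = character(0),
               arm = character(0), class_label = character(0),
               mature_offset = integer(0),
               ref_id = character(0), n_pairs = integer(0),
               unpaired_mature = integer(0), stringsAsFactors = FALSE)
  # collapse duplex partners: when a star read was annotated as its own
  # locus, either its predicted star is the mature of the locus it came
  # from or vice versa — one direction of evidence is enough, and the
  # first-seen (mature, higher-count) locus of the pair is kept
  if (nrow(loci_df) > 1L) {
    drop <- rep(FALSE, nrow(loci_df))
    for (r in 2:nrow(loci_df)) {
      for (q in seq_len(r - 1L)) {
        if (drop[q]) next
        fwd <- !is.na(loci_df$star_seq[q]) &&
          identical(loci_df$star_seq[q], loci_df$mature_seq[r])
        bwd <- !is.na(loci_df$star_seq[r]) &&
          identical(loci_df$star_seq[r], loci_df$mature_seq[q])
        if (fwd || bwd) {
          drop[r] <- TRUE
          # the dropped partner's read is the kept locus's observed star
          if (bwd && is.na(loci_df$star_seq[q])) {
            loci_df$star_seq[q] <- loci_df$mature_seq[r]
            if (loci_df$class_label[q] == "specific_candidate") {
              loci_df$class_label[q] <- "specific_with_star"
            }
          }
        }
      }
    }
    loci_df <- loci_df[!drop, , drop = FALSE]
  }
  expression <- expression_table(loci_df, kept)
  list(loci = loci_df, expression = expression,
       filter_report = filt$report,
       candidate_report = if (length(cand_rows)) do.call(rbind, cand_rows)
       else data.frame(seq = character(0), status = character(0),
                       detail = character(0), stringsAsFactors = FALSE))
}

#' Per-library RPM expression table for annotated loci
#'
#' @param loci loci data.frame from [discover_mirnas()].
#' @param reads collapsed reads (post-filter) with library_id.
#' @return data.frame(mirna_id, library_id, raw_count, rpm).
#' @export
expression_table <- function(loci, reads) {
  out <- list()
  for (lib in unique(reads$library_id)) {
    sub <- reads[reads$library_id == lib, , drop = FALSE]
    total <- sum(sub$count)
    for (r in seq_len(nrow(loci))) {
      cnt <- sum(sub$count[sub$seq == loci$mature_seq[r]])
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = loci$id[r], library_id = lib, raw_count = cnt,
        rpm = if (total > 0) compute_rpm(cnt, total) else 0,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(0), library_id = character(0),
                      raw_count = numeric(0), rpm = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
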