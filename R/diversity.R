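# Nucleotide diversity (pi) per miRNA-related locus class, and a
# length-matched random-interval permutation test against the genome
# background.
#
# pi is the average pairwise per-site difference fraction. From variants it
# is computed with the unbiased per-site heterozygosity n/(n-1) * (1 - sum
# p_a^2), summed over variant sites and divided by the full interval length
# (monomorphic sites count in the denominator).

#' Nucleotide diversity from explicit haplotypes
#'
#' Mean over all unordered haplotype pairs of Hamming distance divided by
#' compared length; positions where any haplotype carries a non-ACGT
#' character are excluded from numerator and denominator.
#'
#' @param seqs character vector of >= 2 equal-length haplotype sequences.
#' @return pi (numeric scalar).
#' @export
pi_from_haplotypes <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 haplotypes")
  if (length(unique(nchar(seqs))) != 1L) stop("haplotypes differ in length")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  ok <- apply(mat, 2, function(col) all(col %in% BASES))
  if (!any(ok)) stop("no comparable (all-ACGT) positions")
  mat <- mat[, ok, drop = FALSE]
  n <- nrow(mat)
  L <- ncol(mat)
  # per-column mean pair difference via allele counts
  npairs <- n * (n - 1) / 2
  col_diff <- apply(mat, 2, function(col) {
    cnt <- table(col)
    1 - sum(cnt * (cnt - 1) / 2) / npairs
  })
  sum(col_diff) / L
}

# Per-variant contribution (n/(n-1)) * (1 - sum p^2); n from the variant's
# allele number or the supplied fallback. Sites with n < 2 contribute 0.
variant_site_contrib <- function(variants, n_haplotypes = NULL) {
  vapply(seq_len(nrow(variants)), function(i) {
    cnt <- variants$counts[[i]]
    if (sum(cnt) == 0) return(0)        # all calls missing at the site
    n <- variants$an[i]
    if (!is.null(n_haplotypes) && (is.na(n) || n == 0)) n <- n_haplotypes
    if (is.na(n) || n < 2) return(0)
    p <- cnt[cnt > 0] / sum(cnt)
    (n / (n - 1)) * (1 - sum(p^2))
  }, numeric(1))
}

#' Nucleotide diversity from variant allele frequencies
#'
#' @param variants data.frame as from [read_variants()] (columns chrom, pos,
#'   an, counts). Monomorphic positions need not be listed.
#' @param intervals data.frame(chrom, start, end), 0-based half-open.
#' @param n_haplotypes fallback haplotype count for sites lacking `an`.
#' @return pi (numeric scalar): summed site contributions over total
#'   interval length.
#' @export
pi_from_variants <- function(variants, intervals, n_haplotypes = NULL) {
  L <- sum(intervals$end - intervals$start)
  if (L <= 0) stop("total interval length is zero")
  if (!nrow(variants)) return(0)
  contrib <- variant_site_contrib(variants, n_haplotypes)
  total <- 0
  for (r in seq_len(nrow(intervals))) {
    sel <- variants$chrom == intervals$chrom[r] &
      variants$pos > intervals$start[r] & variants$pos <= intervals$end[r]
    total <- total + sum(contrib[sel])
  }
  total / L
}

#' Build locus-class interval annotations
#'
#' Produces, per miRNA provenance group (conserved/known vs specific),
#' merged interval sets for mature sequences, precursors and 2-kb flanks,
#' plus miRNA-target binding sites lifted from transcript to genome
#' coordinates through gene models, and the genome background.
#'
#' @param mirna_loci loci data.frame from [discover_mirnas()]; must carry
#'   chrom, start, end, strand, mature_seq, class_label. Mature genomic
#'   intervals are located inside the precursor interval.
#' @param interactions data.frame from [find_sites()] rows (needs
#'   transcript_id, site_start, site_end, mirna_id).
#' @param gene_models data.frame(transcript_id, chrom, start, end, strand),
#'   0-based half-open; transcripts without a model are skipped (logged in
#'   attribute `n_sites_unliftable`).
#' @param genome_lengths named integer vector of chromosome lengths.
#' @param flank flank size in nt (default 2000).
#' @param mirna_classes optional named character vector mirna_id ->
#'   "conserved_known"/"specific" used to split binding sites; default: all
#'   sites pooled.
#' @return data.frame(class_name, group, chrom, start, end) of merged
#'   intervals (0-based half-open).
#' @export
classify_loci <- function(mirna_loci, interactions = NULL, gene_models = NULL,
                          genome_lengths, flank = 2000L,
                          mirna_classes = NULL) {
  grp_of <- function(cl) {
    if (cl %in% c("conserved", "known")) "conserved_known" else "specific"
  }
  rows <- list()
  add <- function(class_name, group, chrom, start, end) {
    if (end > start) {
      rows[[length(rows) + 1L]] <<- data.frame(
        class_name = class_name, group = group, chrom = chrom,
        start = as.integer(start), end = as.integer(end),
        stringsAsFactors = FALSE)
    }
  }
  for (r in seq_len(nrow(mirna_loci))) {
    loc <- mirna_loci[r, ]
    grp <- grp_of(loc$class_label)
    clen <- genome_lengths[[loc$chrom]]
    add("precursor", grp, loc$chrom, loc$start, loc$end)
    add("flank_2kb", grp, loc$chrom, max(0L, loc$start - flank), loc$start)
    add("flank_2kb", grp, loc$chrom, loc$end, min(clen, loc$end + flank))
    # mature genomic interval from the mature's offset within the precursor
    m <- nchar(loc$mature_seq)
    if (!is.null(loc$mature_offset) && !is.na(loc$mature_offset)) {
      off <- loc$mature_offset           # 0-based offset on precursor strand
      if (loc$strand == "+") {
        add("mature", grp, loc$chrom, loc$start + off, loc$start + off + m)
      } else {
        add("mature", grp, loc$chrom, loc$end - off - m, loc$end - off)
      }
    }
  }
  n_unliftable <- 0L
  if (!is.null(interactions) && nrow(interactions) && !is.null(gene_models)) {
    for (r in seq_len(nrow(interactions))) {
      it <- interactions[r, ]
      gm <- gene_models[gene_models$transcript_id == it$transcript_id, ]
      if (!nrow(gm)) {
        n_unliftable <- n_unliftable + 1L
        next
      }
      gm <- gm[1, ]
      grp <- "all"
      if (!is.null(mirna_classes) && it$mirna_id %in% names(mirna_classes)) {
        grp <- unname(mirna_classes[[it$mirna_id]])
      }
      if (gm$strand == "+") {
        add("binding_site", grp, gm$chrom, gm$start + it$site_start - 1L,
            gm$start + it$site_end)
      } else {
        add("binding_site", grp, gm$chrom, gm$end - it$site_end,
            gm$end - it$site_start + 1L)
      }
    }
  }
  for (chrom in names(genome_lengths)) {
    add("genome_background", "all", chrom, 0L, genome_lengths[[chrom]])
  }
  df <- do.call(rbind, rows)
  # merge overlapping intervals within each (class, group, chrom)
  merged <- list()
  for (key in unique(paste(df$class_name, df$group, df$chrom, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- df[df$class_name == parts[1] & df$group == parts[2] &
                df$chrom == parts[3], , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = sub$start + 1L,
                                           end = sub$end))
    merged[[length(merged) + 1L]] <- data.frame(
      class_name = parts[1], group = parts[2], chrom = parts[3],
      start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$class_name, out$group, out$chrom, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sites_unliftable") <- n_unliftable
  out
}

# Fast pi over many interval sets: precompute per-chromosome sorted variant
# positions and cumulative contributions.
pi_index <- function(variants, n_haplotypes = NULL) {
  contrib <- variant_site_contrib(variants, n_haplotypes)
  idx <- list()
  for (chrom in unique(variants$chrom)) {
    sel <- which(variants$chrom == chrom)
    ord <- sel[order(variants$pos[sel])]
    idx[[chrom]] <- list(pos = variants$pos[ord],
                         cum = cumsum(contrib[ord]))
  }
  idx
}

pi_from_index <- function(idx, intervals) {
  L <- sum(intervals$end - intervals$start)
  total <- 0
  for (r in seq_len(nrow(intervals))) {
    ci <- idx[[intervals$chrom[r]]]
    if (is.null(ci)) next
    hi <- findInterval(intervals$end[r], ci$pos)
    lo <- findInterval(intervals$start[r], ci$pos)  # pos <= start excluded
    if (hi > lo) {
      total <- total + ci$cum[hi] - if (lo > 0) ci$cum[lo] else 0
    }
  }
  total / L
}

#' Permutation test of class pi against the genome background
#'
#' Draws `n_perm` random interval sets matched in number and length to the
#' class intervals (uniform placement over chromosomes, weighted by the
#' number of valid start positions), computes pi for each, and returns the
#' one-sided p-value for the class pi being low:
#' p = (1 + #\{null pi <= observed\}) / (n_perm + 1).
#'
#' @param class_intervals data.frame(chrom, start, end) for one class.
#' @param variants variants data.frame.
#' @param genome_lengths named chromosome lengths.
#' @param n_perm number of permutations (>= 1; 199 is a sensible floor for
#'   reporting at alpha = 0.05).
#' @param seed RNG seed.
#' @param n_haplotypes fallback haplotype count.
#' @return list(p, observed_pi, null_pi).
#' @export
permutation_test_pi <- function(class_intervals, variants, genome_lengths,
                                n_perm = 199L, seed = 1L,
                                n_haplotypes = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  lens <- class_intervals$end - class_intervals$start
  if (any(lens > max(unlist(genome_lengths)))) {
    stop("class interval longer than every chromosome")
  }
  idx <- pi_index(variants, n_haplotypes)
  obs <- pi_from_index(idx, class_intervals)
  chroms <- names(genome_lengths)
  clens <- as.numeric(unlist(genome_lengths))
  null_pi <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      draw <- lapply(lens, function(L) {
        valid <- pmax(clens - L + 1, 0)
        ci <- sample.int(length(chroms), 1L, prob = valid)
        s0 <- sample.int(valid[ci], 1L) - 1L
        c(ci, s0, s0 + L)
      })
      dm <- do.call(rbind, draw)
      pi_from_index(idx, data.frame(chrom = chroms[dm[, 1]],
                                    start = dm[, 2], end = dm[, 3],
                                    stringsAsFactors = FALSE))
    }, numeric(1))
  })
  list(p = (1 + sum(null_pi <= obs)) / (n_perm + 1), observed_pi = obs,
       null_pi = null_pi)
}

#' Diversity summary across locus classes
#'
#' @param classes data.frame from [classify_loci()].
#' @param variants variants data.frame.
#' @param genome_lengths named chromosome lengths.
#' @param n_perm permutations per class.
#' @param seed RNG seed (each class gets a derived child seed).
#' @param n_haplotypes fallback haplotype count.
#' @return data.frame(class_name, group, n_sites, n_variant_sites, pi,
#'   perm_p, n_perm, seed).
#' @export
diversity_table <- function(classes, variants, genome_lengths,
                            n_perm = 199L, seed = 1L, n_haplotypes = NULL) {
  keys <- unique(classes[, c("class_name", "group")])
  out <- list()
  for (r in seq_len(nrow(keys))) {
    sub <- classes[classes$class_name == keys$class_name[r] &
                     classes$group == keys$group[r], , drop = FALSE]
    n_sites <- sum(sub$end - sub$start)
    nvar <- 0L
    for (i in seq_len(nrow(sub))) {
      nvar <- nvar + sum(variants$chrom == sub$chrom[i] &
                           variants$pos > sub$start[i] &
                           variants$pos <= sub$end[i])
    }
    pi <- pi_from_variants(variants, sub, n_haplotypes)
    pp <- if (keys$class_name[r] == "genome_background") NA_real_ else
      permutation_test_pi(sub, variants, genome_lengths, n_perm,
                          child_seed(seed, paste0("perm_", keys$class_name[r],
                                                  "_", keys$group[r])),
                          n_haplotypes)$p
    out[[length(out) + 1L]] <- data.frame(
      class_name = keys$class_name[r], group = keys$group[r],
      n_sites = n_sites, n_variant_sites = nvar, pi = pi, perm_p = pp,
      n_perm = n_perm, seed = seed, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
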