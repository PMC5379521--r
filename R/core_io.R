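# Readers/writers for the external formats shared by every stage:
# FASTA sequences, collapsed small-RNA reads, VCF variants with per-group
# allele frequencies, and strand-aware interval extraction.

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are normalized to uppercase DNA (U -> T); the original alphabet
#' (RNA/DNA) is kept per record in the `alphabet` attribute. Record ids are
#' the first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return named character vector of sequences, with attribute `alphabet`
#'   (named character vector, "RNA" or "DNA" per record).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1])
  raw <- as.character(set)
  alphabet <- ifelse(grepl("[Uu]", raw), "RNA", "DNA")
  seqs <- normalize_seq(raw)
  if (any(!nzchar(seqs))) stop("empty sequence for id: ", ids[!nzchar(seqs)][1])
  names(seqs) <- ids
  names(alphabet) <- ids
  attr(seqs, "alphabet") <- alphabet
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector. If `alphabet` (argument or attribute)
#'   marks a record as RNA it is written with U instead of T.
#' @param path output file.
#' @param alphabet optional named character vector ("DNA"/"RNA").
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, alphabet = attr(seqs, "alphabet"),
                        width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    s <- seqs[[id]]
    if (!is.null(alphabet) && identical(unname(alphabet[id]), "RNA")) {
      s <- chartr("T", "U", s)
    }
    writeLines(paste0(">", id), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read collapsed small-RNA reads
#'
#' Supports three dialects: `header_xN` (headers like `>r1_x57`),
#' `header_count` (`>r1 count=57`) and `tsv` (sequence<TAB>count).
#'
#' @param path input file.
#' @param dialect one of "header_xN", "header_count", "tsv".
#' @param library_id label attached to every read.
#' @return data.frame with columns seq, count, library_id.
#' @export
read_collapsed_reads <- function(path,
                                 dialect = c("header_xN", "header_count", "tsv"),
                                 library_id = "lib1") {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                             col.names = c("seq", "count"))
    counts <- suppressWarnings(as.integer(tab$count))
    if (anyNA(counts)) stop("unparseable count at TSV row ",
                            which(is.na(counts))[1])
    seqs <- normalize_seq(tab$seq)
  } else {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty reads file: ", path)
    headers <- names(set)
    pat <- if (dialect == "header_xN") ".*_x([0-9]+)\\s*$" else
      ".*count=([0-9]+)\\s*$"
    ok <- grepl(pat, headers)
    if (any(!ok)) stop("unparseable header at record ", which(!ok)[1],
                       ": ", headers[!ok][1])
    counts <- as.integer(sub(pat, "\\1", headers))
    seqs <- normalize_seq(as.character(set))
  }
  if (any(counts < 1L)) {
    stop("non-positive read count at record ", which(counts < 1L)[1])
  }
  data.frame(seq = unname(seqs), count = counts, library_id = library_id,
             stringsAsFactors = FALSE)
}

# Expand an allele string into its IUPAC base set ("-" and multi-base
# strings are indels and return NULL).
expand_allele <- function(a) {
  if (nchar(a) != 1L || a == "-" || a == "*") return(NULL)
  IUPAC_SETS[[a]]
}

#' Read SNPs from a VCF with per-group allele frequencies
#'
#' Keeps biallelic and multiallelic single-base substitutions; indel records
#' are skipped and counted (attribute `n_indels_skipped`). Degenerate IUPAC
#' allele letters are expanded to their base sets, each expanded base taking
#' an equal share of that allele's count. Missing genotypes are excluded
#' from frequency denominators.
#'
#' @param path VCF file (plain text).
#' @param group_map named character vector sample -> group, or a two-column
#'   data.frame (sample, group).
#' @return data.frame with columns chrom, pos (1-based), ref, alt
#'   (comma-joined), an (total non-missing allele count) and list-columns
#'   `counts` (overall base counts) and `freqs` (per-group named list of
#'   base frequencies).
#' @export
read_variants <- function(path, group_map) {
  if (is.data.frame(group_map)) {
    gm <- stats::setNames(as.character(group_map[[2]]),
                          as.character(group_map[[1]]))
  } else gm <- group_map
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(vcf@gt)[-1]))
  samples <- colnames(gt)
  missing_samples <- setdiff(names(gm), samples)
  if (length(missing_samples)) {
    stop("sample in group map absent from VCF: ", missing_samples[1])
  }
  groups <- unique(unname(gm))
  n_indels <- 0L
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    alleles <- c(ref, alts)
    sets <- lapply(alleles, expand_allele)
    if (any(vapply(sets, is.null, logical(1)))) {
      n_indels <- n_indels + 1L
      next
    }
    # per-sample allele index counts
    count_bases <- function(smp) {
      cnt <- stats::setNames(numeric(4), BASES)
      for (s in smp) {
        g <- gt[i, s]
        if (is.na(g) || g %in% c(".", "./.", ".|.")) next
        idx <- strsplit(g, "[/|]")[[1]]
        for (a in idx) {
          if (a == ".") next
          set <- sets[[as.integer(a) + 1L]]
          cnt[set] <- cnt[set] + 1 / length(set)
        }
      }
      cnt
    }
    all_cnt <- count_bases(samples)
    an <- sum(all_cnt)
    gf <- lapply(groups, function(g) {
      cnt <- count_bases(names(gm)[gm == g])
      tot <- sum(cnt)
      if (tot == 0) return(stats::setNames(numeric(0), character(0)))
      f <- cnt[cnt > 0] / tot
      f
    })
    names(gf) <- groups
    rows[[i]] <- list(chrom = fix[i, "CHROM"],
                      pos = as.integer(fix[i, "POS"]),
                      ref = ref, alt = paste(alts, collapse = ","),
                      an = an, counts = all_cnt, freqs = gf)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- data.frame(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    pos = vapply(rows, `[[`, integer(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    an = vapply(rows, `[[`, numeric(1), "an"),
    stringsAsFactors = FALSE)
  out$counts <- lapply(rows, `[[`, "counts")
  out$freqs <- lapply(rows, `[[`, "freqs")
  attr(out, "n_indels_skipped") <- n_indels
  out
}

#' Extract a genomic interval
#'
#' Intervals are 0-based half-open; minus-strand intervals are returned
#' reverse-complemented.
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds.
#' @param strand "+" or "-".
#' @return the extracted sequence (character scalar).
#' @export
extract_interval <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  L <- nchar(genome[[chrom]])
  if (start < 0 || end > L || start >= end) {
    stop("interval [", start, ",", end, ") out of bounds for ", chrom,
         " (length ", L, ")")
  }
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}
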