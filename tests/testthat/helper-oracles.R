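# Independent brute-force oracles used to verify the analysis code.
# These deliberately re-derive each quantity from its definition with
# plain loops, sharing no code path with the package internals.

oracle_pair_pen <- function(mb, sb, params) {
  wc <- (mb == "A" && sb == "T") || (mb == "T" && sb == "A") ||
    (mb == "G" && sb == "C") || (mb == "C" && sb == "G")
  if (wc) return(0)
  if ((mb == "G" && sb == "T") || (mb == "T" && sb == "G")) {
    return(params$gu_penalty)
  }
  params$mismatch_penalty
}

# exhaustive enumeration of all <=1-bulge alignments of a duplex
oracle_score_duplex <- function(mirna, site, params) {
  m <- nchar(mirna)
  s <- nchar(site)
  mir <- strsplit(mirna, "")[[1]]
  rs <- rev(strsplit(site, "")[[1]])
  w <- rep(1, m)
  w[params$core_start:min(params$core_end, m)] <- 2
  best <- Inf
  if (s == m) {
    tot <- 0
    for (i in seq_len(m)) tot <- tot + w[i] * oracle_pair_pen(mir[i], rs[i], params)
    best <- tot
  } else if (s == m - 1) {
    for (k in seq_len(m)) {             # miRNA base k bulged
      tot <- params$bulge_penalty * w[k]
      for (i in seq_len(m)) {
        if (i == k) next
        r <- if (i < k) i else i - 1
        tot <- tot + w[i] * oracle_pair_pen(mir[i], rs[r], params)
      }
      best <- min(best, tot)
    }
  } else if (s == m + 1) {
    for (k in seq_len(m + 1)) {         # site base (3'->5' index k) bulged
      tot <- params$bulge_penalty * w[min(k, m)]
      for (i in seq_len(m)) {
        r <- if (i < k) i else i + 1
        tot <- tot + w[i] * oracle_pair_pen(mir[i], rs[r], params)
      }
      best <- min(best, tot)
    }
  } else stop("bad lengths")
  best
}

# brute-force site search: every window, every length class, then collapse
# overlap clusters to the lowest score (leftmost on ties)
oracle_find_sites <- function(mirna, transcript, params) {
  m <- nchar(mirna)
  L <- nchar(transcript)
  cand <- list()
  for (len in c(m - 1, m, m + 1)) {
    if (len < 1 || len > L) next
    for (st in seq_len(L - len + 1)) {
      sc <- oracle_score_duplex(mirna, substr(transcript, st, st + len - 1),
                                params)
      if (sc <= params$cutoff) {
        cand[[length(cand) + 1]] <- c(st, st + len - 1, sc)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(site_start = integer(0), site_end = integer(0),
                      score = numeric(0)))
  }
  cd <- do.call(rbind, cand)
  cd <- cd[order(cd[, 1], cd[, 2]), , drop = FALSE]
  # overlap clustering by iterative union
  out <- list()
  i <- 1
  while (i <= nrow(cd)) {
    j <- i
    hi <- cd[i, 2]
    while (j < nrow(cd) && cd[j + 1, 1] <= hi) {
      j <- j + 1
      hi <- max(hi, cd[j, 2])
    }
    blk <- cd[i:j, , drop = FALSE]
    best <- blk[blk[, 3] == min(blk[, 3]), , drop = FALSE]
    best <- best[which.min(best[, 1]), ]
    out[[length(out) + 1]] <- best
    i <- j + 1
  }
  od <- do.call(rbind, out)
  data.frame(site_start = od[, 1], site_end = od[, 2], score = od[, 3])
}

# maximal nested pairing by plain recursion (no shared code with the DP)
oracle_nussinov <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  ok <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i, j - 1)
    for (k in i:(j - min_loop - 1)) {
      if (ok(ch[k], ch[j])) {
        left <- if (k > i) rec(i, k - 1) else 0
        best <- max(best, left + 1 + rec(k + 1, j - 1))
      }
    }
    best
  }
  rec(1, length(ch))
}

# pi by direct double loop over haplotype pairs
oracle_pi <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  keep <- apply(mat, 2, function(cl) all(cl %in% c("A", "C", "G", "T")))
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat)
  tot <- 0
  np <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(mat[i, ] != mat[j, ]) / ncol(mat)
      np <- np + 1
    }
  }
  tot / np
}

# direct restatement of the cleavage-category definitions
oracle_classify <- function(counts, pos) {
  key <- as.character(pos)
  c0 <- counts[key]
  if (is.na(c0)) return(NA_integer_)
  c0 <- unname(c0)
  M <- max(counts)
  med <- median(counts)
  if (c0 == 1) return(4L)
  if (c0 == M && sum(counts == M) == 1) return(0L)
  if (c0 == M) return(1L)
  if (c0 > med && c0 < M) return(2L)
  3L
}

# Needleman-Wunsch score by straightforward DP (small instances)
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- gap * (0:n)
  D[1, ] <- gap * (0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- if (ca[i] == cb[j]) match else mismatch
      D[i + 1, j + 1] <- max(D[i, j] + sub, D[i, j + 1] + gap,
                             D[i + 1, j] + gap)
    }
  }
  D[n + 1, m + 1]
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# minimal variants data.frame in read_variants() layout
make_variant_df <- function(chrom, pos, counts_list, an = NULL,
                            freqs = NULL) {
  n <- length(pos)
  df <- data.frame(chrom = rep(chrom, length.out = n), pos = pos,
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  df$an <- if (is.null(an)) vapply(counts_list, sum, numeric(1)) else an
  df$counts <- counts_list
  df$freqs <- if (is.null(freqs)) replicate(n, list(), simplify = FALSE)
    else freqs
  df
}
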