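# Plant miRNA-target complementarity scoring and site search.
#
# The classical plant penalty scheme: each miRNA position i (counted from
# the miRNA 5' end) is paired against the site base opposite it (the site
# read 3'->5'), with penalties mismatch 1, G:U wobble 0.5, bulge 1, all
# doubled inside the core region (miRNA positions 2-13 by default), at most
# one single-nucleotide bulge, and a reporting cutoff of 4.0. Cleavage is
# called opposite miRNA position 10.

#' Scoring parameters for miRNA-target duplexes
#'
#' @param mismatch_penalty penalty per mismatched pair.
#' @param gu_penalty penalty per G:U wobble pair.
#' @param bulge_penalty penalty for the single allowed bulged base.
#' @param core_start,core_end 1-based miRNA positions whose penalties are
#'   doubled (the seed/cleavage-critical core).
#' @param cutoff maximum total penalty for a reported site.
#' @return list of class "score_params".
#' @export
score_params <- function(mismatch_penalty = 1, gu_penalty = 0.5,
                         bulge_penalty = 1, core_start = 2L, core_end = 13L,
                         cutoff = 4) {
  stopifnot(mismatch_penalty >= 0, gu_penalty >= 0, bulge_penalty >= 0,
            core_start >= 1, core_end >= core_start)
  structure(list(mismatch_penalty = mismatch_penalty,
                 gu_penalty = gu_penalty, bulge_penalty = bulge_penalty,
                 core_start = as.integer(core_start),
                 core_end = as.integer(core_end), cutoff = cutoff),
            class = "score_params")
}

# 4x4 penalty matrix pm[mir_base, site_base] before position weighting;
# rows/cols indexed by codes 1..4 (A,C,G,T). Non-ACGT site bases are treated
# as mismatches (code NA handled by callers).
penalty_matrix <- function(params) {
  pm <- matrix(params$mismatch_penalty, 4, 4, dimnames = list(BASES, BASES))
  pm["A", "T"] <- pm["T", "A"] <- pm["G", "C"] <- pm["C", "G"] <- 0
  pm["G", "T"] <- pm["T", "G"] <- params$gu_penalty
  pm
}

position_weights <- function(m, params) {
  w <- rep(1, m)
  w[params$core_start:min(params$core_end, m)] <- 2
  w
}

state_of <- function(pen, params) {
  ifelse(pen == 0, "match",
         ifelse(pen == params$gu_penalty & params$gu_penalty != params$mismatch_penalty,
                "gu", "mismatch"))
}

#' Score one miRNA against one candidate site
#'
#' The site is given 5'->3' as it appears in the transcript and is read
#' 3'->5' against the miRNA. At most one single-nucleotide bulge is allowed
#' (on the miRNA if the site is one base shorter, on the site if one base
#' longer). A site base bulged between miRNA positions k-1 and k takes
#' effective miRNA position min(k, m) for core doubling.
#'
#' @param mirna_seq,site_seq DNA strings; lengths may differ by at most 1.
#' @param params a [score_params()] object.
#' @return list with `score`, `states` (per alignment column: match / gu /
#'   mismatch / bulge), `aln` (string: "|" match, ":" G:U, "." mismatch,
#'   "-" bulge), `bulge_type` ("none"/"mirna"/"site") and `bulge_pos`
#'   (alignment column of the bulge, NA if none).
#' @export
score_duplex <- function(mirna_seq, site_seq, params = score_params()) {
  m <- nchar(mirna_seq); s <- nchar(site_seq)
  if (abs(s - m) > 1L) stop("site and miRNA lengths differ by more than 1")
  mir <- seq_codes(mirna_seq)
  rs <- rev(seq_codes(site_seq))        # rs[i] is opposite miRNA position i
  if (anyNA(mir)) stop("miRNA contains non-ACGT characters")
  pm <- penalty_matrix(params)
  w <- position_weights(m, params)
  pen_at <- function(j, r) {            # weighted penalty miRNA j vs rs[r]
    b <- rs[r]
    p <- if (is.na(b)) params$mismatch_penalty else pm[mir[j], b]
    w[j] * p
  }
  base_pen <- function(j, r) {          # unweighted, for state labelling
    b <- rs[r]
    if (is.na(b)) params$mismatch_penalty else pm[mir[j], b]
  }
  if (s == m) {
    pens <- vapply(seq_len(m), function(j) pen_at(j, j), numeric(1))
    states <- state_of(vapply(seq_len(m), function(j) base_pen(j, j), numeric(1)), params)
    res <- list(score = sum(pens), states = states, bulge_type = "none",
                bulge_pos = NA_integer_)
  } else if (s == m - 1L) {
    # miRNA base k bulged; miRNA j pairs rs[j] for j<k, rs[j-1] for j>k
    A <- vapply(seq_len(m - 1L), function(j) pen_at(j, j), numeric(1))
    B <- c(0, vapply(2:m, function(j) pen_at(j, j - 1L), numeric(1)))
    prefA <- c(0, cumsum(A))
    sufB <- rev(cumsum(rev(B)))         # sufB[k] = sum B[k..m]
    sufB <- c(sufB, 0)
    sc <- vapply(seq_len(m), function(k) {
      prefA[k] + params$bulge_penalty * w[k] + sufB[k + 1L]
    }, numeric(1))
    k <- which.min(sc)
    states <- character(m)
    if (k > 1L) states[seq_len(k - 1L)] <-
      state_of(vapply(seq_len(k - 1L), function(j) base_pen(j, j), numeric(1)), params)
    states[k] <- "bulge"
    if (k < m) states[(k + 1L):m] <-
      state_of(vapply((k + 1L):m, function(j) base_pen(j, j - 1L), numeric(1)), params)
    res <- list(score = sc[k], states = states, bulge_type = "mirna",
                bulge_pos = k)
  } else {
    # site base bulged at rs position k (k = 1..m+1); miRNA j pairs rs[j]
    # for j<k and rs[j+1] for j>=k
    A <- vapply(seq_len(m), function(j) pen_at(j, j), numeric(1))
    B <- vapply(seq_len(m), function(j) pen_at(j, j + 1L), numeric(1))
    prefA <- c(0, cumsum(A))
    sufB <- c(rev(cumsum(rev(B))), 0)   # sufB[k] = sum B[k..m]
    sc <- vapply(seq_len(m + 1L), function(k) {
      prefA[k] + params$bulge_penalty * w[min(k, m)] + sufB[k]
    }, numeric(1))
    k <- which.min(sc)
    states <- character(m + 1L)
    if (k > 1L) states[seq_len(k - 1L)] <-
      state_of(vapply(seq_len(k - 1L), function(j) base_pen(j, j), numeric(1)), params)
    states[k] <- "bulge"
    if (k <= m) states[(k + 1L):(m + 1L)] <-
      state_of(vapply(k:m, function(j) base_pen(j, j + 1L), numeric(1)), params)
    res <- list(score = sc[k], states = states, bulge_type = "site",
                bulge_pos = k)
  }
  res$aln <- paste(c(match = "|", gu = ":", mismatch = ".",
                     bulge = "-")[res$states], collapse = "")
  res
}

#' Recompute a duplex score from its alignment states
#'
#' @param states character vector of alignment-column states.
#' @param bulge_type "none", "mirna" or "site".
#' @param params a [score_params()] object.
#' @return numeric score.
#' @export
score_from_alignment <- function(states, bulge_type = "none",
                                 params = score_params()) {
  ncols <- length(states)
  m <- if (bulge_type == "site") ncols - 1L else ncols
  w <- position_weights(m, params)
  bk <- if (bulge_type == "site") which(states == "bulge")[1] else NA_integer_
  total <- 0
  for (i in seq_len(ncols)) {
    pos <- i
    if (bulge_type == "site") {
      # columns before the bulged site base sit opposite miRNA position i,
      # the bulge takes min(k, m), later columns sit opposite i - 1
      pos <- if (i < bk) i else if (i == bk) min(bk, m) else i - 1L
    }
    p <- switch(states[i],
                match = 0,
                gu = params$gu_penalty,
                mismatch = params$mismatch_penalty,
                bulge = params$bulge_penalty)
    total <- total + w[pos] * p
  }
  total
}

empty_interactions <- function() {
  data.frame(mirna_id = character(0), transcript_id = character(0),
             site_start = integer(0), site_end = integer(0),
             score = numeric(0), alignment = character(0),
             bulge_type = character(0), bulge_pos = integer(0),
             cleavage_pos = integer(0), approximate = logical(0),
             stringsAsFactors = FALSE)
}

# Vectorized minimal-score scan of one miRNA over every window of one
# transcript, for one window-length class ("m-1", "m", "m+1").
# Returns numeric vector indexed by window end position e (1-based), NA
# where the window does not fit.
scan_windows <- function(mirQ, L, m, params, len_class) {
  # mirQ: m x L matrix of weighted penalties Q[j, t]
  wb <- params$bulge_penalty * position_weights(m, params)
  out <- rep(NA_real_, L)
  if (len_class == "m") {
    if (L < m) return(out)
    es <- m:L
    S <- numeric(length(es))
    for (j in seq_len(m)) S <- S + mirQ[j, es - j + 1L]
    out[es] <- S
  } else if (len_class == "m+1") {
    if (L < m + 1L) return(out)
    es <- (m + 1L):L
    SB <- numeric(length(es))
    for (j in seq_len(m)) SB <- SB + mirQ[j, es - j]
    best <- rep(Inf, length(es))
    pa <- numeric(length(es)); pb <- numeric(length(es))
    for (k in seq_len(m + 1L)) {
      cand <- pa + wb[min(k, m)] + (SB - pb)
      best <- pmin(best, cand)
      if (k <= m) {
        pa <- pa + mirQ[k, es - k + 1L]
        pb <- pb + mirQ[k, es - k]
      }
    }
    out[es] <- best
  } else {                              # "m-1": miRNA bulge
    if (L < m - 1L) return(out)
    es <- (m - 1L):L
    SB <- numeric(length(es))           # sum over j=2..m of b_j
    for (j in 2:m) SB <- SB + mirQ[j, es - j + 2L]
    best <- rep(Inf, length(es))
    pa <- numeric(length(es)); pb <- numeric(length(es))
    # pa after k-1 terms of a_j (j=1..m-1); pb after k terms of b_j (j<=k)
    for (k in seq_len(m)) {
      if (k >= 2L) pb <- pb + mirQ[k, es - k + 2L]
      cand <- pa + wb[k] + (SB - pb)
      best <- pmin(best, cand)
      if (k <= m - 1L) pa <- pa + mirQ[k, es - k + 1L]
    }
    out[es] <- best
  }
  out
}

#' Find all target sites of a miRNA on a transcript
#'
#' Scores every window of length m-1, m and m+1 (m = miRNA length), keeps
#' windows with penalty <= cutoff, collapses overlapping windows to the
#' lowest-scoring one (ties to the leftmost) and returns them in coordinate
#' order with the inferred cleavage position.
#'
#' @param mirna_seq miRNA sequence (DNA letters).
#' @param transcript_seq transcript sequence.
#' @param params a [score_params()] object.
#' @param mirna_id,transcript_id labels carried into the result.
#' @return data.frame with one row per site: mirna_id, transcript_id,
#'   site_start, site_end (1-based inclusive), score, alignment, bulge_type,
#'   bulge_pos, cleavage_pos, approximate.
#' @export
find_sites <- function(mirna_seq, transcript_seq, params = score_params(),
                       mirna_id = "mir", transcript_id = "tx") {
  m <- nchar(mirna_seq)
  L <- nchar(transcript_seq)
  empty <- empty_interactions()
  if (L < m - 1L) return(empty)
  mir <- seq_codes(mirna_seq)
  tx <- seq_codes(transcript_seq)
  pm <- penalty_matrix(params)
  w <- position_weights(m, params)
  # Q[j, t]: weighted penalty of miRNA j opposite transcript base t
  Q <- matrix(0, m, L)
  for (j in seq_len(m)) {
    p <- pm[mir[j], tx]
    p[is.na(p)] <- params$mismatch_penalty
    Q[j, ] <- w[j] * p
  }
  cand <- list()
  for (lc in c("m-1", "m", "m+1")) {
    site_len <- m + switch(lc, `m-1` = -1L, m = 0L, `m+1` = 1L)
    sc <- scan_windows(Q, L, m, params, lc)
    hits <- which(!is.na(sc) & sc <= params$cutoff)
    for (e in hits) {
      cand[[length(cand) + 1L]] <- c(start = e - site_len + 1L, end = e,
                                     score = sc[e])
    }
  }
  if (!length(cand)) return(empty)
  cdf <- as.data.frame(do.call(rbind, cand))
  cdf <- cdf[order(cdf$start, cdf$end), , drop = FALSE]
  # collapse overlap clusters to the lowest score (tie -> leftmost)
  keep <- list()
  grp_max <- -Inf
  grp <- integer(0)
  flush <- function(grp) {
    sub <- cdf[grp, , drop = FALSE]
    best <- which(sub$score == min(sub$score))
    sub[best[which.min(sub$start[best])], , drop = FALSE]
  }
  for (r in seq_len(nrow(cdf))) {
    if (!length(grp) || cdf$start[r] <= grp_max) {
      grp <- c(grp, r)
      grp_max <- max(grp_max, cdf$end[r])
    } else {
      keep[[length(keep) + 1L]] <- flush(grp)
      grp <- r
      grp_max <- cdf$end[r]
    }
  }
  keep[[length(keep) + 1L]] <- flush(grp)
  kdf <- do.call(rbind, keep)
  rows <- lapply(seq_len(nrow(kdf)), function(r) {
    st <- kdf$start[r]; en <- kdf$end[r]
    dup <- score_duplex(mirna_seq, substr(transcript_seq, st, en), params)
    cl <- cleavage_position(site_end = en, bulge_type = dup$bulge_type,
                            bulge_pos = dup$bulge_pos, mirna_len = m)
    data.frame(mirna_id = mirna_id, transcript_id = transcript_id,
               site_start = as.integer(st), site_end = as.integer(en),
               score = dup$score, alignment = dup$aln,
               bulge_type = dup$bulge_type,
               bulge_pos = if (is.na(dup$bulge_pos)) NA_integer_ else
                 as.integer(dup$bulge_pos),
               cleavage_pos = cl$pos, approximate = cl$approximate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$site_start), , drop = FALSE]
}

#' Infer the cleavage position of an interaction
#'
#' The transcript coordinate of the base opposite miRNA position 10; for a
#' bulge-free site this is `site_end - 9`. A bulge at miRNA positions 9-11
#' makes the call approximate.
#'
#' @param site_end 1-based transcript coordinate of the site 3' end (the
#'   base opposite miRNA position 1).
#' @param bulge_type "none", "mirna" or "site".
#' @param bulge_pos alignment column of the bulge (NA if none).
#' @param mirna_len miRNA length.
#' @return list with `pos` (1-based transcript coordinate) and
#'   `approximate` (logical).
#' @export
cleavage_position <- function(site_end, bulge_type = "none",
                              bulge_pos = NA_integer_, mirna_len = 21L) {
  approx <- FALSE
  if (bulge_type == "none" || is.na(bulge_pos)) {
    pos <- site_end - 9L
  } else if (bulge_type == "mirna") {
    if (bulge_pos > 10L) pos <- site_end - 9L
    else if (bulge_pos < 10L) pos <- site_end - 8L
    else pos <- site_end - 9L
    if (bulge_pos >= 9L && bulge_pos <= 11L) approx <- TRUE
  } else {                              # site bulge at rs column bulge_pos
    if (bulge_pos > 10L) pos <- site_end - 9L
    else pos <- site_end - 10L
    if (bulge_pos >= 9L && bulge_pos <= 11L) approx <- TRUE
  }
  list(pos = as.integer(pos), approximate = approx)
}
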