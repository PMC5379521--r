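# Degradome (PARE) 5'-tag mapping, CleaveLand-style cleavage-category
# classification, a per-site significance test, and confirmation of
# predicted interactions.

#' Map degradome tags onto transcripts
#'
#' Tags are exact 5' sequence prefixes; each tag's 5'-end position is
#' recorded on every transcript where the tag matches exactly. Tags shorter
#' than `min_tag_len` are skipped (counted in attribute `n_short_skipped`);
#' tags matching several transcripts are counted on each and flagged.
#'
#' @param tags data.frame(seq, count).
#' @param transcripts named character vector.
#' @param min_tag_len minimum usable tag length (default 15).
#' @return named list of profiles, one per transcript with any tag: list
#'   (transcript_id, counts = named numeric by 1-based position,
#'   total_tags, transcript_length, multi = logical per stored position).
#' @export
map_tags <- function(tags, transcripts, min_tag_len = 15L) {
  profiles <- lapply(names(transcripts), function(tid) {
    list(transcript_id = tid, counts = numeric(0),
         total_tags = 0, transcript_length = nchar(transcripts[[tid]]),
         multi = logical(0))
  })
  names(profiles) <- names(transcripts)
  n_short <- 0L
  for (i in seq_len(nrow(tags))) {
    tg <- tags$seq[i]
    if (nchar(tg) < min_tag_len) {
      n_short <- n_short + 1L
      next
    }
    hit_tids <- character(0)
    hit_pos <- list()
    for (tid in names(transcripts)) {
      g <- gregexpr(tg, transcripts[[tid]], fixed = TRUE)[[1]]
      if (g[1] > 0) {
        hit_tids <- c(hit_tids, tid)
        hit_pos[[tid]] <- as.integer(g)
      }
    }
    multi <- length(hit_tids) > 1L
    for (tid in hit_tids) {
      for (p in hit_pos[[tid]]) {
        key <- as.character(p)
        cur <- profiles[[tid]]$counts[key]
        profiles[[tid]]$counts[key] <-
          (if (is.na(cur)) 0 else cur) + tags$count[i]
        profiles[[tid]]$multi[key] <-
          isTRUE(profiles[[tid]]$multi[key]) || multi
        profiles[[tid]]$total_tags <- profiles[[tid]]$total_tags +
          tags$count[i]
      }
    }
  }
  profiles <- Filter(function(p) length(p$counts) > 0, profiles)
  attr(profiles, "n_short_skipped") <- n_short
  profiles
}

#' Classify a candidate cleavage position (CleaveLand-style categories)
#'
#' With c the tag count at the position, M the profile maximum and med the
#' median over stored (nonzero) positions: category 4 if c == 1; 0 if
#' c > 1 and c is the unique maximum; 1 if c > 1 and the maximum is shared;
#' 2 if med < c < M; 3 if 1 < c <= med. Positions with no tags get no call
#' (NA).
#'
#' @param profile a profile from [map_tags()].
#' @param position 1-based transcript position.
#' @param median_include_zeros include zero-count positions in the median
#'   (default FALSE: median over stored positions only).
#' @return integer category 0-4, or NA if no tag at the position.
#' @export
classify_site <- function(profile, position, median_include_zeros = FALSE) {
  if (position < 1L || position > profile$transcript_length) {
    stop("position outside transcript")
  }
  key <- as.character(position)
  c0 <- profile$counts[key]
  if (is.na(c0)) return(NA_integer_)
  c0 <- unname(c0)
  M <- max(profile$counts)
  med <- if (median_include_zeros) {
    all_counts <- numeric(profile$transcript_length)
    all_counts[as.integer(names(profile$counts))] <- profile$counts
    stats::median(all_counts)
  } else stats::median(profile$counts)
  if (c0 == 1) return(4L)
  if (c0 == M) {
    if (sum(profile$counts == M) == 1L) return(0L) else return(1L)
  }
  if (c0 > med) return(2L)
  3L
}

#' Significance of a cleavage position under a uniform-null model
#'
#' Binomial tail p = P(X >= c) for X ~ Binomial(total_tags,
#' 1/effective_positions), effective_positions = transcript_length -
#' tag_len + 1. The seeded resampling variant places all tags uniformly at
#' random and uses the empirical tail.
#'
#' @param profile a profile from [map_tags()].
#' @param position 1-based transcript position.
#' @param tag_len tag length used for the effective position count.
#' @param method "binomial" (closed form) or "resampling".
#' @param n_shuffles,seed resampling controls.
#' @return p-value in (0, 1].
#' @export
site_pvalue <- function(profile, position, tag_len = 20L,
                        method = c("binomial", "resampling"),
                        n_shuffles = 1000L, seed = 1L) {
  method <- match.arg(method)
  eff <- profile$transcript_length - tag_len + 1L
  if (eff <= 0) stop("effective position count <= 0")
  key <- as.character(position)
  c0 <- profile$counts[key]
  c0 <- if (is.na(c0)) 0 else unname(c0)
  if (c0 == 0) return(1.0)
  n <- profile$total_tags
  if (method == "binomial") {
    stats::pbinom(c0 - 1, n, 1 / eff, lower.tail = FALSE)
  } else {
    with_seed(seed, {
      hits <- vapply(seq_len(n_shuffles), function(s) {
        placed <- sample.int(eff, n, replace = TRUE)
        sum(placed == 1L) >= c0      # null is exchangeable across positions
      }, logical(1))
      (1 + sum(hits)) / (n_shuffles + 1)
    })
  }
}

#' Confirm a predicted interaction against a degradome profile
#'
#' Looks for tags within `window` nt of the predicted cleavage position and
#' returns the best call (lowest category, then highest count), with its
#' binomial p-value.
#'
#' @param interaction one row from [find_sites()] (needs cleavage_pos,
#'   transcript_id, mirna_id).
#' @param profile profile for the same transcript.
#' @param window search half-width around the predicted position (default 1).
#' @param tag_len tag length for [site_pvalue()].
#' @param alpha significance level (default 0.05).
#' @return data.frame row (transcript_id, mirna_id, position, count,
#'   category, p_value, significant) or NULL if no tags in the window.
#' @export
confirm_interaction <- function(interaction, profile, window = 1L,
                                tag_len = 20L, alpha = 0.05) {
  center <- interaction$cleavage_pos
  cand <- (center - window):(center + window)
  cand <- cand[cand >= 1L & cand <= profile$transcript_length]
  cand <- cand[as.character(cand) %in% names(profile$counts)]
  if (!length(cand)) return(NULL)
  cats <- vapply(cand, function(p) classify_site(profile, p), integer(1))
  cnts <- unname(profile$counts[as.character(cand)])
  ord <- order(cats, -cnts, abs(cand - center))
  best <- ord[1]
  p <- site_pvalue(profile, cand[best], tag_len)
  data.frame(transcript_id = profile$transcript_id,
             mirna_id = interaction$mirna_id,
             position = as.integer(cand[best]), count = cnts[best],
             category = cats[best], p_value = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}
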