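# RNA secondary structure by Nussinov maximum base pairing.
#
# Deterministic and exactly checkable against enumeration of nested
# pairings, which is what the hairpin criteria need; structures from an
# external thermodynamic folder can be injected through parse_dotbracket().

# 4x4 logical: which base pairs are allowed (Watson-Crick + G:T wobble).
pairable_matrix <- function() {
  P <- matrix(FALSE, 4, 4, dimnames = list(BASES, BASES))
  P["A", "T"] <- P["T", "A"] <- TRUE
  P["G", "C"] <- P["C", "G"] <- TRUE
  P["G", "T"] <- P["T", "G"] <- TRUE
  P
}

#' Fold a sequence by Nussinov maximum pairing
#'
#' Finds a nested pairing of maximal cardinality over the allowed pairs
#' \{A:T, G:C, G:T\} with at least `min_loop` unpaired bases inside every
#' hairpin loop. Traceback is deterministic: at each subproblem the 3' base
#' is paired with the smallest admissible partner before it is left
#' unpaired, so pairing is preferred over bifurcation.
#'
#' @param seq DNA string (ACGT only after degenerate expansion).
#' @param min_loop minimum unpaired loop length (default 3).
#' @return object of class "hairpin_structure": list with `seq`, `pairs`
#'   (two-column matrix of 1-based paired indices, i < j), `n_pairs`,
#'   `partner` (integer vector, NA where unpaired) and `db` (dot-bracket).
#' @export
fold_nussinov <- function(seq, min_loop = 3L) {
  codes <- seq_codes(seq)
  if (anyNA(codes)) stop("fold_nussinov: sequence contains non-ACGT characters")
  n <- length(codes)
  if (n < min_loop + 2L) {
    return(structure_from_pairs(seq, matrix(integer(0), ncol = 2)))
  }
  P <- pairable_matrix()
  # can_pair[k, j]: may bases k and j pair
  can <- P[codes, codes, drop = FALSE]
  N <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- N[i, j - 1L]
      ks <- i:(j - min_loop - 1L)
      ks <- ks[can[ks, j]]
      if (length(ks)) {
        left <- ifelse(ks == i, 0L, N[i, pmax(ks - 1L, 1L)])
        vals <- left + N[cbind(ks + 1L, j - 1L)] + 1L
        best <- max(best, max(vals))
      }
      N[i, j] <- best
    }
  }
  # deterministic traceback (explicit stack)
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i < min_loop + 1L || N[i, j] == 0L) next
    placed <- FALSE
    ks <- i:(j - min_loop - 1L)
    ks <- ks[can[ks, j]]
    for (k in ks) {
      left <- if (k == i) 0L else N[i, k - 1L]
      if (left + N[k + 1L, j - 1L] + 1L == N[i, j]) {
        pairs <- rbind(pairs, c(k, j))
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        placed <- TRUE
        break
      }
    }
    if (!placed) stack[[length(stack) + 1L]] <- c(i, j - 1L)
  }
  structure_from_pairs(seq, pairs)
}

structure_from_pairs <- function(seq, pairs) {
  n <- nchar(seq)
  if (length(pairs)) {
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  partner <- rep(NA_integer_, n)
  db <- rep(".", n)
  if (nrow(pairs)) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  structure(list(seq = seq, pairs = pairs, n_pairs = nrow(pairs),
                 partner = partner, db = paste(db, collapse = "")),
            class = "hairpin_structure")
}

#' Import a structure from dot-bracket notation
#'
#' Hook for substituting structures computed by an external thermodynamic
#' folder for the built-in maximum-pairing fold.
#'
#' @param seq the folded sequence.
#' @param db dot-bracket string of the same length ("(", ")", ".").
#' @return a "hairpin_structure" object.
#' @export
parse_dotbracket <- function(seq, db) {
  if (nchar(db) != nchar(seq)) stop("dot-bracket length != sequence length")
  ch <- seq_chars(db)
  if (any(!ch %in% c("(", ")", "."))) stop("invalid dot-bracket character")
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket at position ", i)
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '('")
  structure_from_pairs(seq, pairs)
}
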