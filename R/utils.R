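# Shared alphabet and small-sequence helpers.
#
# All sequences are handled internally as uppercase DNA character strings
# (U is normalized to T on input). Intervals are 0-based half-open with an
# explicit strand; positions reported to users are 1-based.

BASES <- c("A", "C", "G", "T")

# IUPAC degenerate letters -> base sets (used when expanding variant alleles)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_SETS)

#' Normalize a nucleotide string
#'
#' Uppercases and converts U to T. Errors on characters outside the IUPAC
#' alphabet.
#'
#' @param x character vector of sequences.
#' @return normalized character vector.
#' @export
normalize_seq <- function(x) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl(paste0("[^", paste(IUPAC_LETTERS, collapse = ""), "]"), x)
  if (any(bad)) {
    stop("non-IUPAC character in sequence: ", substr(x[bad][1], 1, 40))
  }
  x
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences (IUPAC letters allowed).
#' @return reverse complement of each element.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Encode a sequence as integer codes 1..4 (A,C,G,T), NA for anything else.
seq_codes <- function(s) match(seq_chars(s), BASES)

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic child seed for a labelled component stream; stays < 2^31.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483587) + 1L
}

random_seq <- function(n, alphabet = BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
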