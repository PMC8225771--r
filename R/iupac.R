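# IUPAC nucleotide alphabet as 4-bit base sets (A=1, C=2, G=4, T=8).
# The bitmask representation makes the two degeneracy relations used by the
# site scanner cheap: subset (bitwAnd(s, p) == s) and non-empty intersection
# (bitwAnd(s, p) > 0).
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

IUPAC_LETTERS <- names(IUPAC_MASK)

# complement is a bijection on base sets: A<->T, C<->G, everything else follows
IUPAC_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_TO   <- "TGCAYRSWMKVHDBN"

#' Normalise a nucleotide sequence to the IUPAC alphabet
#'
#' Uppercases, maps U to T and verifies that every residue is one of the 15
#' IUPAC nucleotide codes. Used at every parse boundary; downstream code can
#' then assume clean sequences.
#'
#' @param x Character vector of sequences.
#' @param what Label used in error messages (e.g. a record id).
#' @return The normalised character vector.
#' @export
iupac_normalize <- function(x, what = "sequence") {
  if (length(x) == 0L) stop("no sequence supplied for ", what)
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- regexpr(sprintf("[^%s]", IUPAC_FROM), x)
  if (any(x == "")) {
    stop("empty sequence for ", what)
  }
  hit <- which(bad > 0L)
  if (length(hit) > 0L) {
    i <- hit[1L]
    stop(sprintf(
      "non-IUPAC character '%s' at position %d in %s%s",
      substr(x[i], bad[i], bad[i]), bad[i], what,
      if (length(x) > 1L) sprintf(" (element %d)", i) else ""
    ))
  }
  x
}

#' Reverse complement of an IUPAC sequence
#'
#' Degeneracy-aware: ambiguity codes map to the code of the complemented base
#' set (e.g. R = A/G becomes Y = C/T), so `iupac_revcomp()` is an involution
#' on the full 15-letter alphabet.
#'
#' @param x Character vector of IUPAC sequences.
#' @return Character vector of reverse complements.
#' @export
iupac_revcomp <- function(x) {
  x <- iupac_normalize(x, "revcomp input")
  comp <- chartr(IUPAC_FROM, IUPAC_TO, x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# integer bitmask vector for one sequence string
iupac_mask <- function(seq) {
  unname(IUPAC_MASK[strsplit(seq, "", fixed = TRUE)[[1L]]])
}
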