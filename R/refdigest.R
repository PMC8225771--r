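LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family",
                   "genus", "species")

#' Read an annotated reference sequence set
#'
#' Reads a multi-FASTA of marker-gene reference sequences and attaches
#' taxonomy from a two-column TSV (`id`, `lineage`), where `lineage` is a
#' semicolon-delimited string of ranks from domain down to species (trailing
#' ranks may be absent). Sequences are uppercased and U is mapped to T; any
#' other non-IUPAC residue is an error.
#'
#' @param fasta_path Path to the FASTA file. The record id is the first
#'   whitespace-delimited token of the description line.
#' @param taxonomy_path Path to the taxonomy TSV.
#' @param permissive If `TRUE`, records missing from the taxonomy table get
#'   an all-`NA` lineage instead of raising an error.
#' @return A `data.frame` of class `trflp_refset` with columns `id`, `seq`,
#'   `lineage` and one column per rank.
#' @export
read_reference <- function(fasta_path, taxonomy_path, permissive = FALSE) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id: ", dup[1L])
  }
  seqchr <- as.character(seqs)
  seqchr <- vapply(seq_along(seqchr), function(i) {
    iupac_normalize(unname(seqchr[i]), sprintf("record '%s'", ids[i]))
  }, character(1))

  tax <- utils::read.delim(taxonomy_path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  for (col in c("id", "lineage")) {
    if (!col %in% names(tax)) {
      stop("taxonomy table lacks mandatory column '", col, "'")
    }
  }
  idx <- match(ids, tax$id)
  if (anyNA(idx) && !permissive) {
    stop("FASTA id '", ids[which(is.na(idx))[1L]],
         "' absent from taxonomy table (use permissive = TRUE to keep it)")
  }
  lineage <- ifelse(is.na(idx), "", tax$lineage[idx])
  ranks <- t(vapply(lineage, parse_lineage, character(length(LINEAGE_RANKS))))
  out <- data.frame(id = ids, seq = unname(seqchr),
                    lineage = unname(lineage),
                    ranks, row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("trflp_refset", "data.frame")
  out
}

#' Remove exact duplicate sequences
#'
#' Keeps the first occurrence (input order) of every distinct sequence string
#' and reports which records were dropped in favour of which kept record.
#'
#' @param records A `trflp_refset` (or any data.frame with `id` and `seq`).
#' @return A list with `records` (the kept rows) and `removed`, a data.frame
#'   mapping each `removed_id` to the `kept_id` it duplicated.
#' @export
dedup_records <- function(records) {
  dup <- duplicated(records$seq)
  first_of <- records$id[match(records$seq, records$seq)]
  removed <- data.frame(removed_id = records$id[dup],
                        kept_id = first_of[dup],
                        stringsAsFactors = FALSE)
  kept <- records[!dup, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept, removed = removed)
}

# vectorised degeneracy-aware window scan over a mask vector.
# guaranteed: sequence base set a subset of the pattern base set everywhere;
# possible:   non-empty intersection everywhere.
scan_mask <- function(smask, pmask, semantics) {
  n <- length(smask)
  m <- length(pmask)
  k <- n - m + 1L
  if (k < 1L) return(integer(0))
  ok <- rep(TRUE, k)
  for (j in seq_len(m)) {
    s <- smask[j:(j + k - 1L)]
    ok <- ok & if (semantics == "guaranteed") {
      bitwAnd(s, pmask[j]) == s
    } else {
      bitwAnd(s, pmask[j]) > 0L
    }
  }
  which(ok)
}

#' Locate restriction sites under degeneracy-aware semantics
#'
#' Scans every window of the top strand and, when the recognition pattern is
#' not its own reverse complement, of the bottom strand (reported as
#' top-strand coordinates of the site start). Two semantics resolve IUPAC
#' ambiguity between sequence and pattern:
#'
#' * `"guaranteed"`: a window matches iff at every position the sequence
#'   code's base set is a subset of the pattern code's base set - every
#'   disambiguation of the sequence carries the site.
#' * `"possible"`: a non-empty intersection suffices - some disambiguation
#'   carries the site.
#'
#' `"guaranteed"` is the default: degenerate primer tags contribute many N
#' positions, and `"possible"` semantics would manufacture spurious cut sites
#' inside them.
#'
#' @param seq A single IUPAC sequence string.
#' @param enzyme A [enzyme()] object.
#' @param semantics `"guaranteed"` or `"possible"`.
#' @return Strictly increasing integer vector of 0-based site start positions.
#' @examples
#' find_sites("GGGAGCTGGG", enzyme("AluI", "AGCT", 2))
#' @export
find_sites <- function(seq, enzyme, semantics = c("guaranteed", "possible")) {
  semantics <- match.arg(semantics)
  seq <- iupac_normalize(seq, "find_sites input")
  if (nchar(seq) < nchar(enzyme$site)) {
    stop("sequence shorter than the recognition site of ", enzyme$name)
  }
  smask <- iupac_mask(seq)
  hits <- scan_mask(smask, iupac_mask(enzyme$site), semantics)
  rc_site <- iupac_revcomp(enzyme$site)
  if (rc_site != enzyme$site) {
    hits <- sort(unique(c(hits, scan_mask(smask, iupac_mask(rc_site),
                                          semantics))))
  }
  as.integer(hits) - 1L
}

#' Construct a primer-tagged amplicon
#'
#' Prepends the forward primer and appends the reverse complement of the
#' reverse primer, reproducing the standard amplicon structure (for the
#' default 23-bp primers and a 588-bp insert, a 634-bp tagged amplicon).
#'
#' @param insert Insert sequence (IUPAC string).
#' @param fwd,rev [primer()] objects.
#' @return A list of class `trflp_amplicon` with `seq` and `insert_len`.
#' @export
tag_with_primers <- function(insert, fwd, rev) {
  insert <- iupac_normalize(insert, "insert")
  structure(list(seq = paste0(fwd$seq, insert, iupac_revcomp(rev$seq)),
                 insert_len = nchar(insert)),
            class = "trflp_amplicon")
}

# leftmost window at/after `from` (1-based) where the primer is compatible
# with the sequence under possible (non-empty intersection) semantics
first_binding <- function(smask, pmask, from = 1L) {
  n <- length(smask)
  m <- length(pmask)
  if (from > n - m + 1L) return(NA_integer_)
  ok <- rep(TRUE, n - m - from + 2L)
  for (j in seq_len(m)) {
    s <- smask[(from + j - 1L):(n - m + j)]
    ok <- ok & (bitwAnd(s, pmask[j]) > 0L)
  }
  w <- which(ok)
  if (length(w) == 0L) NA_integer_ else from + w[1L] - 1L
}

#' Primer-anchored in silico PCR
#'
#' Finds the leftmost top-strand window compatible with the forward primer
#' and the leftmost downstream window whose reverse complement is compatible
#' with the reverse primer (compatibility = non-empty IUPAC intersection at
#' every aligned position), then returns the tagged amplicon
#' `fwd + insert + revcomp(rev)` where the insert is the template between the
#' two binding windows. Returns `NULL` ("no amplicon") when either primer
#' fails to bind in a consistent orientation.
#'
#' @param template Template sequence (IUPAC string).
#' @param fwd,rev [primer()] objects.
#' @return A `trflp_amplicon` or `NULL`.
#' @export
insilico_pcr <- function(template, fwd, rev) {
  template <- iupac_normalize(template, "template")
  smask <- iupac_mask(template)
  fmask <- iupac_mask(fwd$seq)
  rmask <- iupac_mask(iupac_revcomp(rev$seq))
  i <- first_binding(smask, fmask)
  if (is.na(i)) return(NULL)
  j <- first_binding(smask, rmask, from = i + length(fmask))
  if (is.na(j)) return(NULL)
  insert <- substr(template, i + length(fmask), j - 1L)
  if (nchar(insert) == 0L) return(NULL)
  tag_with_primers(insert, fwd, rev)
}

#' Labelled terminal fragment of a digested amplicon
#'
#' The detected fragment runs from the labelled 5' terminus to the first cut:
#' length = first site start (0-based) + `cut_offset`. With no site the whole
#' amplicon survives and is flagged `unrestricted`.
#'
#' @param tagged A `trflp_amplicon` (or plain sequence string).
#' @param enzyme A [enzyme()] object.
#' @param semantics Degeneracy semantics passed to [find_sites()].
#' @return List with `length` (bp) and `unrestricted` (logical).
#' @export
terminal_fragment <- function(tagged, enzyme,
                              semantics = c("guaranteed", "possible")) {
  semantics <- match.arg(semantics)
  seq <- if (inherits(tagged, "trflp_amplicon")) tagged$seq else tagged
  sites <- find_sites(seq, enzyme, semantics)
  if (length(sites) == 0L) {
    list(length = nchar(seq), unrestricted = TRUE)
  } else {
    list(length = sites[1L] + enzyme$cut_offset, unrestricted = FALSE)
  }
}

#' Digest a reference set into a terminal-fragment profile
#'
#' Tags every record with the primer pair, digests it in silico, and returns
#' one labelled terminal fragment per record with its lineage carried along
#' (the in silico TRF profile).
#'
#' @param records A `trflp_refset`.
#' @param fwd,rev [primer()] objects.
#' @param enzyme A [enzyme()] object.
#' @param semantics Degeneracy semantics passed to [find_sites()].
#' @return A `data.frame` of class `trflp_fragments` with columns
#'   `record_id`, `length`, `unrestricted`, `lineage` and the rank columns;
#'   attribute `enzyme` records the enzyme name.
#' @export
digest_dataset <- function(records, fwd, rev, enzyme,
                           semantics = c("guaranteed", "possible")) {
  semantics <- match.arg(semantics)
  if (nrow(records) == 0L) stop("no records to digest")
  frags <- lapply(records$seq, function(s) {
    terminal_fragment(tag_with_primers(s, fwd, rev), enzyme, semantics)
  })
  out <- data.frame(
    record_id = records$id,
    length = vapply(frags, `[[`, numeric(1), "length"),
    unrestricted = vapply(frags, `[[`, logical(1), "unrestricted"),
    stringsAsFactors = FALSE
  )
  keep <- intersect(c("lineage", LINEAGE_RANKS), names(records))
  out <- cbind(out, records[, keep, drop = FALSE])
  rownames(out) <- NULL
  attr(out, "enzyme") <- enzyme$name
  class(out) <- c("trflp_fragments", "data.frame")
  out
}
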