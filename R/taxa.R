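#' Parse a semicolon-delimited lineage string
#'
#' Splits `"domain;phylum;class;order;family;genus;species"` into the seven
#' canonical ranks. Missing trailing ranks and empty fields become `NA`; more
#' than seven fields is an error.
#'
#' @param lineage_string A single lineage string (may be empty).
#' @return Named character vector over the seven ranks.
#' @export
parse_lineage <- function(lineage_string) {
  out <- stats::setNames(rep(NA_character_, length(LINEAGE_RANKS)),
                         LINEAGE_RANKS)
  if (is.na(lineage_string) || lineage_string == "") return(out)
  parts <- trimws(strsplit(lineage_string, ";", fixed = TRUE)[[1L]])
  if (length(parts) > length(LINEAGE_RANKS)) {
    stop("lineage has ", length(parts), " fields; at most ",
         length(LINEAGE_RANKS), " ranks are allowed")
  }
  parts[parts == ""] <- NA_character_
  out[seq_along(parts)] <- parts
  out
}

#' Distinct-taxon counts over a set of fragment hits
#'
#' @param hits A data.frame of fragments carrying the rank columns.
#' @param count_na If `TRUE`, unannotated (`NA`) values count as one
#'   pseudo-taxon per rank; by default only named taxa are counted.
#' @return List with `n_phyla`, `n_genera` and `tallies`, a per-rank list of
#'   descending counts per taxon.
#' @export
rollup_taxa_counts <- function(hits, count_na = FALSE) {
  tallies <- lapply(LINEAGE_RANKS, function(rk) {
    v <- if (rk %in% names(hits)) hits[[rk]] else character(0)
    if (!count_na) v <- v[!is.na(v)] else v[is.na(v)] <- "NA"
    if (length(v) == 0L) return(integer(0))
    sort(table(v), decreasing = TRUE)
  })
  names(tallies) <- LINEAGE_RANKS
  list(n_phyla = length(tallies$phylum),
       n_genera = length(tallies$genus),
       tallies = tallies)
}

#' Match experimental oTRFs against an in silico profile
#'
#' For each experimental oTRF label, collects (a) the in silico TRFs whose
#' size equals the label exactly and (b) the members of every in silico oTRF
#' whose label lies within `window` bp. Taxonomy is rolled up over the
#' active hit set: the exact TRF hits when any exist, otherwise the windowed
#' oTRF hits - the fallback used when binning has shifted fragment sizes off
#' their in silico values.
#'
#' @param ex_table An `otrf_table` of experimental oTRFs.
#' @param is_fragments A `trflp_fragments` profile (already range-filtered
#'   with the same [binning_config()] as the experimental table).
#' @param is_otrfs An `otrf_clusters` result for the same fragments; computed
#'   from `is_fragments` with `config` when omitted.
#' @param window Match half-window in bp (default 2).
#' @param config [binning_config()] used when `is_otrfs` must be computed.
#' @param count_na Passed to [rollup_taxa_counts()].
#' @return A data.frame of class `comparison_table`, one row per
#'   experimental label, with hit counts, distinct phylum/genus counts over
#'   the active set, a `no_prediction` flag and a `top_taxa` summary;
#'   attribute `hits` keeps the per-label active hit sets.
#' @export
match_ex_to_is <- function(ex_table, is_fragments, is_otrfs = NULL,
                           window = 2L, config = binning_config(),
                           count_na = FALSE) {
  ex_enz <- attr(ex_table, "enzyme")
  is_enz <- attr(is_fragments, "enzyme")
  if (!is.null(ex_enz) && !is.null(is_enz) && !identical(ex_enz, is_enz)) {
    stop("enzyme mismatch: experimental table is ", ex_enz,
         ", in silico profile is ", is_enz)
  }
  if (is.null(is_otrfs)) {
    is_otrfs <- cluster_moving_average(
      data.frame(size = as.integer(is_fragments$length), weight = 1), config)
  }
  sizes <- as.integer(is_fragments$length)
  labels <- sort(as.integer(rownames(ex_table)))
  active_sets <- vector("list", length(labels))
  rows <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    e <- labels[k]
    exact <- is_fragments[sizes == e, , drop = FALSE]
    near <- is_otrfs[abs(is_otrfs$label - e) <= window, , drop = FALSE]
    member_sizes <- sort(unique(unlist(near$members)))
    windowed <- is_fragments[sizes %in% member_sizes, , drop = FALSE]
    active <- if (nrow(exact) > 0L) exact else windowed
    counts <- rollup_taxa_counts(active, count_na = count_na)
    top <- counts$tallies$genus
    rows[[k]] <- data.frame(
      ex_otrf_bp = e,
      n_is_trf_fragments = nrow(exact),
      n_is_trf_sizes = length(unique(exact$length)),
      n_is_otrf = nrow(windowed),
      n_phyla = counts$n_phyla,
      n_genera = counts$n_genera,
      no_prediction = nrow(exact) == 0L && nrow(windowed) == 0L,
      top_taxa = paste(utils::head(names(top), 3L), collapse = ","),
      stringsAsFactors = FALSE
    )
    active_sets[[k]] <- active
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(active_sets) <- as.character(labels)
  attr(out, "hits") <- active_sets
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Write a comparison table as TSV
#'
#' Fixed column order: `ex_otrf_bp`, `n_is_trf_fragments`, `n_is_trf_sizes`,
#' `n_is_otrf`, `n_phyla`, `n_genera`, `no_prediction`, `top_taxa`.
#'
#' @param table A `comparison_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_comparison <- function(table, path) {
  cols <- c("ex_otrf_bp", "n_is_trf_fragments", "n_is_trf_sizes",
            "n_is_otrf", "n_phyla", "n_genera", "no_prediction", "top_taxa")
  df <- as.data.frame(table)[, cols, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
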