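#' Noise filter configuration
#'
#' Iterative proportion-threshold removal of background peaks: at each pass
#' every peak contributing less than `min_proportion` of the current total
#' fluorescence of its sample is dropped, and the threshold is re-evaluated
#' on the survivors until no peak is removed (or `max_iterations` passes).
#'
#' @param min_proportion Fraction of per-sample total fluorescence below
#'   which a peak is noise (default 0.005, i.e. 0.5%).
#' @param max_iterations Safety cap on the number of passes (default 100).
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(min_proportion = 0.005, max_iterations = 100L) {
  if (min_proportion < 0 || min_proportion >= 1) {
    stop("min_proportion must lie in [0, 1)")
  }
  structure(list(min_proportion = min_proportion,
                 max_iterations = as.integer(max_iterations)),
            class = "noise_config")
}

#' Read a fragment-analysis peak table exported as CSV
#'
#' Ingests the per-peak CSV exported by instrument software (one row per
#' called peak; header row required). Column names are configurable; rows
#' whose size field is empty or non-numeric are skipped with a logged count.
#'
#' @param path CSV path.
#' @param columns Named list mapping the roles `size`, `height` (mandatory)
#'   and `dye`, `sample` (optional) to header names.
#' @return A `data.frame` of class `peak_table` with columns `sample`,
#'   `size`, `height`, `dye`; attribute `skipped` counts dropped rows.
#' @export
read_peak_csv <- function(path,
                          columns = list(size = "Size", height = "Height",
                                         dye = "Dye", sample = "Sample File Name")) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  for (role in c("size", "height")) {
    if (!columns[[role]] %in% names(raw)) {
      stop("peak CSV lacks mandatory column '", columns[[role]], "'")
    }
  }
  size <- suppressWarnings(as.numeric(raw[[columns$size]]))
  height <- suppressWarnings(as.numeric(raw[[columns$height]]))
  skip <- is.na(size) | size <= 0 | is.na(height)
  neg <- which(!is.na(height) & height < 0)
  if (length(neg) > 0L) {
    stop("negative peak height in row ", neg[1L], " of ", path)
  }
  if (all(skip)) stop("no parsable peak rows in ", path)
  if (any(skip)) {
    message(sum(skip), " row(s) without a numeric size skipped in ",
            basename(path))
  }
  dye <- if (!is.null(columns$dye) && columns$dye %in% names(raw)) {
    raw[[columns$dye]]
  } else {
    rep(NA_character_, nrow(raw))
  }
  sample <- if (!is.null(columns$sample) && columns$sample %in% names(raw)) {
    raw[[columns$sample]]
  } else {
    rep(basename(path), nrow(raw))
  }
  out <- data.frame(sample = sample[!skip], size = size[!skip],
                    height = height[!skip], dye = dye[!skip],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- sum(skip)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Keep peaks of one dye channel
#'
#' Retains peaks whose dye tag starts with the requested channel letter
#' (e.g. `"B"` for the blue FAM channel, discarding the orange size
#' standard). A table without dye information passes through unchanged when
#' no channel is requested.
#'
#' @param table A `peak_table`.
#' @param dye Channel prefix, or `NULL` for no filtering.
#' @return The filtered `peak_table`.
#' @export
select_channel <- function(table, dye = "B") {
  if (is.null(dye)) return(table)
  if (all(is.na(table$dye))) {
    stop("peak table has no dye column; cannot select channel '", dye, "'")
  }
  keep <- !is.na(table$dye) & startsWith(table$dye, dye)
  if (!any(keep)) {
    stop("channel '", dye, "' yields zero peaks in every sample")
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative background-noise removal
#'
#' Per sample, repeatedly removes every peak whose height is less than
#' `min_proportion` of the current total fluorescence, recomputing the total
#' after each pass, until stable. Deterministic and idempotent; a larger
#' threshold never retains a peak a smaller one removed.
#'
#' @param peaks A `peak_table` (one or more samples).
#' @param config A [noise_config()].
#' @return A list with `peaks` (kept rows) and `removed` (count).
#' @export
noise_filter <- function(peaks, config = noise_config()) {
  if (nrow(peaks) == 0L) stop("no peaks to filter")
  keep_idx <- unlist(lapply(split(seq_len(nrow(peaks)), peaks$sample),
                            function(ix) {
    h <- peaks$height[ix]
    alive <- rep(TRUE, length(ix))
    for (iter in seq_len(config$max_iterations)) {
      tot <- sum(h[alive])
      drop <- alive & (h / tot < config$min_proportion)
      if (!any(drop)) break
      alive <- alive & !drop
      if (!any(alive)) {
        stop("noise filter removed every peak of sample '",
             peaks$sample[ix[1L]], "'; reduce min_proportion")
      }
    }
    ix[alive]
  }), use.names = FALSE)
  out <- peaks[sort(keep_idx), , drop = FALSE]
  rownames(out) <- NULL
  list(peaks = out, removed = nrow(peaks) - nrow(out))
}

#' Per-sample relative abundance of integer-sized peaks
#'
#' Rounds peak sizes half-away-from-zero to integer bp, sums fluorescence of
#' equal rounded sizes, and scales each sample to 100%.
#'
#' @param peaks A noise-filtered `peak_table`.
#' @return A data.frame with columns `sample`, `size` (integer bp) and
#'   `weight` (relative abundance %, each sample summing to 100), directly
#'   consumable by [bin_profile()].
#' @export
relative_abundance <- function(peaks) {
  if (nrow(peaks) == 0L) stop("no peaks")
  size_int <- as.integer(sign(peaks$size) * floor(abs(peaks$size) + 0.5))
  agg <- stats::aggregate(height ~ sample + size,
                          data = data.frame(sample = peaks$sample,
                                            size = size_int,
                                            height = peaks$height),
                          FUN = sum)
  tot <- tapply(agg$height, agg$sample, sum)
  if (any(tot == 0)) stop("zero total height in sample '",
                          names(tot)[tot == 0][1L], "'")
  agg$weight <- 100 * agg$height / as.numeric(tot[agg$sample])
  out <- agg[order(agg$sample, agg$size), c("sample", "size", "weight")]
  rownames(out) <- NULL
  out
}
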