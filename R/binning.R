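#' Binning configuration
#'
#' Parameters of the size filter and the moving-average oTRF clustering.
#' Defaults follow common T-RFLP practice for ~634-bp amplicons: fragments
#' outside 50-640 bp are discarded and fragments within +/- 2 bp of each
#' other are binned into one operational TRF (oTRF) unit.
#'
#' @param window Clustering half-window `w` in bp (default 2).
#' @param min_bp,max_bp Inclusive analysis size range in bp (defaults 50,
#'   640).
#' @param rounding How the abundance-weighted mean member size becomes the
#'   integer bin label: `"nearest-even"` (default; snaps to the even-bp
#'   lattice on which capillary-sized oTRFs are conventionally reported) or
#'   `"nearest-integer"`. Exact ties round down.
#' @return A list of class `binning_config`.
#' @export
binning_config <- function(window = 2L, min_bp = 50L, max_bp = 640L,
                           rounding = c("nearest-even", "nearest-integer")) {
  rounding <- match.arg(rounding)
  window <- as.integer(window)
  min_bp <- as.integer(min_bp)
  max_bp <- as.integer(max_bp)
  if (is.na(window) || window < 1L) stop("window must be >= 1 bp")
  if (min_bp >= max_bp) stop("min_bp must be smaller than max_bp")
  structure(list(window = window, min_bp = min_bp, max_bp = max_bp,
                 rounding = rounding),
            class = "binning_config")
}

round_label <- function(x, rounding) {
  if (rounding == "nearest-even") {
    # nearest even integer, exact ties (odd integers) to the lower even
    as.integer(2L * ceiling(x / 2 - 0.5))
  } else {
    as.integer(ceiling(x - 0.5))
  }
}

#' Restrict a TRF multiset to the analysis size range
#'
#' Keeps entries with `min_bp <= size <= max_bp` (both ends inclusive);
#' weights and provenance columns are untouched.
#'
#' @param trfs A data.frame with at least a `size` column (bp).
#' @param config A [binning_config()].
#' @return The filtered data.frame.
#' @export
filter_size_range <- function(trfs, config = binning_config()) {
  keep <- trfs$size >= config$min_bp & trfs$size <= config$max_bp
  out <- trfs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# recursive largest-gap splitting: any run of sizes whose span exceeds 2w is
# cut at its largest internal gap (leftmost on ties) until all spans fit
split_span <- function(sizes, w) {
  if (length(sizes) < 2L || sizes[length(sizes)] - sizes[1L] <= 2L * w) {
    return(list(sizes))
  }
  gaps <- diff(sizes)
  cut <- which.max(gaps)  # leftmost maximal gap
  c(split_span(sizes[seq_len(cut)], w),
    split_span(sizes[(cut + 1L):length(sizes)], w))
}

#' Cluster terminal fragment sizes into oTRF units
#'
#' The moving-average binning used for both experimental and in silico TRF
#' profiles:
#'
#' 1. sort the unique integer sizes;
#' 2. chain successive sizes whose gap is at most `window` into one cluster;
#' 3. recursively split any cluster whose span exceeds `2 * window` at its
#'    largest internal gap (leftmost on ties);
#' 4. label each cluster with the abundance-weighted mean member size,
#'    rounded per `config$rounding`;
#' 5. merge clusters whose labels collide.
#'
#' @param trfs A data.frame with columns `size` (integer bp) and `weight`
#'   (fragment counts for in silico profiles; fluorescence or relative
#'   abundance for experimental profiles). Assumed already range-filtered.
#' @param config A [binning_config()].
#' @return A data.frame of class `otrf_clusters`, sorted by `label`, with
#'   columns `label`, `weight` (total member weight), `n_sizes`, `size_min`,
#'   `size_max` and a list column `members` of member sizes.
#' @examples
#' cluster_moving_average(data.frame(size = c(70, 71, 72, 73),
#'                                   weight = c(2, 2, 1, 4)))
#' @export
cluster_moving_average <- function(trfs, config = binning_config()) {
  if (!inherits(config, "binning_config")) stop("config must be a binning_config")
  if (nrow(trfs) == 0L) {
    out <- data.frame(label = integer(0), weight = numeric(0),
                      n_sizes = integer(0), size_min = integer(0),
                      size_max = integer(0))
    out$members <- list()
    class(out) <- c("otrf_clusters", "data.frame")
    return(out)
  }
  if (any(trfs$weight <= 0)) stop("weights must be positive")
  agg <- stats::aggregate(weight ~ size, data = trfs, FUN = sum)
  agg <- agg[order(agg$size), , drop = FALSE]
  sizes <- as.integer(agg$size)
  weights <- agg$weight
  w <- config$window

  chains <- split(sizes, cumsum(c(1L, diff(sizes) > w)))
  clusters <- unlist(lapply(chains, split_span, w = w), recursive = FALSE)

  rows <- lapply(clusters, function(cs) {
    wt <- weights[match(cs, sizes)]
    lab <- round_label(stats::weighted.mean(cs, wt), config$rounding)
    data.frame(label = lab, weight = sum(wt), n_sizes = length(cs),
               size_min = cs[1L], size_max = cs[length(cs)],
               members = I(list(cs)))
  })
  out <- do.call(rbind, rows)

  # merge label collisions
  if (anyDuplicated(out$label)) {
    merged <- lapply(split(seq_len(nrow(out)), out$label), function(ix) {
      cs <- sort(unlist(out$members[ix]))
      data.frame(label = out$label[ix[1L]], weight = sum(out$weight[ix]),
                 n_sizes = length(cs), size_min = cs[1L],
                 size_max = cs[length(cs)], members = I(list(cs)))
    })
    out <- do.call(rbind, merged)
  }
  out <- out[order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("otrf_clusters", "data.frame")
  out
}

# normalise the heterogeneous inputs of bin_profile to a long data.frame
# with columns sample, size, weight
as_trf_long <- function(x) {
  if (inherits(x, "trflp_fragments")) {
    src <- attr(x, "enzyme")
    data.frame(sample = if (is.null(src)) "IS" else paste0("IS_", src),
               size = as.integer(x$length), weight = 1,
               stringsAsFactors = FALSE)
  } else {
    x <- as.data.frame(x)
    if (!all(c("size", "weight") %in% names(x))) {
      stop("expected columns 'size' and 'weight'")
    }
    if (!"sample" %in% names(x)) x$sample <- "sample1"
    x[, c("sample", "size", "weight")]
  }
}

#' Bin a fragment profile or peak table into an oTRF abundance table
#'
#' Applies the size filter and the moving-average clustering and returns a
#' label x sample abundance matrix. Bin boundaries are computed on the
#' multiset pooled over all samples, so a given oTRF label denotes the same
#' fragment population in every column; per-sample weights are then
#' aggregated within each bin.
#'
#' @param x A `trflp_fragments` object (in silico profile; each fragment
#'   contributes weight 1) or a data.frame with columns `sample`, `size`,
#'   `weight` (e.g. relative abundances from [relative_abundance()]).
#' @param config A [binning_config()].
#' @param normalise If `TRUE`, scale every sample column to sum to 100
#'   (relative abundance percent).
#' @return A numeric matrix of class `otrf_table` (rownames = oTRF labels,
#'   colnames = samples) with attributes `clusters` (the [cluster_moving_average()]
#'   result), `config` and `enzyme`.
#' @export
bin_profile <- function(x, config = binning_config(), normalise = FALSE) {
  long <- as_trf_long(x)
  enz <- attr(x, "enzyme")
  samples <- unique(long$sample)
  long <- filter_size_range(long, config)
  gone <- setdiff(samples, unique(long$sample))
  for (s in gone) {
    warning("sample '", s, "' has no peaks inside the size range ",
            "[", config$min_bp, ", ", config$max_bp, "]")
  }
  if (nrow(long) == 0L) {
    mat <- matrix(0, nrow = 0, ncol = length(samples),
                  dimnames = list(NULL, samples))
    return(structure(mat, clusters = cluster_moving_average(long, config),
                     config = config, enzyme = enz, class = "otrf_table"))
  }
  clusters <- cluster_moving_average(
    stats::aggregate(weight ~ size, data = long, FUN = sum), config)
  size2lab <- integer(0)
  for (i in seq_len(nrow(clusters))) {
    size2lab[as.character(clusters$members[[i]])] <- clusters$label[i]
  }
  long$label <- size2lab[as.character(long$size)]
  mat <- matrix(0, nrow = nrow(clusters), ncol = length(samples),
                dimnames = list(as.character(clusters$label), samples))
  agg <- stats::aggregate(weight ~ label + sample, data = long, FUN = sum)
  mat[cbind(as.character(agg$label), agg$sample)] <- agg$weight
  if (normalise) {
    tot <- colSums(mat)
    nz <- tot > 0
    mat[, nz] <- sweep(mat[, nz, drop = FALSE], 2, tot[nz], "/") * 100
  }
  structure(mat, clusters = clusters, config = config, enzyme = enz,
            class = "otrf_table")
}

#' Write an oTRF table as TSV
#'
#' The main table has `otrf_bp` as its first column and one column per
#' sample. An optional sidecar TSV maps each oTRF label to its member
#' fragment sizes.
#'
#' @param table An `otrf_table`.
#' @param path Output TSV path.
#' @param sidecar_path Optional path for the label-to-members map.
#' @return `path`, invisibly.
#' @export
write_otrf_table <- function(table, path, sidecar_path = NULL) {
  df <- data.frame(otrf_bp = as.integer(rownames(table)),
                   as.data.frame(unclass(table)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sidecar_path)) {
    cl <- attr(table, "clusters")
    side <- data.frame(
      otrf_bp = cl$label,
      member_sizes = vapply(cl$members, paste, character(1), collapse = ","),
      weight = cl$weight
    )
    utils::write.table(side, sidecar_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read an oTRF table written by [write_otrf_table()]
#'
#' @param path TSV path.
#' @return An `otrf_table` matrix.
#' @export
read_otrf_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df$otrf_bp)
  structure(mat, class = "otrf_table")
}
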