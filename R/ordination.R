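#' Distance matrix between oTRF profiles
#'
#' Samples are the columns of the abundance table. Euclidean distances come
#' from [stats::dist()]; Bray-Curtis dissimilarity
#' `1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))` from [vegan::vegdist()]. A
#' pair of all-zero samples has an undefined Bray-Curtis value and is
#' reported as 0 with a warning.
#'
#' @param table An `otrf_table` (or any nonnegative matrix, taxa x samples).
#' @param metric `"euclidean"` or `"bray"`.
#' @return A `dist` object with attribute `metric`.
#' @export
profile_distance <- function(table, metric = c("euclidean", "bray")) {
  metric <- match.arg(metric)
  x <- t(unclass(table))
  if (nrow(x) < 2L) stop("need at least two samples")
  if (any(x < 0)) stop("negative abundances")
  d <- if (metric == "euclidean") {
    stats::dist(x)
  } else {
    dd <- vegan::vegdist(x, method = "bray")
    if (anyNA(dd)) {
      warning("all-zero sample pair: Bray-Curtis dissimilarity set to 0")
      dd[is.na(dd)] <- 0
    }
    dd
  }
  attr(d, "metric") <- metric
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Wraps [stats::cmdscale()]: Gower double-centering of `-0.5 * D^2`,
#' eigendecomposition, coordinates scaled by the square root of the positive
#' eigenvalues. Negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis) are dropped and their total magnitude
#' reported via `message()`. Axis signs are fixed so the largest-magnitude
#' coordinate on each axis is positive, making outputs reproducible.
#'
#' @param d A `dist` object (e.g. from [profile_distance()]).
#' @param n_axes Number of axes to return (truncated with a warning if it
#'   exceeds the number of positive eigenvalues).
#' @param covariates Optional data.frame of per-sample covariates (e.g. VFA
#'   g/L, CH4 %, CO2 %) passed through for downstream overlay; must have one
#'   row per sample in the order of `d`'s labels.
#' @return A list of class `trflp_pcoa` with `coordinates` (sample x axis),
#'   `eigenvalues` (positive only), `proportion` (variance share per axis)
#'   and `covariates`.
#' @export
pcoa <- function(d, n_axes = 2L, covariates = NULL) {
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * sqrt(.Machine$double.eps)
  npos <- sum(eig > tol)
  if (npos == 0L) stop("no positive eigenvalues: degenerate distance matrix")
  neg <- sum(abs(eig[eig < -tol]))
  if (neg > 0) {
    message(sprintf("dropped negative eigenvalues (total magnitude %.4g)",
                    neg))
  }
  if (n_axes > npos) {
    warning("only ", npos, " positive eigenvalue(s); axes truncated")
    n_axes <- npos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) {
      coords[, j] <- -coords[, j]
    }
  }
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  if (!is.null(covariates) && nrow(covariates) != n) {
    stop("covariates must have one row per sample")
  }
  structure(list(coordinates = coords,
                 eigenvalues = eig[seq_len(npos)],
                 proportion = eig[seq_len(npos)] / sum(eig[seq_len(npos)]),
                 covariates = covariates),
            class = "trflp_pcoa")
}

#' @export
print.trflp_pcoa <- function(x, ...) {
  cat(sprintf("<PCoA: %d samples, %d positive axes; axis 1-2 variance %.1f%% / %.1f%%>\n",
              nrow(x$coordinates), length(x$eigenvalues),
              100 * x$proportion[1],
              if (length(x$proportion) > 1) 100 * x$proportion[2] else 0))
  invisible(x)
}

#' Write PCoA coordinates and eigenvalues as TSV
#'
#' @param fit A `trflp_pcoa` object.
#' @param coord_path TSV path for sample coordinates (covariates appended as
#'   extra columns when present).
#' @param eig_path Optional TSV path for eigenvalues and variance shares.
#' @return `coord_path`, invisibly.
#' @export
write_ordination <- function(fit, coord_path, eig_path = NULL) {
  df <- data.frame(sample = rownames(fit$coordinates), fit$coordinates,
                   row.names = NULL, check.names = FALSE)
  if (!is.null(fit$covariates)) df <- cbind(df, fit$covariates)
  utils::write.table(df, coord_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(eig_path)) {
    utils::write.table(
      data.frame(axis = seq_along(fit$eigenvalues),
                 eigenvalue = fit$eigenvalues,
                 proportion = fit$proportion),
      eig_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(coord_path)
}
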