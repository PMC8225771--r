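#' Define a restriction enzyme
#'
#' A recognition pattern over the IUPAC alphabet plus the top-strand cut
#' offset, measured in bases from the 5' end of the recognition site. The
#' labelled terminal fragment of a digest ends at the first cut, so its
#' length is the 0-based site start plus `cut_offset`.
#'
#' @param name Enzyme name, e.g. `"AluI"`.
#' @param site Recognition pattern (IUPAC codes allowed, e.g. `"TCNNGA"`).
#' @param cut_offset Integer in `[0, nchar(site)]`: top-strand cut position.
#' @return An object of class `trflp_enzyme`.
#' @examples
#' enzyme("AluI", "AGCT", 2)
#' @export
enzyme <- function(name, site, cut_offset) {
  site <- iupac_normalize(site, sprintf("recognition site of %s", name))
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site)) {
    stop(sprintf("cut_offset of %s must lie in [0, %d]", name, nchar(site)))
  }
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "trflp_enzyme")
}

#' @export
print.trflp_enzyme <- function(x, ...) {
  cat(sprintf("<enzyme %s: %s, cut at +%d>\n", x$name, x$site, x$cut_offset))
  invisible(x)
}

#' Define a PCR primer
#'
#' @param name Primer name.
#' @param seq Primer sequence, 5' to 3', IUPAC codes allowed.
#' @param label Optional fluorophore tag on the 5' terminus (e.g. `"FAM"`);
#'   the labelled primer defines which terminal fragment the instrument sees.
#' @return An object of class `trflp_primer`.
#' @export
primer <- function(name, seq, label = NULL) {
  seq <- iupac_normalize(seq, sprintf("primer %s", name))
  structure(list(name = name, seq = seq, label = label),
            class = "trflp_primer")
}

#' @export
print.trflp_primer <- function(x, ...) {
  cat(sprintf("<primer %s: 5'-%s%s-3'>\n",
              x$name, if (is.null(x$label)) "" else paste0("[", x$label, "]"),
              x$seq))
  invisible(x)
}

#' Built-in enzyme definitions
#'
#' Reads the editable YAML shipped with the package
#' (`system.file("extdata", "enzymes.yaml", package = "trflptools")`), which
#' carries REBASE-standard definitions for AluI (AG^CT) and Hpy188III
#' (TC^NNGA). Point `path` at your own file to add enzymes.
#'
#' @param path Optional path to an alternative enzyme YAML.
#' @return Named list of `trflp_enzyme` objects.
#' @export
default_enzymes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "enzymes.yaml", package = "trflptools")
  }
  cfg <- yaml::read_yaml(path)
  out <- lapply(cfg$enzymes, function(e) enzyme(e$name, e$site, e$cut_offset))
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Built-in primer pair
#'
#' The degenerate, tagged FTHFS primer pair used for in silico amplicon
#' construction (forward FAM-labelled). Shipped as editable YAML alongside
#' the enzymes.
#'
#' @param path Optional path to an alternative primer YAML.
#' @return List with elements `fwd` and `rev` (`trflp_primer`).
#' @export
default_primers <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "primers.yaml", package = "trflptools")
  }
  cfg <- yaml::read_yaml(path)
  list(
    fwd = primer(cfg$primers$fwd$name, cfg$primers$fwd$seq,
                 cfg$primers$fwd$label),
    rev = primer(cfg$primers$rev$name, cfg$primers$rev$seq,
                 cfg$primers$rev$label)
  )
}
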