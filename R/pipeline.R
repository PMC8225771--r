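#' Read a pipeline run configuration from YAML
#'
#' The config gathers every knob of a full analysis: reference FASTA +
#' taxonomy TSV, peak CSVs and dye channel, enzyme and primer selections,
#' binning and noise parameters, ordination metric/axes, seed and output
#' directory. Referenced input files must exist.
#'
#' @param path YAML path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' Build a run configuration from a list
#'
#' @param cfg Named list with the same structure as the YAML accepted by
#'   [read_run_config()].
#' @return A list of class `run_config`.
#' @export
as_run_config <- function(cfg) {
  for (p in c(cfg$reference$fasta, cfg$reference$taxonomy,
              unlist(cfg$peaks$csv))) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  if (is.null(cfg$enzyme)) cfg$enzyme <- "AluI"
  if (is.null(cfg$semantics)) cfg$semantics <- "guaranteed"
  b <- cfg$binning
  cfg$binning_config <- binning_config(
    window = if (is.null(b$window)) 2L else b$window,
    min_bp = if (is.null(b$min_bp)) 50L else b$min_bp,
    max_bp = if (is.null(b$max_bp)) 640L else b$max_bp,
    rounding = if (is.null(b$rounding)) "nearest-even" else b$rounding
  )
  nz <- cfg$noise
  cfg$noise_config <- noise_config(
    min_proportion = if (is.null(nz$min_proportion)) 0.005 else nz$min_proportion,
    max_iterations = if (is.null(nz$max_iterations)) 100L else nz$max_iterations
  )
  if (is.null(cfg$ordination$metric)) cfg$ordination$metric <- "bray"
  if (is.null(cfg$ordination$axes)) cfg$ordination$axes <- 2L
  if (is.null(cfg$peaks$dye)) cfg$peaks$dye <- "B"
  if (is.null(cfg$seed)) cfg$seed <- 1L
  class(cfg) <- "run_config"
  cfg
}

resolve_enzyme <- function(x) {
  if (inherits(x, "trflp_enzyme")) return(x)
  if (is.list(x)) return(enzyme(x$name, x$site, x$cut_offset))
  enzymes <- default_enzymes()
  if (!x %in% names(enzymes)) {
    stop("unknown enzyme '", x, "'; built-ins: ",
         paste(names(enzymes), collapse = ", "))
  }
  enzymes[[x]]
}

resolve_primers <- function(cfg) {
  if (is.null(cfg$primers)) return(default_primers())
  list(fwd = primer(cfg$primers$fwd$name, cfg$primers$fwd$seq,
                    cfg$primers$fwd$label),
       rev = primer(cfg$primers$rev$name, cfg$primers$rev$seq,
                    cfg$primers$rev$label))
}

#' Run the full T-RFLP analysis pipeline
#'
#' Executes digest -> bin (in silico), peaks -> channel -> noise filter ->
#' relative abundance -> bin (experimental), experimental/in-silico matching
#' and ordination, writing seven TSV artifacts plus a JSON manifest (file
#' list with content hashes, config echo, package version) into the output
#' directory. A failing stage removes the partial outputs and re-raises the
#' error prefixed with the stage name.
#'
#' @param config A `run_config` (from [read_run_config()] or
#'   [as_run_config()]).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  out_dir <- config$output
  if (is.null(out_dir)) stop("config must name an output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(p) { written <<- c(written, p); p }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  enz <- stage("setup", resolve_enzyme(config$enzyme))
  primers <- stage("setup", resolve_primers(config))
  bc <- config$binning_config

  records <- stage("read_reference", read_reference(
    config$reference$fasta, config$reference$taxonomy,
    permissive = isTRUE(config$reference$permissive)))

  is_frag <- stage("digest", {
    digest_dataset(records, primers$fwd, primers$rev, enz,
                   semantics = config$semantics)
  })
  stage("digest", {
    df <- as.data.frame(is_frag)
    df$enzyme <- attr(is_frag, "enzyme")
    utils::write.table(df, note(file.path(out_dir, "is_fragments.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  is_table <- stage("bin_is", bin_profile(is_frag, bc))
  stage("bin_is", write_otrf_table(
    is_table, note(file.path(out_dir, "is_otrfs.tsv")),
    note(file.path(out_dir, "otrf_members.tsv"))))

  ex_table <- stage("peaks", {
    pk <- do.call(rbind, lapply(unlist(config$peaks$csv), read_peak_csv))
    class(pk) <- c("peak_table", "data.frame")
    pk <- select_channel(pk, config$peaks$dye)
    pk <- noise_filter(pk, config$noise_config)$peaks
    ra <- relative_abundance(pk)
    tab <- bin_profile(ra, bc, normalise = TRUE)
    attr(tab, "enzyme") <- enz$name
    tab
  })
  stage("peaks", write_otrf_table(
    ex_table, note(file.path(out_dir, "ex_otrfs.tsv"))))

  stage("compare", {
    is_filtered <- is_frag[is_frag$length >= bc$min_bp &
                             is_frag$length <= bc$max_bp, , drop = FALSE]
    attr(is_filtered, "enzyme") <- attr(is_frag, "enzyme")
    class(is_filtered) <- class(is_frag)
    cmp <- match_ex_to_is(ex_table, is_filtered,
                          is_otrfs = attr(is_table, "clusters"),
                          window = bc$window, config = bc)
    export_comparison(cmp, note(file.path(out_dir, "comparison.tsv")))
  })

  stage("ordinate", {
    d <- profile_distance(ex_table, config$ordination$metric)
    cov <- NULL
    if (!is.null(config$covariates) && file.exists(config$covariates)) {
      cv <- utils::read.delim(config$covariates)
      cov <- cv[match(colnames(ex_table), cv$sample), , drop = FALSE]
    }
    fit <- pcoa(d, n_axes = config$ordination$axes, covariates = cov)
    write_ordination(fit, note(file.path(out_dir, "pcoa_coordinates.tsv")),
                     note(file.path(out_dir, "pcoa_eigenvalues.tsv")))
  })

  manifest <- list(
    tool = "trflptools",
    version = as.character(utils::packageVersion("trflptools")),
    config = unclass(config)[setdiff(names(config),
                                     c("binning_config", "noise_config"))],
    artifacts = lapply(written, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
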