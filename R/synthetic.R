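#' Simulation configuration
#'
#' Parameters of the synthetic study: a reference database with planted
#' terminal fragments, a two-reactor community time series (stable control
#' versus disturbance followed by recovery, with reactor covariates), and
#' electropherograms with size-calling jitter and sub-threshold noise peaks.
#' One seed fixes every random draw end to end.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_taxa Number of reference taxa (default 20).
#' @param n_timepoints Time points per reactor (default 12).
#' @param insert_len_range Insert length range in bp (default 570-600,
#'   mimicking ~588-bp marker-gene amplicon inserts).
#' @param gc GC fraction of random insert sequence (default 0.5).
#' @param enzyme A [enzyme()] the fragments are planted for (default AluI).
#' @param trf_range Range the planted terminal fragment sizes are drawn from
#'   (default 60-600 bp; even values, so bin labels on the even-bp lattice
#'   coincide with the true sizes).
#' @param trf_min_gap Minimum spacing between planted fragment sizes
#'   (default 8 bp, keeping bins of distinct taxa well separated).
#' @param disturbance_window Indices `(start, end)` of the overloading
#'   disturbance in the disturbed reactor (default timepoints 5-9).
#' @param n_disturbed Number of taxa responding to the disturbance
#'   (default 5).
#' @param max_fold Peak fold change of disturbed taxa at the window midpoint
#'   (default 6; 1 = no disturbance).
#' @param sigma Size-calling jitter (standard deviation, bp; default 0.4 -
#'   the single-base uncertainty that motivates the +/- 2 bp binning window).
#' @param noise_rate Poisson mean of background noise peaks per sample
#'   (default 10).
#' @param amp_sdlog Log-sd of the per-peak amplification factor
#'   (default 0.1, a modest PCR/injection bias calibrated so that profile
#'   distortion stays well inside the pipeline recovery tolerance).
#' @param min_proportion Noise-filter threshold the simulator keeps its
#'   noise peaks under (default 0.005).
#' @param vfa_peak Peak total VFA (g/L) in the disturbed reactor
#'   (default 18).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_taxa = 20L, n_timepoints = 12L,
                       insert_len_range = c(570L, 600L), gc = 0.5,
                       enzyme = default_enzymes()[["AluI"]],
                       trf_range = c(60L, 600L), trf_min_gap = 8L,
                       disturbance_window = c(5L, 9L), n_disturbed = 5L,
                       max_fold = 6, sigma = 0.4, noise_rate = 10,
                       amp_sdlog = 0.1, min_proportion = 0.005,
                       vfa_peak = 18) {
  stopifnot(n_taxa >= 1L, n_timepoints >= 1L,
            disturbance_window[1] <= disturbance_window[2],
            sigma >= 0, max_fold > 0)
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 n_timepoints = as.integer(n_timepoints),
                 insert_len_range = as.integer(insert_len_range), gc = gc,
                 enzyme = enzyme, trf_range = as.integer(trf_range),
                 trf_min_gap = as.integer(trf_min_gap),
                 disturbance_window = as.integer(disturbance_window),
                 n_disturbed = as.integer(min(n_disturbed, n_taxa)),
                 max_fold = max_fold, sigma = sigma,
                 noise_rate = noise_rate, amp_sdlog = amp_sdlog,
                 min_proportion = min_proportion, vfa_peak = vfa_peak),
            class = "sim_config")
}

# small synthetic taxonomy tree; deterministic given the RNG state
synth_lineages <- function(n_taxa) {
  phyla <- paste0("Synthophyta_", LETTERS[1:4])
  n_genera <- max(1L, ceiling(n_taxa * 0.7))
  genus_phylum <- sample(phyla, n_genera, replace = TRUE)
  genera <- sprintf("Synthogenus_%02d", seq_len(n_genera))
  gi <- sample(n_genera, n_taxa, replace = TRUE)
  data.frame(
    domain = "Bacteria",
    phylum = genus_phylum[gi],
    class = paste0(genus_phylum[gi], "_classis"),
    order = paste0(genus_phylum[gi], "_ales"),
    family = paste0(genera[gi], "_aceae"),
    genus = genera[gi],
    species = sprintf("%s sp. %d", genera[gi], seq_len(n_taxa)),
    stringsAsFactors = FALSE
  )
}

# concrete realization of a (possibly degenerate) recognition site
concrete_site <- function(site) {
  sets <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
            W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
            V = "ACG", N = "ACGT")
  paste(vapply(strsplit(site, "")[[1L]], function(ch) {
    opts <- strsplit(sets[[ch]], "")[[1L]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Generate a synthetic reference database with planted terminal fragments
#'
#' Every taxon receives a random insert carrying exactly one recognition site
#' placed so that the tagged amplicon digests to an assigned terminal
#' fragment size; inserts with an accidental upstream site (under guaranteed
#' semantics) are rejection-sampled away. Planted sizes are pairwise at least
#' `trf_min_gap` apart and inside the analysis range.
#'
#' @param config A [sim_config()].
#' @param fwd,rev [primer()] objects (default: the built-in pair).
#' @return A list with `records` (a `trflp_refset`), `taxonomy` (id/lineage
#'   data.frame) and `truth` (id, planted `trf`, lineage ranks).
#' @export
gen_reference_db <- function(config = sim_config(),
                             fwd = default_primers()$fwd,
                             rev = default_primers()$rev) {
  set.seed(config$seed)
  enz <- config$enzyme
  candidates <- seq(config$trf_range[1], config$trf_range[2], by = 2L)
  shuffled <- sample(candidates)
  planted <- integer(0)
  for (s in shuffled) {
    if (all(abs(s - planted) >= config$trf_min_gap)) planted <- c(planted, s)
    if (length(planted) == config$n_taxa) break
  }
  if (length(planted) < config$n_taxa) {
    stop("cannot place ", config$n_taxa, " fragment sizes at spacing >= ",
         config$trf_min_gap, " inside [", config$trf_range[1], ", ",
         config$trf_range[2], "]")
  }
  lineages <- synth_lineages(config$n_taxa)
  site_len <- nchar(enz$site)
  base_prob <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
                 G = config$gc / 2, T = (1 - config$gc) / 2)

  seqs <- character(config$n_taxa)
  for (i in seq_len(config$n_taxa)) {
    p0 <- planted[i] - enz$cut_offset            # 0-based site start, tagged
    ipos <- p0 - nchar(fwd$seq)                  # 0-based site start, insert
    if (ipos < 0L) stop("planted fragment shorter than the forward primer")
    min_len <- max(config$insert_len_range[1], ipos + site_len)
    if (min_len > config$insert_len_range[2]) {
      stop("planted fragment of ", planted[i],
           " bp does not fit the insert length range")
    }
    ok <- FALSE
    for (try in seq_len(500L)) {
      len <- sample(min_len:config$insert_len_range[2], 1L)
      ins <- paste(sample(names(base_prob), len, replace = TRUE,
                          prob = base_prob), collapse = "")
      substr(ins, ipos + 1L, ipos + site_len) <- concrete_site(enz$site)
      tagged <- tag_with_primers(ins, fwd, rev)
      sites <- find_sites(tagged$seq, enz, "guaranteed")
      if (length(sites) > 0L && sites[1L] == p0) {
        seqs[i] <- ins
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("failed to place a clean site for fragment size ", planted[i],
           " after bounded retries")
    }
  }
  ids <- sprintf("SYN%03d", seq_len(config$n_taxa))
  lineage_str <- apply(lineages, 1L, paste, collapse = ";")
  records <- data.frame(id = ids, seq = seqs, lineage = lineage_str,
                        lineages, stringsAsFactors = FALSE)
  class(records) <- c("trflp_refset", "data.frame")
  truth <- data.frame(id = ids, trf = planted, lineages,
                      stringsAsFactors = FALSE)
  list(records = records,
       taxonomy = data.frame(id = ids, lineage = lineage_str,
                             stringsAsFactors = FALSE),
       truth = truth)
}

# triangular disturbance trajectory: 0 outside the window, 1 at its midpoint
disturbance_profile <- function(t, window) {
  mid <- mean(window)
  hw <- (window[2] - window[1]) / 2 + 1
  pmax(0, 1 - abs(t - mid) / hw)
}

#' Generate a two-reactor community time series with covariates
#'
#' The control reactor holds Dirichlet-style stable proportions with small
#' multiplicative drift; the disturbed reactor applies a log-linear fold
#' change (peaking at `max_fold` mid-window) to the disturbance taxa on top
#' of the control trajectories, then renormalises. Total VFA rises and CH4
#' falls (CO2 rises) along the same trajectory, emulating an overloading
#' disturbance with recovery.
#'
#' @param config A [sim_config()].
#' @return A list with `abundance` (list of timepoint x taxon matrices, rows
#'   summing to 100, for reactors `R1` = disturbed and `R2` = control),
#'   `covariates` (per sample: reactor, timepoint, vfa, ch4, co2),
#'   `disturbed_taxa` (indices) and `samples` (sample id vector).
#' @export
gen_community_series <- function(config = sim_config()) {
  set.seed(config$seed + 1L)
  n <- config$n_taxa
  tt <- seq_len(config$n_timepoints)
  base <- stats::rgamma(n, shape = 1.5)
  base <- base / sum(base)
  control <- t(vapply(tt, function(t) {
    p <- base * exp(stats::rnorm(n, 0, 0.08))
    100 * p / sum(p)
  }, numeric(n)))
  disturbed_taxa <- sample.int(n, config$n_disturbed)
  tri <- disturbance_profile(tt, config$disturbance_window)
  disturbed <- control
  for (k in seq_along(tt)) {
    fold <- rep(1, n)
    fold[disturbed_taxa] <- config$max_fold^tri[k]
    row <- control[k, ] * fold
    disturbed[k, ] <- 100 * row / sum(row)
  }
  taxa <- sprintf("SYN%03d", seq_len(n))
  dimnames(control) <- dimnames(disturbed) <-
    list(sprintf("t%02d", tt), taxa)
  samples <- c(sprintf("R1_t%02d", tt), sprintf("R2_t%02d", tt))
  cov <- data.frame(
    sample = samples,
    reactor = rep(c("R1", "R2"), each = length(tt)),
    timepoint = rep(tt, 2L),
    vfa = c(0.5 + (config$vfa_peak - 0.5) * tri +
              abs(stats::rnorm(length(tt), 0, 0.2)),
            0.5 + abs(stats::rnorm(length(tt), 0, 0.2))),
    ch4 = c(58 - 16 * tri + stats::rnorm(length(tt), 0, 0.8),
            58 + stats::rnorm(length(tt), 0, 0.8)),
    co2 = c(33 + 17 * tri + stats::rnorm(length(tt), 0, 0.8),
            33 + stats::rnorm(length(tt), 0, 0.8)),
    stringsAsFactors = FALSE
  )
  list(abundance = list(R1 = disturbed, R2 = control),
       covariates = cov, disturbed_taxa = disturbed_taxa, samples = samples)
}

#' Simulate electropherogram peak tables from a community time series
#'
#' Per sample, each taxon produces one labelled (blue-channel) peak at size
#' `Normal(planted TRF, sigma)` with height proportional to its abundance
#' times a lognormal amplification factor; a Poisson number of background
#' noise peaks is added at uniform sizes, their heights scaled so their total
#' stays below the noise-filter threshold; an orange-channel size ladder is
#' appended. Written in the peak CSV dialect read by [read_peak_csv()].
#'
#' @param series Output of [gen_community_series()].
#' @param reference Output of [gen_reference_db()] (provides planted sizes).
#' @param config A [sim_config()].
#' @param path Output CSV path.
#' @return The peak data.frame, invisibly; the CSV is written to `path`.
#' @export
simulate_electropherogram <- function(series, reference,
                                      config = sim_config(), path) {
  set.seed(config$seed + 2L)
  trf <- reference$truth$trf
  ladder <- seq(50, 640, by = 50)
  rows <- list()
  for (reactor in names(series$abundance)) {
    ab <- series$abundance[[reactor]]
    for (k in seq_len(nrow(ab))) {
      smp <- sprintf("%s_%s.fsa", reactor, rownames(ab)[k])
      abund <- ab[k, ]
      sizes <- stats::rnorm(length(trf), trf, config$sigma)
      heights <- abund * 100 *
        stats::rlnorm(length(trf), 0, config$amp_sdlog)
      s_total <- sum(heights)
      k_noise <- stats::rpois(1L, config$noise_rate)
      if (k_noise > 0L) {
        u <- stats::runif(k_noise, 0.05, 1)
        noise_budget <- stats::runif(1L, 0.2, 0.8) *
          config$min_proportion * s_total
        noise_h <- u / sum(u) * noise_budget
        noise_s <- stats::runif(k_noise, 50, 640)
      } else {
        noise_h <- noise_s <- numeric(0)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        `Sample File Name` = smp,
        Size = c(sizes, noise_s, ladder),
        Height = c(heights, noise_h, rep(800, length(ladder))),
        Dye = c(rep("B", length(sizes) + length(noise_s)),
                rep("O", length(ladder))),
        check.names = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(out)
}

#' Write a reference set as FASTA
#'
#' Plain two-line records; byte-identical across runs for identical input.
#'
#' @param records A `trflp_refset`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(records, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0(">", records$id, "\n", records$seq), con, sep = "\n")
  invisible(path)
}

#' Write a taxonomy table as TSV
#'
#' @param taxonomy Data.frame with columns `id` and `lineage`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  utils::write.table(taxonomy[, c("id", "lineage")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
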