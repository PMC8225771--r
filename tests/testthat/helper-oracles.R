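# Independent oracles for the site scanner, kept deliberately separate from
# the package implementation: regex-based window scanning over concrete
# sequences, and exhaustive disambiguation for degenerate ones.

ORACLE_SETS <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                 S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                 D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracle_rc <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(s, "")[[1L]]]), collapse = "")
}

# 0-based starts of a degenerate pattern in a CONCRETE sequence, both strands,
# via overlapping lookahead regex
oracle_sites_concrete <- function(seq, site) {
  rex <- function(p) {
    cls <- vapply(strsplit(p, "")[[1L]],
                  function(ch) paste0("[", ORACLE_SETS[[ch]], "]"),
                  character(1))
    paste0("(?=", paste(cls, collapse = ""), ")")
  }
  hits <- function(p) {
    m <- gregexpr(rex(p), seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  }
  h <- hits(site)
  rc <- oracle_rc(site)
  if (rc != site) h <- sort(unique(c(h, hits(rc))))
  h
}

# all concrete realizations of a degenerate sequence
oracle_expand <- function(seq) {
  opts <- lapply(strsplit(seq, "")[[1L]],
                 function(ch) strsplit(ORACLE_SETS[[ch]], "")[[1L]])
  do.call(paste0, expand.grid(opts, stringsAsFactors = FALSE))
}

random_concrete_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# concrete sequence with k ambiguity codes injected at random positions
random_degenerate_seq <- function(n, k) {
  ch <- strsplit(random_concrete_seq(n), "")[[1L]]
  amb <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  ch[sample.int(n, k)] <- sample(amb, k, replace = TRUE)
  paste(ch, collapse = "")
}

random_multiset <- function() {
  k <- sample(3:25, 1L)
  data.frame(size = sample(50:640, k), weight = stats::rlnorm(k, 4, 1))
}

# run the full simulate -> read -> channel -> noise -> RA -> bin -> match
# recovery experiment; returns per-timepoint Bray-Curtis against truth, the
# exact-match status of every recovered bin, and the disturbance silhouette
run_recovery_experiment <- function(seed) {
  cfg <- sim_config(seed = seed)
  db <- gen_reference_db(cfg)
  series <- gen_community_series(cfg)
  primers <- default_primers()
  frag <- digest_dataset(db$records, primers$fwd, primers$rev, cfg$enzyme)
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv))
  simulate_electropherogram(series, db, cfg, csv)
  pk <- select_channel(read_peak_csv(csv), "B")
  pk <- noise_filter(pk, noise_config(cfg$min_proportion))$peaks
  ex <- bin_profile(relative_abundance(pk), binning_config(),
                    normalise = TRUE)
  attr(ex, "enzyme") <- cfg$enzyme$name
  bc <- binning_config()
  is_filtered <- frag[frag$length >= bc$min_bp & frag$length <= bc$max_bp, ]
  class(is_filtered) <- class(frag)
  attr(is_filtered, "enzyme") <- attr(frag, "enzyme")
  cmp <- match_ex_to_is(ex, is_filtered, window = bc$window, config = bc)

  labels <- as.integer(rownames(ex))
  taxon <- db$truth$id[match(labels, db$truth$trf)]
  braycurtis <- vapply(colnames(ex), function(s) {
    reactor <- sub("_(t[0-9]+)\\.fsa$", "", s)
    tp <- sub(".*_(t[0-9]+)\\.fsa$", "\\1", s)
    truth <- series$abundance[[reactor]][tp, ]
    recovered <- stats::setNames(rep(0, length(truth)), names(truth))
    recovered[taxon] <- ex[, s]
    sum(abs(truth - recovered)) / (sum(truth) + sum(recovered))
  }, numeric(1))

  w <- cfg$disturbance_window
  disturbed <- sprintf("R1_t%02d.fsa", w[1]:w[2])
  control <- grep("^R2", colnames(ex), value = TRUE)
  sel <- c(disturbed, control)
  sil <- cluster::silhouette(as.integer(sel %in% disturbed) + 1L,
                             profile_distance(ex[, sel], "bray"))
  list(ex = ex, comparison = cmp, truth = db$truth,
       braycurtis = braycurtis,
       exact_per_bin = cmp$n_is_trf_fragments > 0,
       taxon_per_bin = taxon,
       mean_silhouette = mean(sil[, "sil_width"]))
}
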