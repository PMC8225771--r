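write_fixture_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

write_fixture_taxonomy <- function(ids, lineages) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(id = ids, lineage = lineages),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("read_reference round-trips records, normalises case and U, and attaches lineages", {
  fa <- write_fixture_fasta(c("r1", "r2"), c("acgu", "GGNNCC"))
  tx <- write_fixture_taxonomy(
    c("r1", "r2"),
    c("Bacteria;Firmicutes;Clostridia;Eubacteriales;Lachnospiraceae;Blautia;Blautia sp.",
      "Bacteria;Actinobacteria"))
  refs <- read_reference(fa, tx)
  expect_s3_class(refs, "trflp_refset")
  expect_equal(refs$id, c("r1", "r2"))
  expect_equal(refs$seq, c("ACGT", "GGNNCC"))
  expect_equal(refs$genus[1], "Blautia")
  expect_equal(refs$phylum, c("Firmicutes", "Actinobacteria"))
  expect_true(is.na(refs$class[2]))
})

test_that("read_reference rejects duplicate ids and non-IUPAC residues, names the culprit", {
  fa <- write_fixture_fasta(c("a", "a"), c("ACGT", "ACGA"))
  tx <- write_fixture_taxonomy("a", "Bacteria")
  expect_error(read_reference(fa, tx), "duplicate FASTA id: a")

  fa2 <- write_fixture_fasta("b", "ACXGT")
  tx2 <- write_fixture_taxonomy("b", "Bacteria")
  expect_error(read_reference(fa2, tx2), "non-IUPAC character 'X' at position 3")
})

test_that("records missing from the taxonomy error unless permissive, then get all-NA lineage", {
  fa <- write_fixture_fasta(c("x", "y"), c("ACGT", "TTTT"))
  tx <- write_fixture_taxonomy("x", "Bacteria;Firmicutes")
  expect_error(read_reference(fa, tx), "'y' absent from taxonomy")
  refs <- read_reference(fa, tx, permissive = TRUE)
  ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")
  expect_true(all(is.na(unlist(refs[2, ranks]))))
  expect_equal(refs$phylum[1], "Firmicutes")
})

test_that("dedup_records keeps first occurrences and reports removals", {
  recs <- data.frame(id = c("A", "B", "C"), seq = c("ACGT", "ACGT", "ACGA"))
  out <- dedup_records(recs)
  expect_equal(out$records$id, c("A", "C"))
  expect_equal(out$removed,
               data.frame(removed_id = "B", kept_id = "A"))

  distinct <- data.frame(id = c("A", "B"), seq = c("AA", "CC"))
  expect_equal(dedup_records(distinct)$records, distinct)

  triple <- data.frame(id = c("A", "B", "C"), seq = rep("GGGG", 3))
  out3 <- dedup_records(triple)
  expect_equal(nrow(out3$records), 1L)
  expect_equal(out3$removed$kept_id, c("A", "A"))
})

test_that("reverse complement is a degeneracy-aware involution", {
  expect_equal(iupac_revcomp("ACGTRYSWKMBDHVN"), "NBDHVKMWSRYACGT")
  set.seed(11)
  for (i in 1:40) {
    s <- random_degenerate_seq(sample(5:60, 1), sample(1:5, 1))
    expect_equal(iupac_revcomp(iupac_revcomp(s)), s)
  }
})

test_that("tagging reproduces the ~634 bp amplicon arithmetic and is invertible", {
  primers <- default_primers()
  expect_equal(nchar(primers$fwd$seq), 23L)
  expect_equal(nchar(primers$rev$seq), 23L)
  insert <- random_concrete_seq(588)
  tagged <- tag_with_primers(insert, primers$fwd, primers$rev)
  expect_equal(nchar(tagged$seq), 634L)
  expect_equal(tagged$insert_len, 588L)
  # removing both flanks recovers the insert
  expect_equal(substr(tagged$seq, 24, nchar(tagged$seq) - 23), insert)

  tiny <- tag_with_primers("A", primer("f", "C"), primer("r", "G"))
  expect_equal(tiny$seq, "CAC")
})

test_that("insilico_pcr anchors on compatible windows and returns no-amplicon otherwise", {
  fwd <- primer("f", "ACGAC")
  rev <- primer("r", "GGTGG")
  template <- paste0("TT", fwd$seq, "AAAA", iupac_revcomp(rev$seq), "TT")
  amp <- insilico_pcr(template, fwd, rev)
  expect_equal(nchar(amp$seq), 5 + 4 + 5)
  expect_equal(amp$insert_len, 4L)
  expect_equal(amp$seq, paste0("ACGAC", "AAAA", "CCACC"))

  expect_null(insilico_pcr("TTTTTTTTTTTT", fwd, rev))

  # degenerate compatibility: N intersects G
  dfwd <- primer("df", "ACN")
  amp2 <- insilico_pcr(paste0("ACG", "AAAA", "CCACC"), dfwd, rev)
  expect_equal(amp2$insert_len, 4L)
  expect_equal(amp2$seq, paste0("ACN", "AAAA", "CCACC"))
})

test_that("find_sites matches hand-derived scans for both enzymes", {
  enzymes <- default_enzymes()
  expect_equal(find_sites("GGGAGCTGGG", enzymes$AluI), 3L)
  expect_equal(find_sites("AATCGTGATT", enzymes$Hpy188III), 2L)
  expect_error(find_sites("AG", enzymes$AluI), "shorter than")
  expect_error(find_sites("ACGTACGT", enzymes$AluI, "sometimes"))
})

test_that("guaranteed and possible semantics split on ambiguous windows as designed", {
  alu <- default_enzymes()$AluI
  expect_equal(find_sites("AANCTAGCTAA", alu, "guaranteed"), 5L)
  expect_equal(find_sites("AANCTAGCTAA", alu, "possible"), c(1L, 5L))
})

test_that("both built-in recognition patterns are their own reverse complement, and bottom-strand scanning works for one that is not", {
  enzymes <- default_enzymes()
  expect_equal(iupac_revcomp(enzymes$AluI$site), enzymes$AluI$site)
  expect_equal(iupac_revcomp(enzymes$Hpy188III$site), enzymes$Hpy188III$site)

  asym <- enzyme("FakeI", "GACGC", 2)  # rc = GCGTC, distinct
  seq <- "TTGACGCTTGCGTCTT"            # site on top at 2, on bottom at 9
  expect_equal(find_sites(seq, asym), c(2L, 9L))
  expect_equal(oracle_sites_concrete(seq, asym$site), c(2L, 9L))
})

test_that("site scanner agrees with the regex oracle on random concrete sequences", {
  set.seed(31)
  enzymes <- default_enzymes()
  for (i in 1:50) {
    s <- random_concrete_seq(120)
    for (enz in enzymes) {
      expected <- oracle_sites_concrete(s, enz$site)
      expect_identical(find_sites(s, enz, "guaranteed"), expected)
      expect_identical(find_sites(s, enz, "possible"), expected)
    }
  }
})

test_that("degenerate semantics equal intersection/union over exhaustive disambiguations", {
  set.seed(32)
  enzymes <- default_enzymes()
  for (i in 1:30) {
    s <- random_degenerate_seq(30, sample(1:4, 1))
    concrete <- oracle_expand(s)
    for (enz in enzymes) {
      per <- lapply(concrete, oracle_sites_concrete, site = enz$site)
      expect_identical(find_sites(s, enz, "guaranteed"),
                       as.integer(Reduce(intersect, per)))
      expect_identical(find_sites(s, enz, "possible"),
                       as.integer(sort(unique(unlist(per)))))
    }
  }
})

test_that("terminal_fragment applies the leftmost-site rule and flags uncut amplicons", {
  alu <- default_enzymes()$AluI
  tf <- terminal_fragment("GGGAGCTGGG", alu)
  expect_equal(tf$length, 5)
  expect_false(tf$unrestricted)

  tf2 <- terminal_fragment("AGCTAGCT", alu)
  expect_equal(tf2$length, 2)

  free <- paste(rep("A", 634), collapse = "")
  tf3 <- terminal_fragment(free, alu)
  expect_equal(tf3$length, 634)
  expect_true(tf3$unrestricted)
})

test_that("digest_dataset preserves cardinality, carries lineage, and plants resolve as expected", {
  alu <- default_enzymes()$AluI
  primers <- default_primers()
  set.seed(5)
  # three site-free records (alphabet without G cannot host AGCT)
  seqs <- replicate(3, paste(sample(c("A", "C", "T"), 80, TRUE), collapse = ""))
  recs <- data.frame(id = c("a", "b", "c"), seq = seqs,
                     lineage = "Bacteria;Firmicutes",
                     domain = "Bacteria", phylum = "Firmicutes",
                     class = NA, order = NA, family = NA, genus = NA,
                     species = NA, stringsAsFactors = FALSE)
  class(recs) <- c("trflp_refset", "data.frame")
  prof <- digest_dataset(recs, primers$fwd, primers$rev, alu)
  expect_equal(nrow(prof), 3L)
  expect_true(all(prof$unrestricted))
  expect_equal(prof$phylum, rep("Firmicutes", 3))

  # planted AluI site at tagged position 100 -> fragment length 102
  insert <- paste(sample(c("A", "C", "T"), 300, TRUE), collapse = "")
  substr(insert, 78, 81) <- "AGCT"   # tagged pos 77 + 23 = 100 (0-based)
  recs$seq[2] <- insert
  prof2 <- digest_dataset(recs, primers$fwd, primers$rev, alu)
  expect_equal(prof2$length[2], 102)
})

test_that("digesting a permuted record set permutes the fragments identically", {
  cfg <- sim_config(seed = 3, n_taxa = 6)
  db <- gen_reference_db(cfg)
  primers <- default_primers()
  prof <- digest_dataset(db$records, primers$fwd, primers$rev, cfg$enzyme)
  perm <- c(4, 2, 6, 1, 3, 5)
  shuffled <- db$records[perm, ]
  class(shuffled) <- class(db$records)
  prof_perm <- digest_dataset(shuffled, primers$fwd, primers$rev, cfg$enzyme)
  expect_equal(prof_perm$record_id, prof$record_id[perm])
  expect_equal(prof_perm$length, prof$length[perm])
})
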