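test_that("size range filter is inclusive at both bounds", {
  trfs <- data.frame(size = c(49, 50, 640, 641), weight = 1)
  kept <- filter_size_range(trfs, binning_config())
  expect_equal(kept$size, c(50, 640))
  expect_equal(nrow(filter_size_range(trfs[0, ], binning_config())), 0L)
  inside <- data.frame(size = c(100, 200), weight = c(2, 3))
  expect_equal(filter_size_range(inside, binning_config()), inside)
})

test_that("a chained run spanning 4 bp forms one bin labelled by its weighted mean", {
  # weighted mean 6322/24 = 263.42 -> nearest even 264
  cl <- cluster_moving_average(
    data.frame(size = c(262, 263, 265, 266), weight = c(7, 11, 1, 5)))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$label, 264L)
  expect_equal(cl$weight, 24)

  single <- cluster_moving_average(data.frame(size = 100, weight = 1))
  expect_equal(single$label, 100L)
  expect_equal(single$n_sizes, 1L)
})

test_that("over-wide chains are split at the leftmost largest gap until spans fit", {
  cl <- cluster_moving_average(
    data.frame(size = c(100, 102, 104, 106), weight = 1))
  expect_equal(cl$label, c(100L, 104L))
  expect_equal(cl$weight, c(1, 3))
  expect_equal(cl$members[[2]], c(102L, 104L, 106L))
  expect_true(all(cl$size_max - cl$size_min <= 4L))
})

test_that("binning conserves weight and keeps labels within one bp of member spans", {
  set.seed(41)
  for (i in 1:50) {
    trfs <- random_multiset()
    cl <- cluster_moving_average(trfs)
    expect_equal(sum(cl$weight), sum(trfs$weight))
    expect_true(all(cl$size_max - cl$size_min <= 4L))
    expect_true(all(cl$label %% 2L == 0L))
    expect_true(all(cl$label >= cl$size_min - 1L & cl$label <= cl$size_max + 1L))
  }
})

test_that("each produced bin is a fixed point of re-binning, and well-separated label sets are stable", {
  set.seed(42)
  for (i in 1:30) {
    cl <- cluster_moving_average(random_multiset())
    for (j in seq_len(nrow(cl))) {
      again <- cluster_moving_average(
        data.frame(size = cl$members[[j]],
                   weight = rep(1, length(cl$members[[j]]))))
      expect_equal(nrow(again), 1L)
    }
    labels <- cl$label
    if (length(labels) == 1L || min(diff(labels)) > 2L) {
      relab <- cluster_moving_average(data.frame(size = labels, weight = 1))
      expect_equal(relab$label, labels)
    }
  }
})

test_that("bin_profile recovers one bin per planted taxon and aligns columns across samples", {
  cfg <- sim_config(seed = 8, n_taxa = 3)
  db <- gen_reference_db(cfg)
  primers <- default_primers()
  frag <- digest_dataset(db$records, primers$fwd, primers$rev, cfg$enzyme)
  tab <- bin_profile(frag)
  expect_s3_class(tab, "otrf_table")
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab == 1))
  expect_setequal(as.integer(rownames(tab)), db$truth$trf)

  peaks <- data.frame(sample = rep(c("s1", "s2"), each = 3),
                      size = rep(c(120, 240, 360), 2),
                      weight = rep(c(10, 30, 60), 2))
  tab2 <- bin_profile(peaks)
  expect_equal(tab2[, "s1"], tab2[, "s2"])
})

test_that("normalised oTRF tables have columns summing to 100", {
  peaks <- data.frame(sample = rep(c("s1", "s2"), each = 2),
                      size = c(100, 200, 101, 333),
                      weight = c(3, 7, 12, 4))
  tab <- bin_profile(peaks, normalise = TRUE)
  expect_equal(unname(colSums(tab)), c(100, 100), tolerance = 1e-9)
})

test_that("a sample emptied by the size filter keeps an all-zero column and warns", {
  peaks <- data.frame(sample = c("ok", "ok", "gone"),
                      size = c(100, 200, 20),
                      weight = c(1, 1, 5))
  expect_warning(tab <- bin_profile(peaks), "'gone' has no peaks inside")
  expect_equal(unname(tab[, "gone"]), c(0, 0))
  expect_equal(unname(colSums(tab)), c(2, 0))
})

test_that("oTRF tables round-trip through the TSV writer with their sidecar", {
  peaks <- data.frame(sample = rep("s1", 3), size = c(70, 71, 73),
                      weight = c(2, 2, 5))
  tab <- bin_profile(peaks)
  main <- tempfile(fileext = ".tsv")
  side <- tempfile(fileext = ".tsv")
  write_otrf_table(tab, main, side)
  back <- read_otrf_table(main)
  expect_equal(rownames(back), rownames(tab))
  expect_equal(unname(back[, "s1"]), unname(tab[, "s1"]))
  side_df <- read.delim(side)
  expect_equal(side_df$member_sizes, "70,71,73")
})
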