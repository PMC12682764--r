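# Window ranking: filters, bin assignment, merging, scoring, locus lookup.

test_that("transcript filter thresholds are inclusive and order-preserving", {
  tx <- make_tx("chr1", list(c(1000, 1300), c(5000, 5250), c(9000, 9300)),
                fpkm = c(0.3, 10, 0.29))
  out <- filter_transcripts(tx, min_length = 300, min_fpkm = 0.3)
  # 300 nt at FPKM 0.3 retained (both inclusive); 250 nt and 0.29 dropped
  expect_equal(out$transcript_id, "tx001")
  expect_error(filter_transcripts(tx, min_length = -1), "min_length")
  expect_equal(nrow(filter_transcripts(tx[0, ])), 0L)
})

test_that("annotation overlap removes transcripts on either strand", {
  tx <- make_tx("chr1", list(c(1000, 2000), c(5000, 6000)), strand = "+")
  ann <- data.frame(chrom = "chr1", start = 1500, end = 1600, strand = "-")
  out <- filter_transcripts(tx, min_length = 0, min_fpkm = 0,
                            known_annotation = ann)
  expect_equal(out$transcript_id, "tx002")
})

test_that("filter survival matches a record-by-record brute-force check", {
  tx <- random_tx(200, five_chrom_genome(), seed = 42)
  ann <- data.frame(chrom = "chr2", start = (1:40) * 1e6,
                    end = (1:40) * 1e6 + 5e4)
  got <- filter_transcripts(tx, 300, 0.3, ann)$transcript_id
  want <- character()
  for (i in seq_len(nrow(tx))) {
    ok <- tx$mature_length[i] >= 300 && tx$fpkm[i] >= 0.3
    if (ok)
      for (a in seq_len(nrow(ann)))
        if (tx$chrom[i] == ann$chrom[a] && tx$start[i] < ann$end[a] &&
            tx$end[i] > ann$start[a]) { ok <- FALSE; break }
    if (ok) want <- c(want, tx$transcript_id[i])
  }
  expect_identical(got, want)
})

test_that("transcripts are assigned to the bin holding their 5' end", {
  tx <- make_tx("chr1", list(c(150000, 151000), c(150000, 251000)),
                strand = c("+", "-"), fpkm = 2)
  bins <- compute_bin_stats(tx, c(chr1 = 5e5), bin_size = 1e5)
  # plus strand: start 150,000 -> bin 1; minus strand: 5' = end-1 -> bin 2
  expect_equal(bins$hits[bins$bin_index == 1], 1L)
  expect_equal(bins$hits[bins$bin_index == 2], 1L)
  # weighted coverage = mature length x FPKM
  expect_equal(bins$weighted_coverage[bins$bin_index == 1], 1000 * 2)
  # empty bins reported with zeros
  expect_equal(nrow(bins), 5L)
  expect_true(all(bins$hits[!bins$bin_index %in% c(1, 2)] == 0L))
})

test_that("unknown chromosomes are reported by transcript id", {
  tx <- make_tx("chrZ", list(c(0, 1000)))
  expect_error(compute_bin_stats(tx, c(chr1 = 1e6)), "tx001")
})

test_that("per-bin sums equal a brute-force accumulation", {
  tx <- random_tx(300, five_chrom_genome(), seed = 7)
  bins <- compute_bin_stats(tx, five_chrom_genome(), bin_size = 1e5)
  for (i in sample.int(nrow(bins), 50)) {
    fp <- ifelse(tx$strand == "-", tx$end - 1, tx$start)
    in_bin <- tx$chrom == bins$chrom[i] &
      fp >= bins$start[i] & fp < bins$start[i] + 1e5
    expect_equal(bins$hits[i], sum(in_bin))
    expect_equal(bins$total_length[i], sum(tx$mature_length[in_bin]))
    expect_equal(bins$weighted_coverage[i],
                 sum(tx$mature_length[in_bin] * tx$fpkm[in_bin]))
  }
  # conservation: bins partition the transcripts
  expect_equal(sum(bins$hits), nrow(tx))
  expect_equal(sum(bins$total_length), sum(tx$mature_length))
})

make_bins_from_pattern <- function(occ) {
  data.frame(chrom = "chr1", bin_index = seq_along(occ) - 1L,
             start = (seq_along(occ) - 1L) * 1e5,
             end = seq_along(occ) * 1e5,
             hits = as.integer(occ), total_length = as.numeric(occ) * 100,
             weighted_coverage = as.numeric(occ) * 10)
}

test_that("a 2-bin gap does not split a window, a 3-bin gap does", {
  w <- merge_windows(make_bins_from_pattern(c(1, 0, 0, 1)))
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$start, w$end), c(0, 4e5))
  expect_equal(w$n_bins, 4L)
  w2 <- merge_windows(make_bins_from_pattern(c(1, 0, 0, 0, 1)))
  expect_equal(nrow(w2), 2L)
})

test_that("window merging matches the brute-force oracle on random patterns", {
  set.seed(123)
  for (k in 1:200) {
    occ <- runif(sample(4:14, 1)) < 0.5
    gap <- sample(0:3, 1)
    got <- merge_windows(make_bins_from_pattern(occ), max_gap_bins = gap)
    want <- oracle_merge(occ, gap)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$first_bin, vapply(want, `[`, numeric(1), 1) - 1)
      expect_equal(got$last_bin, vapply(want, `[`, numeric(1), 2) - 1)
    }
  }
})

test_that("windowing is idempotent on a window's member bins", {
  occ <- c(1, 0, 1, 1, 0, 0, 1)
  w <- merge_windows(make_bins_from_pattern(occ))
  expect_equal(nrow(w), 1L)
  again <- merge_windows(make_bins_from_pattern(occ[1:7]))
  expect_identical(w, again)
})

test_that("a single window ranks (1,1,1) with overall score 3", {
  w <- score_and_rank(merge_windows(make_bins_from_pattern(c(1, 1))))
  expect_equal(unlist(w[1, c("rank_hits", "rank_length", "rank_coverage")],
                      use.names = FALSE), c(1, 1, 1))
  expect_equal(w$overall_score, 3)
  expect_equal(w$overall_rank, 1L)
  expect_error(score_and_rank(w[0, ]), "no windows")
})

test_that("a window dominating all criteria is rank 1", {
  w <- random_window_set(15, seed = 5)
  w$hits[3] <- 99; w$total_length[3] <- 1e6; w$weighted_coverage[3] <- 1e7
  r <- score_and_rank(w)
  expect_equal(r$chrom[r$overall_rank == 1], w$chrom[3])
  expect_equal(r$start[r$overall_rank == 1], w$start[3])
})

test_that("ranking matches the independent sort oracle with tie rules", {
  for (s in 1:50) {
    w <- random_window_set(20, seed = s)
    got <- score_and_rank(w)
    want <- oracle_rank(w)
    key <- paste(w$chrom, w$start)
    got_key <- paste(got$chrom, got$start)
    perm <- match(key, got_key)
    expect_equal(got$rank_hits[perm], want$rank_hits)
    expect_equal(got$rank_length[perm], want$rank_length)
    expect_equal(got$rank_coverage[perm], want$rank_coverage)
    expect_equal(got$overall_score[perm], want$overall_score)
    expect_equal(got$overall_rank[perm], want$overall_rank)
    expect_setequal(got$overall_rank, seq_len(20))
  }
})

test_that("raw-sum mode ranks by descending summed criteria", {
  w <- random_window_set(10, seed = 9)
  r <- score_and_rank(w, score_mode = "raw_sum")
  raw <- w$hits + w$total_length + w$weighted_coverage
  expect_equal(r$overall_score[r$overall_rank == 1], max(raw))
})

test_that("adding a transcript to a window never worsens its ranks", {
  w <- random_window_set(12, seed = 31)
  r0 <- score_and_rank(w)
  i <- 5
  w2 <- w
  w2$hits[i] <- w2$hits[i] + 1L
  w2$total_length[i] <- w2$total_length[i] + 800
  w2$weighted_coverage[i] <- w2$weighted_coverage[i] + 400
  r1 <- score_and_rank(w2)
  key <- paste(w$chrom[i], w$start[i])
  g0 <- r0[paste(r0$chrom, r0$start) == key, ]
  g1 <- r1[paste(r1$chrom, r1$start) == key, ]
  expect_lte(g1$rank_hits, g0$rank_hits)
  expect_lte(g1$rank_length, g0$rank_length)
  expect_lte(g1$rank_coverage, g0$rank_coverage)
})

test_that("locus lookup flags splitting and containment correctly", {
  bins <- make_bins_from_pattern(c(1, 1, 0, 0, 0, 1, 1))
  w <- score_and_rank(merge_windows(bins))
  # locus inside the first window
  loc <- locate_locus(w, "chr1", 0, 2e5)
  expect_true(loc$single_window)
  expect_true(loc$contained)
  # locus spanning both windows: split
  loc2 <- locate_locus(w, "chr1", 1e5, 6e5)
  expect_false(loc2$single_window)
  expect_equal(nrow(loc2$windows), 2L)
  # no overlap
  loc3 <- locate_locus(w, "chr1", 3e5, 4e5)
  expect_false(loc3$single_window)
  expect_equal(nrow(loc3$windows), 0L)
})

test_that("locus overlap sets match brute-force interval intersection", {
  set.seed(77)
  w <- score_and_rank(random_window_set(15, seed = 77))
  w$end <- w$start + sample.int(20, 15) * 1e5
  for (k in 1:30) {
    s <- runif(1, 0, 1.2e7); e <- s + runif(1, 1e4, 3e6)
    chrom <- sample(paste0("chr", 1:3), 1)
    got <- locate_locus(w, chrom, s, e)
    want <- which(w$chrom == chrom & w$start < e & w$end > s)
    expect_setequal(paste(got$windows$chrom, got$windows$start),
                    paste(w$chrom[want], w$start[want]))
  }
})

test_that("window criteria conserve the filtered transcript totals", {
  cfg <- planted_cfg(seed = 13)
  tx <- simulate_transcriptome(cfg)
  lw <- rank_windows(tx, cfg$chrom_sizes)
  kept <- filter_transcripts(tx)
  expect_equal(sum(lw$windows$hits), nrow(kept))
  expect_equal(sum(lw$windows$total_length), sum(kept$mature_length))
  expect_equal(sum(lw$windows$weighted_coverage),
               sum(kept$mature_length * kept$fpkm))
})
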