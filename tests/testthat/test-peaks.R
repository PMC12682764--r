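# SPM conversion, consensus merging, reproducibility filtering, promoter
# normalization.

peak_df <- function(spans, score, chrom = "chr1", name = NULL) {
  n <- length(spans)
  data.frame(
    chrom = rep_len(chrom, n),
    start = vapply(spans, `[`, numeric(1), 1),
    end = vapply(spans, `[`, numeric(1), 2),
    name = if (is.null(name)) sprintf("p%02d", seq_len(n)) else name,
    score_raw = rep_len(score, n), stringsAsFactors = FALSE)
}

test_that("SPM follows the score-per-million formula exactly", {
  # scores summing to 1e6: SPM equals the raw score
  p <- peak_df(list(c(0, 100), c(200, 300)), c(4e5, 6e5))
  expect_equal(to_spm(p)$spm, p$score_raw)
  # scores summing to 2e6: a score-4 peak gets SPM 2
  p2 <- peak_df(list(c(0, 100), c(200, 300)), c(4, 2e6 - 4))
  expect_equal(to_spm(p2)$spm[1], 2)
  expect_error(to_spm(peak_df(list(c(0, 10)), 0)), "positive")
})

test_that("per-sample SPM totals are conserved at one million", {
  set.seed(50)
  for (k in 1:100) {
    n <- sample(5:60, 1)
    s <- sort(sample.int(1e6, n)) * 2
    p <- peak_df(lapply(s, function(x) c(x, x + 100)),
                 rgamma(n, 2, scale = 12))
    expect_equal(sum(to_spm(p)$spm), 1e6, tolerance = 1e-6)
  }
})

test_that("identical peaks from two samples collapse to one consensus", {
  a <- to_spm(peak_df(list(c(100, 500)), 10))
  b <- to_spm(peak_df(list(c(100, 500)), 20))
  m <- merge_peak_sets(list(s1 = a, s2 = b))
  expect_equal(nrow(m$consensus), 1L)
  expect_equal(m$consensus$n_support, 2L)
  expect_setequal(m$support$sample_id, c("s1", "s2"))
})

test_that("the greedy rule keeps the higher-SPM interval, loser as support", {
  a <- to_spm(peak_df(list(c(100, 500), c(1000, 1200)), c(5, 3)))
  b <- to_spm(peak_df(list(c(300, 700)), 10))
  # a: spm 625000 / 375000 ; b: spm 1e6 -> b wins its overlap with a[1]
  m <- merge_peak_sets(list(s1 = a, s2 = b))
  expect_equal(sort(m$consensus$start), c(300, 1000))
  sup <- m$support[m$consensus$consensus_id[
    m$consensus$start == 300][1] == m$support$consensus_id, ]
  expect_setequal(sup$sample_id, c("s1", "s2"))
})

test_that("greedy merge matches a brute-force oracle and ignores file order", {
  brute_merge <- function(pooled) {
    ord <- order(-pooled$spm, -pooled$score_raw, pooled$chrom,
                 pooled$start, pooled$end, pooled$sample_id)
    pooled <- pooled[ord, ]
    kept <- pooled[0, ]
    for (i in seq_len(nrow(pooled))) {
      p <- pooled[i, ]
      ov <- any(kept$chrom == p$chrom & kept$start < p$end &
                  kept$end > p$start)
      if (!ov) kept <- rbind(kept, p)
    }
    kept
  }
  set.seed(60)
  for (k in 1:10) {
    sets <- lapply(1:3, function(s) {
      n <- 25
      st <- sample.int(5e4, n)
      to_spm(peak_df(lapply(st, function(x) c(x, x + sample.int(800, 1))),
                     rgamma(n, 2, scale = 10)))
    })
    names(sets) <- c("s1", "s2", "s3")
    m <- merge_peak_sets(sets)
    pooled <- do.call(rbind, lapply(names(sets), function(s)
      cbind(sets[[s]], sample_id = s)))
    want <- brute_merge(pooled)
    expect_equal(sort(m$consensus$start), sort(want$start))
    # permuting sample order changes nothing
    m2 <- merge_peak_sets(sets[c(3, 1, 2)])
    expect_equal(sort(m2$consensus$start), sort(m$consensus$start))
  }
})

test_that("the reproducibility filter is inclusive and monotone", {
  a <- to_spm(peak_df(list(c(0, 100), c(1000, 1100)), c(2, 999998)))
  b <- to_spm(peak_df(list(c(0, 100), c(5000, 5100)), c(2, 999998)))
  m <- merge_peak_sets(list(s1 = a, s2 = b))
  # shared peak supported at spm exactly 2 in both samples: retained
  f <- reproducibility_filter(m, min_samples = 2, min_spm = 2)
  expect_equal(f$consensus$start, 0)
  # a single-sample peak at huge SPM is removed
  expect_false(1000 %in% f$consensus$start)
  # raising thresholds never adds peaks
  f2 <- reproducibility_filter(m, min_samples = 2, min_spm = 3)
  expect_true(all(f2$consensus$consensus_id %in% f$consensus$consensus_id))
  f3 <- reproducibility_filter(m, min_samples = 3)
  expect_equal(nrow(f3$consensus), 0L)
})

test_that("filtering synthetic peaks recovers exactly the manifest truth", {
  for (s in 1:5) {
    pk <- simulate_peak_samples(peak_sim_config(
      n_true_peaks = 60, n_samples = 3, noise_peaks_per_sample = 30,
      dropout_prob = 0.2, seed = s))
    sets <- lapply(pk$samples, to_spm)
    f <- reproducibility_filter(merge_peak_sets(sets), min_samples = 2,
                                min_spm = 0)
    # with min_spm 0 the filter reduces to >=2-sample support: the truth is
    # exactly the true peaks present in >= 2 samples
    want <- pk$true_peaks[pk$true_peaks$n_samples_present >= 2, ]
    expect_setequal(f$consensus$start, want$start)
    # and no noise interval survives
    noise_starts <- pk$manifest$start[pk$manifest$truth == "noise"]
    expect_false(any(f$consensus$start %in% noise_starts))
  }
})

test_that("promoter windows are strand-aware around the TSS", {
  tss <- data.frame(chrom = "chr1", pos = c(1000, 1000),
                    strand = c("+", "-"))
  w <- promoter_windows(tss)
  # plus strand: [700, 1100); minus strand: (900, 1300]
  expect_equal(GenomicRanges::start(w), c(701, 902))
  expect_equal(GenomicRanges::end(w), c(1100, 1301))
  expect_equal(unname(GenomicRanges::width(w)), c(400, 400))
})

test_that("promoter-insert normalization rescales counts per sample", {
  counts <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
                   dimnames = list(NULL, c("s1", "s2")))
  # equal totals: unchanged
  same <- promoter_insert_normalization(counts, c(s1 = 500, s2 = 500))
  expect_equal(unname(same), unname(counts), ignore_attr = TRUE)
  # s2 has double the promoter depth: its counts halve relative to s1
  norm <- promoter_insert_normalization(counts, c(s1 = 500, s2 = 1000))
  expect_equal(norm[, "s1"] / norm[, "s2"], rep(2, 3))
  expect_error(promoter_insert_normalization(counts, c(s1 = 0, s2 = 10)),
               "zero promoter")
  # brute-force oracle on random inputs
  set.seed(71)
  cc <- matrix(rpois(40, 30), ncol = 4)
  tot <- c(100, 250, 80, 400)
  got <- promoter_insert_normalization(cc, tot)
  for (j in 1:4)
    expect_equal(got[, j], cc[, j] / tot[j] * mean(tot),
                 ignore_attr = TRUE)
})

test_that("promoter totals can be derived from insert positions", {
  tss <- data.frame(chrom = "chr1", pos = 1000, strand = "+")
  ins <- list(
    s1 = data.frame(chrom = "chr1", pos = c(700, 800, 1099, 1100, 200)),
    s2 = data.frame(chrom = "chr1", pos = c(900, 5000)))
  counts <- matrix(c(8, 4), ncol = 2, dimnames = list(NULL, c("s1", "s2")))
  got <- promoter_insert_normalization(counts, inserts = ins, tss = tss)
  # s1 has 3 inserts in [700, 1100); s2 has 1
  expect_equal(attr(got, "promoter_totals"), c(s1 = 3, s2 = 1))
})
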