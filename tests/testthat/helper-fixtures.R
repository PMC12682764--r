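# Shared fixture builders; all randomness is locally seeded.

five_chrom_genome <- function(n = 5, len = 5e7) {
  stats::setNames(rep(len, n), paste0("chr", seq_len(n)))
}

planted_cfg <- function(seed, multiplier = 40, expr_multiplier = 5, ...) {
  transcriptome_sim_config(
    five_chrom_genome(),
    planted_locus = list(chrom = "chr3", start = 2e7, end = 2.3e7),
    planted_multiplier = multiplier,
    planted_expr_multiplier = expr_multiplier,
    seed = seed, ...)
}

# Minimal hand-built transcript table. positions: list of c(start, end);
# strand, fpkm recycled.
make_tx <- function(chrom, spans, strand = "+", fpkm = 1, exons = NULL) {
  n <- length(spans)
  strand <- rep_len(strand, n)
  fpkm <- rep_len(fpkm, n)
  starts <- vapply(spans, `[`, numeric(1), 1L)
  ends <- vapply(spans, `[`, numeric(1), 2L)
  if (is.null(exons))
    exons <- lapply(seq_len(n), function(i)
      list(starts = starts[i], ends = ends[i]))
  data.frame(
    transcript_id = sprintf("tx%03d", seq_len(n)),
    chrom = rep_len(chrom, n), start = starts, end = ends, strand = strand,
    exon_starts = I(lapply(exons, `[[`, "starts")),
    exon_ends = I(lapply(exons, `[[`, "ends")),
    mature_length = vapply(exons, function(e)
      sum(e$ends - e$starts), numeric(1)),
    fpkm = fpkm, stringsAsFactors = FALSE)
}

# Random transcript table for oracle comparisons.
random_tx <- function(n, chrom_sizes, seed) {
  set.seed(seed)
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  len <- pmax(50, round(rlnorm(n, log(900), 1)))
  start <- floor(runif(n) * (chrom_sizes[chrom] - len))
  make_tx_df <- data.frame(
    transcript_id = sprintf("r%04d", seq_len(n)),
    chrom = chrom, start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    exon_starts = I(as.list(start)), exon_ends = I(as.list(start + len)),
    mature_length = len,
    fpkm = rlnorm(n, 0, 1.5), stringsAsFactors = FALSE)
  make_tx_df
}

# Symmetric positive random matrix for balancing tests.
random_symmetric <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, 0.5, 2), n, n)
  m <- (m + t(m)) / 2
  contact_matrix(m)
}

# Brute-force window merge oracle: walks the occupancy vector one bin at a
# time, opening a window at an expressing bin and closing it only after
# observing more than max_gap consecutive empty bins (or the chromosome end).
oracle_merge <- function(occupied, max_gap) {
  runs <- list()
  open <- FALSE
  first <- NA_integer_; last <- NA_integer_; gap <- 0L
  for (i in seq_along(occupied)) {
    if (occupied[i]) {
      if (!open) { open <- TRUE; first <- i }
      last <- i; gap <- 0L
    } else if (open) {
      gap <- gap + 1L
      if (gap > max_gap) {
        runs[[length(runs) + 1L]] <- c(first, last)
        open <- FALSE; gap <- 0L
      }
    }
  }
  if (open) runs[[length(runs) + 1L]] <- c(first, last)
  runs
}

# Independent rank-sum scoring oracle: per-criterion min-ties ranks by
# pairwise counting, overall order by insertion sort over the documented
# tie-break chain.
oracle_rank <- function(w) {
  n <- nrow(w)
  crit_rank <- function(v)
    vapply(seq_len(n), function(i) 1L + sum(v > v[i]), integer(1))
  r1 <- crit_rank(w$hits); r2 <- crit_rank(w$total_length)
  r3 <- crit_rank(w$weighted_coverage)
  score <- r1 + r2 + r3
  before <- function(i, j) {
    if (score[i] != score[j]) return(score[i] < score[j])
    if (w$weighted_coverage[i] != w$weighted_coverage[j])
      return(w$weighted_coverage[i] > w$weighted_coverage[j])
    if (w$chrom[i] != w$chrom[j]) return(w$chrom[i] < w$chrom[j])
    w$start[i] < w$start[j]
  }
  ord <- seq_len(n)
  for (i in seq_len(n)[-1]) {          # insertion sort with `before`
    j <- i
    while (j > 1L && before(ord[j], ord[j - 1L])) {
      tmp <- ord[j]; ord[j] <- ord[j - 1L]; ord[j - 1L] <- tmp
      j <- j - 1L
    }
  }
  rank_out <- integer(n)
  rank_out[ord] <- seq_len(n)
  list(rank_hits = r1, rank_length = r2, rank_coverage = r3,
       overall_score = score, overall_rank = rank_out)
}

random_window_set <- function(n, seed) {
  set.seed(seed)
  data.frame(
    chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
    start = sample.int(100, n) * 1e5,
    end = sample.int(100, n) * 1e5 + 1e7,
    hits = sample.int(10, n, replace = TRUE),
    total_length = sample.int(5, n, replace = TRUE) * 1000,
    weighted_coverage = sample.int(8, n, replace = TRUE) * 500,
    stringsAsFactors = FALSE)
}
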