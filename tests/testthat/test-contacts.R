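# Contact-map operations: balancing, SCC, merging, virtual 4C, calling,
# difference maps.

test_that("balancing equalizes row sums and is idempotent", {
  for (s in 1:3) {
    m <- random_symmetric(100, seed = s)
    b <- balance(m)
    rs <- rowSums(b$counts, na.rm = TRUE)
    rs <- rs[rs > 0]
    expect_lt(sd(rs) / mean(rs), 1e-8)
    b2 <- balance(b)
    expect_equal(b2$counts, b$counts, tolerance = 1e-6)
  }
})

test_that("an already-balanced matrix is returned unchanged up to scale", {
  n <- 20
  m <- contact_matrix(matrix(1, n, n))   # equal row sums already
  b <- balance(m)
  expect_equal(b$counts / b$counts[1, 1], m$counts, tolerance = 1e-9)
})

test_that("zero rows are masked, the rest balanced", {
  set.seed(2)
  cm <- random_symmetric(30, seed = 2)
  counts <- cm$counts
  counts[5, ] <- 0; counts[, 5] <- 0
  b <- balance(contact_matrix(counts))
  expect_true(all(is.na(b$counts[5, ])))
  rs <- rowSums(b$counts, na.rm = TRUE)[-5]
  expect_lt(sd(rs) / mean(rs), 1e-8)
  expect_error(balance(contact_matrix(matrix(0, 12, 12))), "all-zero")
})

test_that("SCC is 1 for self, scale-invariant, and symmetric", {
  m <- simulate_contacts(contact_sim_config(n_bins = 80, seed = 3))
  expect_equal(scc(m, m)$scc, 1, tolerance = 1e-12)
  m2 <- m; m2$counts <- m$counts * 2
  expect_equal(scc(m, m2)$scc, 1, tolerance = 1e-12)
  r1 <- simulate_contacts(contact_sim_config(n_bins = 80, seed = 4))
  expect_equal(scc(m, r1)$scc, scc(r1, m)$scc, tolerance = 1e-12)
  expect_true(abs(scc(m, r1)$scc) <= 1)
  bad <- simulate_contacts(contact_sim_config(n_bins = 40, seed = 4))
  expect_error(scc(m, bad), "grid")
})

stratum_permute <- function(m, seed) {
  set.seed(seed)
  n <- nrow(m$counts)
  out <- matrix(0, n, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    v <- m$counts[cbind(i, i + d)]
    v <- v[sample.int(length(v))]
    out[cbind(i, i + d)] <- v
    out[cbind(i + d, i)] <- v
  }
  contact_matrix(out, chrom = m$chrom, start = m$start,
                 bin_size = m$bin_size)
}

test_that("replicates are concordant; stratum-permuted pairs are not", {
  m1 <- simulate_contacts(contact_sim_config(seed = 31))
  m2 <- simulate_contacts(contact_sim_config(seed = 32))
  expect_gt(scc(m1, m2)$scc, 0.8)
  perm <- stratum_permute(m2, seed = 1)
  expect_lt(abs(scc(m1, perm)$scc), 0.1)
})

test_that("merge_replicates sums concordant pairs and refuses discordant", {
  m1 <- simulate_contacts(contact_sim_config(n_bins = 150, seed = 41))
  # identical replicates: merged = 2x
  same <- merge_replicates(m1, m1)
  expect_equal(same$counts, 2 * m1$counts)
  m2 <- simulate_contacts(contact_sim_config(n_bins = 150, seed = 42))
  merged <- merge_replicates(m1, m2, scc_threshold = 0.9)
  expect_equal(merged$counts, m1$counts + m2$counts)
  expect_gt(attr(merged, "scc"), 0.9)
  perm <- stratum_permute(m2, seed = 2)
  expect_error(merge_replicates(m1, perm), "SCC")
})

test_that("virtual 4C smooths with a centered 3-bin mean", {
  # constant matrix -> constant profile
  cm <- contact_matrix(matrix(4, 12, 12))
  cm$balanced <- TRUE
  p <- virtual_4c(cm, viewpoint = 55000)
  expect_true(all(p$values == 4))
  # impulse row: [0,0,3,0,0,...] -> [0,1,1,1,0,...]
  n <- 10
  counts <- matrix(0, n, n)
  counts[2, 5] <- 3; counts[5, 2] <- 3
  cm2 <- contact_matrix(counts); cm2$balanced <- TRUE
  p2 <- virtual_4c(cm2, viewpoint = (2 - 1) * 10000 + 1)
  expect_equal(p2$values[3:7], c(0, 1, 1, 1, 0))
  # edges average over available neighbors only
  counts3 <- matrix(0, n, n)
  counts3[3, 1] <- 6; counts3[1, 3] <- 6
  cm3 <- contact_matrix(counts3); cm3$balanced <- TRUE
  p3 <- virtual_4c(cm3, viewpoint = 25000)
  expect_equal(p3$values[1], 3)  # mean of bins 1,2 only
  expect_error(virtual_4c(cm3, viewpoint = 1e9), "outside")
})

test_that("smoothed profile equals brute-force 3-bin means everywhere", {
  m <- balance(simulate_contacts(contact_sim_config(n_bins = 60, seed = 6)))
  vp_bin <- 30
  p <- virtual_4c(m, viewpoint = (vp_bin - 1) * 10000)
  row <- m$counts[vp_bin, ]
  for (i in seq_along(row)) {
    win <- row[max(1, i - 1):min(length(row), i + 1)]
    expect_equal(p$values[i], mean(win, na.rm = TRUE))
  }
  # viewpoint zone excluded from eligibility
  expect_false(any(p$eligible[(vp_bin - 1):(vp_bin + 1)]))
})

test_that("top-interaction calls obey the ceil count rule", {
  vals <- seq_len(103) / 10
  p <- structure(list(values = c(vals, rep(NA, 0)),
                      eligible = c(rep(TRUE, 100), rep(FALSE, 3)),
                      viewpoint_bin = 101, chrom = "chrSim", start = 0,
                      bin_size = 1e4, window_bp = 3e4),
                 class = "virtual4c_profile")
  calls <- call_top_interactions(p, fraction = 0.15)
  expect_length(calls$per_replicate[[1]], 15L)   # ceil(0.15 * 100)
  expect_equal(calls$intersection, calls$per_replicate[[1]])
  expect_equal(calls$intersection, 86:100)
  expect_error(call_top_interactions(p, fraction = 1.2), "fraction")
})

test_that("ties at the threshold are all included", {
  p <- structure(list(values = c(rep(5, 4), rep(1, 16)),
                      eligible = rep(TRUE, 20), viewpoint_bin = 1,
                      chrom = "chrSim", start = 0, bin_size = 1e4,
                      window_bp = 3e4),
                 class = "virtual4c_profile")
  calls <- call_top_interactions(p, fraction = 0.15)
  # k = 3 but four bins tie at the threshold value 5
  expect_equal(calls$per_replicate[[1]], 1:4)
})

test_that("the intersection shrinks monotonically with more replicates", {
  profs <- lapply(51:53, function(s)
    virtual_4c(balance(simulate_contacts(contact_sim_config(
      n_bins = 100, seed = s))), viewpoint = 5e5))
  c2 <- call_top_interactions(profs[1:2])
  c3 <- call_top_interactions(profs)
  expect_true(all(c3$intersection %in% c2$intersection))
})

test_that("difference maps are antisymmetric and zero for rank-equal input", {
  mA <- balance(simulate_contacts(contact_sim_config(n_bins = 80,
                                                     seed = 61)))
  mB <- balance(simulate_contacts(contact_sim_config(n_bins = 80,
                                                     seed = 62)))
  d1 <- difference_map(mA, mB)
  d2 <- difference_map(mB, mA)
  expect_equal(d1, -d2)
  expect_equal(d1, t(d1))
  # identical input -> zero
  expect_true(all(difference_map(mA, mA) == 0, na.rm = TRUE))
  # monotone transform -> rank equality -> zero map
  mC <- mA; mC$counts <- mA$counts^1.7 + 3
  d3 <- difference_map(mA, mC)
  expect_true(all(abs(d3) < 1e-9, na.rm = TRUE))
})

test_that("a planted loop dominates the upper-triangle difference", {
  # well-covered maps under the pure decay model (no visibility structure),
  # one 8-fold loop planted in A only
  hits <- 0L
  for (s in 1:10) {
    pp <- data.frame(i = 40, j = 140, fold = 8)
    mA <- balance(simulate_contacts(contact_sim_config(
      n_bins = 200, base_intensity = 1000, structure_amp = 0,
      planted_pairs = pp, seed = s)))
    mB <- balance(simulate_contacts(contact_sim_config(
      n_bins = 200, base_intensity = 1000, structure_amp = 0,
      seed = s + 500)))
    d <- difference_map(mA, mB)
    d[lower.tri(d, diag = TRUE)] <- NA
    top <- which(d == max(d, na.rm = TRUE), arr.ind = TRUE)
    if (any(top[, 1] == 40 & top[, 2] == 140)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
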