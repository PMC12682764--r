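#' Balance a contact matrix to equal row sums
#'
#' Symmetric iterative proportional scaling: finds a diagonal matrix `D` such
#' that every unmasked row of `D %*% M %*% D` sums to the same constant (the
#' mean of the unmasked raw row sums, so merged and unmerged matrices stay on
#' comparable scales). Rows whose raw sum falls below `sparsity * median row
#' sum` are masked (set to `NA`) before balancing, the usual guard against
#' unmappable or empty bins.
#'
#' @param m A raw [contact_matrix()].
#' @param tol Relative row-sum tolerance for convergence (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @param sparsity Row-masking threshold as a fraction of the median raw row
#'   sum (default 0.1).
#' @return A balanced `contact_matrix` (masked rows/columns `NA`). The
#'   scaling vector is attached as attribute `"scaling"`.
#' @export
balance <- function(m, tol = 1e-8, max_iter = 1000, sparsity = 0.1) {
  stopifnot(inherits(m, "contact_matrix"))
  counts <- m$counts
  na_row <- rowSums(!is.na(counts)) == 0L
  rs <- rowSums(counts, na.rm = TRUE)
  if (all(rs == 0)) stop("cannot balance an all-zero matrix", call. = FALSE)
  mask <- na_row | rs < sparsity * median(rs)
  sub <- counts[!mask, !mask, drop = FALSE]
  if (!nrow(sub)) stop("all rows masked; nothing to balance", call. = FALSE)
  target <- mean(rowSums(sub))
  scale_vec <- rep(1, nrow(sub))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    r <- rowSums(sub)
    resid <- max(abs(r / target - 1))
    if (resid < tol) { converged <- TRUE; break }
    s <- sqrt(target / r)
    sub <- sub * outer(s, s)
    scale_vec <- scale_vec * s
  }
  if (!converged) {
    r <- rowSums(sub)
    resid <- max(abs(r / target - 1))
    if (resid >= tol)
      stop(sprintf(
        "balancing did not converge in %d iterations (residual %.3g)",
        max_iter, resid), call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(counts), ncol(counts))
  out[!mask, !mask] <- sub
  res <- contact_matrix(ifelse(is.na(out), 0, out), chrom = m$chrom,
                        start = m$start, bin_size = m$bin_size,
                        balanced = TRUE)
  res$counts <- out
  full_scale <- rep(NA_real_, nrow(counts))
  full_scale[!mask] <- scale_vec
  attr(res, "scaling") <- full_scale
  res
}

#' Stratum-adjusted correlation coefficient between two contact matrices
#'
#' Hi-C replicate concordance that controls for distance decay: within each
#' diagonal stratum `d = 0..max_distance_bins` the two matrices' stratum
#' entries are Pearson-correlated, and the stratum correlations are combined
#' with weights `n_d * sd1_d * sd2_d` (stratum size times the two stratum
#' standard deviations). Strata with zero variance in either matrix are
#' skipped. The result is scale-invariant per matrix and equals 1 for
#' identical inputs.
#'
#' @param m1,m2 Two [contact_matrix()] objects on the same grid.
#' @param max_distance_bins Largest diagonal offset included (default:
#'   all, `N - 1`).
#' @return An object of class `scc_result`: `scc`, `strata` (per-stratum
#'   data.frame with `distance`, `r`, `weight`, `n`), `max_distance_bins`.
#' @export
scc <- function(m1, m2, max_distance_bins = NULL) {
  stopifnot(inherits(m1, "contact_matrix"), inherits(m2, "contact_matrix"))
  check_same_grid(m1, m2)
  n <- nrow(m1$counts)
  if (is.null(max_distance_bins)) max_distance_bins <- n - 1L
  strata <- list()
  for (d in 0:max_distance_bins) {
    i <- seq_len(n - d)
    x <- m1$counts[cbind(i, i + d)]
    y <- m2$counts[cbind(i, i + d)]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2L) next
    sx <- sd(x); sy <- sd(y)
    if (sx == 0 || sy == 0) next
    strata[[length(strata) + 1L]] <- data.frame(
      distance = d, r = cor(x, y), weight = length(x) * sx * sy,
      n = length(x))
  }
  if (!length(strata))
    stop("no informative strata (all constant or missing)", call. = FALSE)
  st <- do.call(rbind, strata)
  structure(list(
    scc = sum(st$r * st$weight) / sum(st$weight),
    strata = st, max_distance_bins = max_distance_bins
  ), class = "scc_result")
}

#' @export
print.scc_result <- function(x, ...) {
  cat(sprintf("SCC = %.4f over %d strata (offsets 0..%d)\n",
              x$scc, nrow(x$strata), x$max_distance_bins))
  invisible(x)
}

#' Merge replicate contact matrices if sufficiently concordant
#'
#' Computes the stratum-adjusted correlation coefficient between two raw
#' replicate matrices; if it meets the threshold (default 0.9) the replicates
#' are merged by entrywise summation of raw counts, otherwise the merge is
#' refused with an error reporting the SCC.
#'
#' @param m1,m2 Raw replicate [contact_matrix()] objects on the same grid.
#' @param scc_threshold Minimum SCC required to merge (default 0.9).
#' @param max_distance_bins Passed to [scc()].
#' @return The merged raw `contact_matrix`; the achieved SCC is attached as
#'   attribute `"scc"`.
#' @export
merge_replicates <- function(m1, m2, scc_threshold = 0.9,
                             max_distance_bins = NULL) {
  s <- scc(m1, m2, max_distance_bins)
  if (s$scc < scc_threshold)
    stop(sprintf("replicates not concordant enough to merge: SCC %.4f < %.2f",
                 s$scc, scc_threshold), call. = FALSE)
  out <- contact_matrix(m1$counts + m2$counts, chrom = m1$chrom,
                        start = m1$start, bin_size = m1$bin_size,
                        balanced = FALSE)
  attr(out, "scc") <- s$scc
  out
}

#' Virtual-4C interaction profile for one viewpoint
#'
#' Extracts the viewpoint bin's row from a balanced contact matrix and
#' smooths it with a centered rolling mean spanning `window_bp` (30 kb over
#' 10-kb bins = 3 bins), stepping one bin (the 10-kb slide). Edge bins
#' average over their available neighbors. The viewpoint bin and its two
#' immediate neighbors are flagged ineligible for interaction calling (the
#' self-ligation zone would otherwise dominate any top-percentile call).
#' Masked bins stay missing.
#'
#' @param m A balanced [contact_matrix()].
#' @param viewpoint Genomic position (bp) of the viewpoint, inside the
#'   matrix region.
#' @param window_bp Rolling-window span in bp (default 30,000).
#' @return An object of class `virtual4c_profile`: `values` (smoothed),
#'   `raw` (unsmoothed row), `viewpoint_bin`, `eligible` (logical per bin),
#'   plus grid metadata.
#' @export
virtual_4c <- function(m, viewpoint, window_bp = 30000) {
  stopifnot(inherits(m, "contact_matrix"))
  vp <- position_to_bin(m, viewpoint)
  row <- m$counts[vp, ]
  k <- max(1L, round(window_bp / m$bin_size))
  half <- (k - 1L) %/% 2L
  n <- length(row)
  sm <- vapply(seq_len(n), function(i) {
    if (is.na(row[i])) return(NA_real_)
    win <- row[max(1L, i - half):min(n, i + half)]
    mean(win, na.rm = TRUE)
  }, numeric(1))
  eligible <- !is.na(sm)
  excl <- max(1L, vp - 1L):min(n, vp + 1L)
  eligible[excl] <- FALSE
  structure(list(
    values = sm, raw = row, viewpoint_bin = vp, eligible = eligible,
    chrom = m$chrom, start = m$start, bin_size = m$bin_size,
    window_bp = window_bp
  ), class = "virtual4c_profile")
}

#' @export
print.virtual4c_profile <- function(x, ...) {
  cat(sprintf(
    "Virtual 4C: viewpoint bin %d (%s:%s), %d bins, %g-bp window, %d eligible\n",
    x$viewpoint_bin, x$chrom,
    format(x$start + (x$viewpoint_bin - 1L) * x$bin_size,
           scientific = FALSE),
    length(x$values), x$window_bp, sum(x$eligible)))
  invisible(x)
}

#' Call top-percentile interactions across replicate virtual-4C profiles
#'
#' Per replicate, flags the eligible bins whose smoothed value reaches the
#' top `fraction` of that profile's eligible bins: with `k =
#' ceiling(fraction * n_eligible)`, every bin whose value is at least the
#' k-th largest eligible value is called, so ties at the threshold may push
#' the call count above `k`. The final call set is the intersection across
#' replicates, the "in both biological replicates" rule.
#'
#' @param profiles A single `virtual4c_profile` or a list of them on the
#'   same grid.
#' @param fraction Top fraction to call, in (0, 1) (default 0.15).
#' @return A list of class `interaction_calls`: `per_replicate` (list of
#'   integer bin-index vectors), `intersection`, `thresholds`, `fraction`.
#' @export
call_top_interactions <- function(profiles, fraction = 0.15) {
  if (inherits(profiles, "virtual4c_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("need at least one profile", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must be in (0, 1)", call. = FALSE)
  n <- length(profiles[[1L]]$values)
  per <- vector("list", length(profiles))
  thr <- numeric(length(profiles))
  for (r in seq_along(profiles)) {
    p <- profiles[[r]]
    if (length(p$values) != n)
      stop("profiles are not on the same grid", call. = FALSE)
    idx <- which(p$eligible)
    vals <- p$values[idx]
    k <- ceiling(fraction * length(idx))
    if (k < 1L) stop("no eligible bins to call", call. = FALSE)
    thr[r] <- sort(vals, decreasing = TRUE)[k]
    per[[r]] <- idx[vals >= thr[r]]
  }
  inter <- Reduce(intersect, per)
  structure(list(per_replicate = per, intersection = sort(inter),
                 thresholds = thr, fraction = fraction),
            class = "interaction_calls")
}

#' @export
print.interaction_calls <- function(x, ...) {
  cat(sprintf(
    "Top-%.0f%% interaction calls: %s per replicate; %d in the intersection\n",
    100 * x$fraction,
    paste(vapply(x$per_replicate, length, integer(1)), collapse = "/"),
    length(x$intersection)))
  invisible(x)
}

#' Quantile-normalized difference map between two contact matrices
#'
#' Within each diagonal stratum (fixed genomic distance), both matrices'
#' entries are quantile-normalized to their pooled empirical distribution
#' (each value rank-mapped to the average of the two sorted samples) and
#' subtracted; the difference is then standardized by the leave-one-out
#' standard deviation of that stratum's differences, so differences at all
#' distances are on one comparable scale and one strong focal difference
#' cannot inflate its own yardstick. Stratification replaces the
#' random-ensemble reference of full-scale difference-heatmap pipelines:
#' like that reference, it calibrates each distance separately, since
#' raw-unit differences would be dominated by the short-range strata where
#' balanced values (and their noise) are largest. Strata with fewer than
#' `min_stratum` jointly observed entries carry too little information to
#' normalize and are set to zero.
#'
#' Rank-equivalent inputs give an identically zero map, and
#' `difference_map(A, B) == -difference_map(B, A)`. Entries missing in
#' either matrix are missing in the result.
#'
#' @param mA,mB Balanced [contact_matrix()] objects on the same grid.
#' @param min_stratum Minimum jointly observed entries for a stratum to be
#'   normalized (default 10).
#' @return A signed symmetric matrix of standardized differences
#'   (positive where `mA` is enriched over `mB`).
#' @export
difference_map <- function(mA, mB, min_stratum = 10) {
  stopifnot(inherits(mA, "contact_matrix"), inherits(mB, "contact_matrix"))
  check_same_grid(mA, mB)
  n <- nrow(mA$counts)
  out <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    a <- mA$counts[cbind(i, i + d)]
    b <- mB$counts[cbind(i, i + d)]
    ok <- !is.na(a) & !is.na(b)
    m <- sum(ok)
    v <- rep(NA_real_, length(a))
    if (m >= max(min_stratum, 3L)) {
      qn <- limma::normalizeQuantiles(cbind(a[ok], b[ok]))
      dv <- qn[, 1L] - qn[, 2L]
      S <- sum(dv); SS <- sum(dv^2)
      mu_i <- (S - dv) / (m - 1)
      var_i <- pmax(0, ((SS - dv^2) - (m - 1) * mu_i^2) / (m - 2))
      v[ok] <- ifelse(var_i > 0, dv / sqrt(var_i), 0)
    } else {
      v[ok] <- 0
    }
    out[cbind(i, i + d)] <- v
    out[cbind(i + d, i)] <- v
  }
  out
}
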