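#' Convert peak scores to score-per-million (SPM)
#'
#' Rescales each peak's -log10(p) score by the sample's total score divided
#' by one million: `spm_i = score_i / (sum(score) / 1e6)`, so the SPMs of one
#' sample sum to exactly one million (up to floating tolerance). This puts
#' peak significance on a common scale across samples of different depth.
#'
#' @param peaks One sample's peak data.frame with column `score_raw`
#'   (non-negative, positive total).
#' @return The data.frame with an added `spm` column.
#' @export
to_spm <- function(peaks) {
  if (!nrow(peaks) || sum(peaks$score_raw) <= 0)
    stop("sample has no positive total peak score", call. = FALSE)
  if (any(peaks$score_raw < 0))
    stop("peak scores must be non-negative", call. = FALSE)
  peaks$spm <- peaks$score_raw / (sum(peaks$score_raw) / 1e6)
  peaks
}

#' Merge per-sample peak sets into a non-overlapping consensus
#'
#' All SPM-converted peaks are pooled and resolved greedily: peaks are
#' visited in descending SPM order (ties: descending raw score, then
#' coordinate, then sample id — a deterministic total order, so the result
#' does not depend on input file order) and a peak is kept iff it overlaps no
#' already-kept peak (overlap = at least one shared base). Each kept
#' consensus peak then collects, per sample, the best-SPM peak of that sample
#' overlapping it as its support.
#'
#' @param peak_sets Named list of per-sample peak data.frames (columns
#'   `chrom`, `start`, `end`, `name`, `score_raw`, `spm`; see [to_spm()]).
#' @return An object of class `merged_peaks`: `consensus` (data.frame of kept
#'   peaks with `consensus_id`, interval, originating sample, `n_support`)
#'   and `support` (long data.frame: `consensus_id`, `sample_id`, `spm`,
#'   `score_raw`).
#' @export
merge_peak_sets <- function(peak_sets) {
  if (is.null(names(peak_sets)) || any(!nzchar(names(peak_sets))))
    stop("'peak_sets' must be a named list (one element per sample)",
         call. = FALSE)
  pooled <- do.call(rbind, lapply(names(peak_sets), function(s) {
    p <- peak_sets[[s]]
    if (!"spm" %in% names(p))
      stop("sample '", s, "' is not SPM-converted; run to_spm() first",
           call. = FALSE)
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               name = p$name, score_raw = p$score_raw, spm = p$spm,
               sample_id = s, stringsAsFactors = FALSE)
  }))
  ord <- order(-pooled$spm, -pooled$score_raw, pooled$chrom, pooled$start,
               pooled$end, pooled$sample_id)
  pooled <- pooled[ord, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    pooled$chrom, IRanges::IRanges(pooled$start + 1L, pooled$end))
  hits <- GenomicRanges::findOverlaps(gr, gr)
  nbr <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  kept <- logical(nrow(pooled))
  for (i in seq_len(nrow(pooled))) {
    others <- nbr[[as.character(i)]]
    kept[i] <- !any(kept[others[others != i]])
  }
  consensus <- pooled[kept, , drop = FALSE]
  consensus$consensus_id <- sprintf("peak%05d", seq_len(nrow(consensus)))
  rownames(consensus) <- NULL
  # Support: per consensus peak and sample, the best-SPM overlapping peak.
  cons_gr <- GenomicRanges::GRanges(
    consensus$chrom, IRanges::IRanges(consensus$start + 1L, consensus$end))
  sup <- GenomicRanges::findOverlaps(cons_gr, gr)
  sup_df <- data.frame(
    consensus_id = consensus$consensus_id[S4Vectors::queryHits(sup)],
    sample_id = pooled$sample_id[S4Vectors::subjectHits(sup)],
    spm = pooled$spm[S4Vectors::subjectHits(sup)],
    score_raw = pooled$score_raw[S4Vectors::subjectHits(sup)],
    peak_name = pooled$name[S4Vectors::subjectHits(sup)],
    stringsAsFactors = FALSE
  )
  # Best per (consensus, sample): pooled is already sorted by descending SPM.
  sup_df <- sup_df[!duplicated(sup_df[, c("consensus_id", "sample_id")]), ,
                   drop = FALSE]
  rownames(sup_df) <- NULL
  n_sup <- table(sup_df$consensus_id)
  consensus$n_support <- as.integer(n_sup[consensus$consensus_id])
  structure(list(consensus = consensus, support = sup_df,
                 samples = names(peak_sets)),
            class = "merged_peaks")
}

#' @export
print.merged_peaks <- function(x, ...) {
  cat(sprintf("Merged peak set: %d consensus peaks from %d samples\n",
              nrow(x$consensus), length(x$samples)))
  if ("pass" %in% names(x$consensus))
    cat(sprintf("  %d pass the reproducibility filter\n",
                sum(x$consensus$pass)))
  invisible(x)
}

#' Filter consensus peaks for cross-sample reproducibility
#'
#' Retains consensus peaks supported in at least `min_samples` samples, each
#' supporting peak having SPM at or above `min_spm` (both thresholds
#' inclusive).
#'
#' @param merged A [merge_peak_sets()] result.
#' @param min_samples Minimum number of qualifying supporting samples
#'   (default 2).
#' @param min_spm Minimum supporting SPM (default 2).
#' @return A `merged_peaks` object containing only the passing consensus
#'   peaks (and their support); the number removed is attached as attribute
#'   `"n_removed"`.
#' @export
reproducibility_filter <- function(merged, min_samples = 2, min_spm = 2) {
  stopifnot(inherits(merged, "merged_peaks"))
  sup <- merged$support
  good <- sup[sup$spm >= min_spm, , drop = FALSE]
  n_good <- table(good$consensus_id)
  pass_ids <- names(n_good)[n_good >= min_samples]
  pass <- merged$consensus$consensus_id %in% pass_ids
  out <- merged
  out$consensus <- merged$consensus[pass, , drop = FALSE]
  out$support <- sup[sup$consensus_id %in% pass_ids, , drop = FALSE]
  rownames(out$consensus) <- NULL
  rownames(out$support) <- NULL
  attr(out, "n_removed") <- sum(!pass)
  out
}

#' Promoter windows around transcription start sites
#'
#' The nucleosome-depleted promoter interval `[TSS - 300, TSS + 100)` in the
#' direction of transcription: coordinates are flipped for minus-strand
#' genes, where the window is `(TSS - 100, TSS + 300]` in genomic
#' coordinates.
#'
#' @param tss Data.frame with `chrom`, `pos` (0-based TSS coordinate),
#'   `strand`.
#' @param upstream,downstream Window extent in bp (defaults 300 and 100).
#' @return A `GRanges` of promoter windows.
#' @export
promoter_windows <- function(tss, upstream = 300, downstream = 100) {
  plus <- tss$strand != "-"
  start0 <- ifelse(plus, tss$pos - upstream, tss$pos - downstream + 1L)
  end0 <- ifelse(plus, tss$pos + downstream, tss$pos + upstream + 1L)
  GenomicRanges::GRanges(tss$chrom,
                         IRanges::IRanges(start0 + 1L, end0),
                         strand = tss$strand)
}

#' Normalize a peak-by-sample count matrix by promoter insert depth
#'
#' Divides each sample's fragment counts by that sample's total number of
#' inserts falling in nucleosome-depleted promoter windows, then rescales by
#' the across-sample mean promoter total so values stay in count-like units.
#' Samples sharing one promoter total are returned unchanged.
#'
#' @param counts Numeric matrix, peaks x samples.
#' @param promoter_totals Either a numeric vector of per-sample promoter
#'   insert totals (named or in column order), or `NULL` to derive them from
#'   `inserts` and `tss`.
#' @param inserts Optional named list (per sample) of data.frames with
#'   `chrom`, `pos` giving insert positions; used with `tss` when
#'   `promoter_totals` is `NULL`.
#' @param tss Optional TSS data.frame (see [promoter_windows()]).
#' @return The normalized matrix; per-sample totals attached as attribute
#'   `"promoter_totals"`.
#' @export
promoter_insert_normalization <- function(counts, promoter_totals = NULL,
                                          inserts = NULL, tss = NULL) {
  counts <- as.matrix(counts)
  if (is.null(promoter_totals)) {
    if (is.null(inserts) || is.null(tss))
      stop("supply promoter_totals, or inserts plus tss", call. = FALSE)
    win <- promoter_windows(tss)
    promoter_totals <- vapply(inserts, function(ins) {
      gr <- GenomicRanges::GRanges(
        ins$chrom, IRanges::IRanges(ins$pos + 1L, ins$pos + 1L))
      sum(GenomicRanges::countOverlaps(gr, win, ignore.strand = TRUE) > 0L)
    }, numeric(1))
  }
  if (length(promoter_totals) != ncol(counts))
    stop("one promoter total per sample is required", call. = FALSE)
  if (any(promoter_totals <= 0)) {
    bad <- which(promoter_totals <= 0)[1L]
    stop("sample ", if (!is.null(names(promoter_totals)))
      names(promoter_totals)[bad] else bad,
      " has zero promoter inserts", call. = FALSE)
  }
  out <- sweep(counts, 2L, promoter_totals, "/") * mean(promoter_totals)
  attr(out, "promoter_totals") <- promoter_totals
  out
}
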