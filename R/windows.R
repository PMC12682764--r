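#' Filter assembled transcripts by length, expression, and annotation overlap
#'
#' Retains transcripts whose mature (exon-sum) length and expression meet the
#' inclusive thresholds used for lncRNA candidate selection (>= 300 nt,
#' FPKM >= 0.3 by default). If a known-gene annotation is supplied, records
#' whose genomic span overlaps any annotated interval on either strand are
#' also dropped, leaving only unannotated transcripts.
#'
#' @param transcripts Transcript data.frame (see [simulate_transcriptome()]
#'   or [read_transcripts_gtf()] for the column contract).
#' @param min_length Minimum mature transcript length, bp (inclusive).
#' @param min_fpkm Minimum expression, FPKM (inclusive).
#' @param known_annotation Optional `GRanges` (or data.frame with `chrom`,
#'   `start`, `end`) of annotated exons/genes; overlap is strand-blind.
#' @return The filtered transcript data.frame, input order preserved.
#' @export
filter_transcripts <- function(transcripts, min_length = 300, min_fpkm = 0.3,
                               known_annotation = NULL) {
  check_transcripts(transcripts)
  stop_if_not_scalar_number(min_length, "min_length", min = 0)
  stop_if_not_scalar_number(min_fpkm, "min_fpkm", min = 0)
  keep <- transcripts$mature_length >= min_length &
    transcripts$fpkm >= min_fpkm
  if (!is.null(known_annotation) && nrow(transcripts)) {
    ann <- as_granges(known_annotation)
    tx_gr <- GenomicRanges::GRanges(
      transcripts$chrom,
      IRanges::IRanges(transcripts$start + 1L, transcripts$end))
    hit <- GenomicRanges::countOverlaps(tx_gr, ann, ignore.strand = TRUE) > 0L
    keep <- keep & !hit
  }
  out <- transcripts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end),
                         strand = if ("strand" %in% names(x)) x$strand else "*")
}

#' Tile the genome and accumulate per-bin transcript statistics
#'
#' Bins tile each chromosome as `[k*bin_size, min((k+1)*bin_size, len))` in
#' 0-based half-open coordinates. Each transcript is assigned to exactly one
#' bin: the one containing its 5'-most genomic coordinate (`start` on the plus
#' strand, `end - 1` on the minus strand). Three statistics accumulate per
#' bin: transcript count (hits), summed mature length, and summed
#' length-by-FPKM weighted coverage. Bins with no transcripts are reported
#' with zeros.
#'
#' @param transcripts Filtered transcript data.frame.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin_size Bin width in bp (default 100,000).
#' @return A data.frame with one row per genome bin: `chrom`, `bin_index`
#'   (0-based), `start`, `end`, `hits`, `total_length`, `weighted_coverage`.
#' @export
compute_bin_stats <- function(transcripts, chrom_sizes, bin_size = 100000) {
  check_transcripts(transcripts)
  check_chrom_sizes(chrom_sizes)
  stop_if_not_scalar_number(bin_size, "bin_size", min = 0, allow_min = FALSE)
  unknown <- setdiff(unique(transcripts$chrom), names(chrom_sizes))
  if (length(unknown)) {
    bad <- transcripts$transcript_id[transcripts$chrom %in% unknown][1L]
    stop("transcript '", bad, "' lies on unknown chromosome '",
         transcripts$chrom[transcripts$chrom %in% unknown][1L], "'",
         call. = FALSE)
  }
  n_bins <- ceiling(chrom_sizes / bin_size)
  bins <- data.frame(
    chrom = rep(names(chrom_sizes), n_bins),
    bin_index = unlist(lapply(n_bins, function(n) seq_len(n) - 1L),
                       use.names = FALSE),
    stringsAsFactors = FALSE
  )
  bins$start <- bins$bin_index * bin_size
  bins$end <- pmin(bins$start + bin_size,
                   chrom_sizes[bins$chrom])
  bins$hits <- 0L
  bins$total_length <- 0
  bins$weighted_coverage <- 0
  if (nrow(transcripts)) {
    five_prime <- ifelse(transcripts$strand == "-",
                         transcripts$end - 1L, transcripts$start)
    bi <- five_prime %/% bin_size
    key <- paste(transcripts$chrom, bi)
    bin_key <- paste(bins$chrom, bins$bin_index)
    idx <- match(key, bin_key)
    if (anyNA(idx))
      stop("transcript '", transcripts$transcript_id[which(is.na(idx))[1L]],
           "' falls outside its chromosome's bins", call. = FALSE)
    for (k in seq_along(idx)) {
      i <- idx[k]
      bins$hits[i] <- bins$hits[i] + 1L
      bins$total_length[i] <- bins$total_length[i] +
        transcripts$mature_length[k]
      bins$weighted_coverage[i] <- bins$weighted_coverage[i] +
        transcripts$mature_length[k] * transcripts$fpkm[k]
    }
  }
  rownames(bins) <- NULL
  bins
}

# Core run-merging on an occupancy vector: returns a list of (first, last)
# 1-based indices of merged runs, where expressing positions separated by
# <= max_gap empty positions share a run.
merge_runs <- function(occupied, max_gap) {
  pos <- which(occupied)
  if (!length(pos)) return(list())
  gap <- diff(pos) - 1L
  brk <- which(gap > max_gap)
  first <- pos[c(1L, brk + 1L)]
  last <- pos[c(brk, length(pos))]
  mapply(function(f, l) c(f, l), first, last, SIMPLIFY = FALSE)
}

#' Merge contiguous expressing bins into windows
#'
#' Within a chromosome, bins containing transcripts (hits > 0) separated by
#' at most `max_gap_bins` empty bins belong to one window; a run of more than
#' `max_gap_bins` consecutive empty bins terminates the window. A window's
#' span runs from its first to its last expressing bin inclusive; interior
#' empty bins are counted in the span and member list but contribute zero to
#' all criteria. Windows never cross chromosomes.
#'
#' @param bin_stats Output of [compute_bin_stats()], covering whole
#'   chromosomes in order.
#' @param max_gap_bins Largest empty-bin gap bridged within a window
#'   (default 2, i.e. a boundary requires > 2 empty bins).
#' @return A data.frame of windows: `chrom`, `start`, `end` (bp, bin-aligned),
#'   `first_bin`, `last_bin`, `n_bins`, `hits`, `total_length`,
#'   `weighted_coverage`. Ranks are unset (see [score_and_rank()]).
#' @export
merge_windows <- function(bin_stats, max_gap_bins = 2) {
  stop_if_not_scalar_number(max_gap_bins, "max_gap_bins", min = 0)
  out <- list()
  for (chrom in unique(bin_stats$chrom)) {
    cb <- bin_stats[bin_stats$chrom == chrom, , drop = FALSE]
    cb <- cb[order(cb$bin_index), , drop = FALSE]
    runs <- merge_runs(cb$hits > 0L, max_gap_bins)
    for (r in runs) {
      mem <- r[1]:r[2]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start = cb$start[r[1]], end = cb$end[r[2]],
        first_bin = cb$bin_index[r[1]], last_bin = cb$bin_index[r[2]],
        n_bins = length(mem),
        hits = sum(cb$hits[mem]),
        total_length = sum(cb$total_length[mem]),
        weighted_coverage = sum(cb$weighted_coverage[mem]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), first_bin = integer(),
                      last_bin = integer(), n_bins = integer(),
                      hits = integer(), total_length = numeric(),
                      weighted_coverage = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score and rank lncRNA-enrichment windows genome-wide
#'
#' In the default `rank_sum` mode each criterion (hits, total length,
#' weighted coverage) is ranked genome-wide with 1 = largest value and ties
#' sharing the minimum rank of the tied group; the overall score is the sum
#' of the three criterion ranks and the overall rank orders windows by
#' ascending score. Overall-rank ties are broken by larger weighted coverage,
#' then by (chrom, start), so the overall rank is a strict permutation of
#' `1..N`. The `raw_sum` mode instead sums the raw criterion values
#' (incommensurate units; provided as the alternative reading) and ranks by
#' descending raw sum with the same tie-breaks.
#'
#' @param windows Output of [merge_windows()] (at least one window).
#' @param score_mode `"rank_sum"` (default) or `"raw_sum"`.
#' @return The windows data.frame with added columns `rank_hits`,
#'   `rank_length`, `rank_coverage`, `overall_score`, `overall_rank`, and
#'   `n_windows_total`, sorted by `overall_rank`.
#' @export
score_and_rank <- function(windows, score_mode = c("rank_sum", "raw_sum")) {
  score_mode <- match.arg(score_mode)
  if (!nrow(windows)) stop("no windows to rank", call. = FALSE)
  w <- windows
  w$rank_hits <- rank(-w$hits, ties.method = "min")
  w$rank_length <- rank(-w$total_length, ties.method = "min")
  w$rank_coverage <- rank(-w$weighted_coverage, ties.method = "min")
  if (score_mode == "rank_sum") {
    w$overall_score <- w$rank_hits + w$rank_length + w$rank_coverage
    ord <- order(w$overall_score, -w$weighted_coverage, w$chrom, w$start)
  } else {
    w$overall_score <- w$hits + w$total_length + w$weighted_coverage
    ord <- order(-w$overall_score, -w$weighted_coverage, w$chrom, w$start)
  }
  w$overall_rank <- NA_integer_
  w$overall_rank[ord] <- seq_len(nrow(w))
  w$n_windows_total <- nrow(w)
  w <- w[order(w$overall_rank), , drop = FALSE]
  rownames(w) <- NULL
  w
}

#' Report the ranked windows overlapping a locus of interest
#'
#' @param windows Ranked windows (from [score_and_rank()] or an
#'   `lnc_windows` object).
#' @param chrom,start,end The locus interval (bp, 0-based half-open).
#' @return A list with `windows` (overlapping windows sorted by overall
#'   rank), `single_window` (`TRUE` iff exactly one window overlaps the
#'   locus, i.e. the locus is not split across windows and not devoid of
#'   them), `contained` (`TRUE` iff some window's span fully contains the
#'   locus interval), and `locus`.
#'
#' @details `single_window` detects window splitting: a locus whose
#'   expressed content straddles a boundary (a run of more than
#'   `max_gap_bins` empty bins) overlaps two or more windows and gets
#'   `FALSE`; a locus overlapping no window also gets `FALSE`. The stricter
#'   `contained` flag additionally requires the single window's bin-aligned
#'   span to cover the locus ends, which fails whenever the outermost locus
#'   bins happen to hold no transcript even though the locus is unsplit.
#' @export
locate_locus <- function(windows, chrom, start, end) {
  if (inherits(windows, "lnc_windows")) windows <- windows$windows
  if (end <= start) stop("locus must satisfy end > start", call. = FALSE)
  ov <- windows$chrom == chrom & windows$start < end & windows$end > start
  hits <- windows[ov, , drop = FALSE]
  if ("overall_rank" %in% names(hits))
    hits <- hits[order(hits$overall_rank), , drop = FALSE]
  rownames(hits) <- NULL
  contained <- any(hits$start <= start & hits$end >= end)
  list(windows = hits, single_window = nrow(hits) == 1L,
       contained = contained,
       locus = list(chrom = chrom, start = start, end = end))
}

#' Rank 100-kb genome windows by lncRNA enrichment
#'
#' End-to-end wrapper: filter transcripts, bin the genome, merge expressing
#' bins into windows, and rank windows genome-wide by the three enrichment
#' criteria.
#'
#' @inheritParams filter_transcripts
#' @inheritParams compute_bin_stats
#' @inheritParams merge_windows
#' @inheritParams score_and_rank
#' @return An object of class `lnc_windows`: a list with `windows` (ranked),
#'   `bin_stats`, `n_transcripts_in` / `n_transcripts_kept`, and `params`.
#' @export
rank_windows <- function(transcripts, chrom_sizes, bin_size = 100000,
                         max_gap_bins = 2, min_length = 300, min_fpkm = 0.3,
                         known_annotation = NULL,
                         score_mode = c("rank_sum", "raw_sum")) {
  score_mode <- match.arg(score_mode)
  kept <- filter_transcripts(transcripts, min_length, min_fpkm,
                             known_annotation)
  bins <- compute_bin_stats(kept, chrom_sizes, bin_size)
  wins <- merge_windows(bins, max_gap_bins)
  ranked <- if (nrow(wins)) score_and_rank(wins, score_mode) else wins
  structure(list(
    windows = ranked, bin_stats = bins,
    n_transcripts_in = nrow(transcripts), n_transcripts_kept = nrow(kept),
    params = list(bin_size = bin_size, max_gap_bins = max_gap_bins,
                  min_length = min_length, min_fpkm = min_fpkm,
                  score_mode = score_mode)
  ), class = "lnc_windows")
}

#' @export
print.lnc_windows <- function(x, n = 5, ...) {
  cat(sprintf(
    "lncRNA enrichment windows: %d windows from %d/%d transcripts (bin %s bp, gap > %d bins splits)\n",
    nrow(x$windows), x$n_transcripts_kept, x$n_transcripts_in,
    format(x$params$bin_size, scientific = FALSE), x$params$max_gap_bins))
  if (nrow(x$windows)) {
    cat("Top windows by overall rank:\n")
    cols <- c("chrom", "start", "end", "hits", "total_length",
              "weighted_coverage", "overall_score", "overall_rank")
    print(head(x$windows[, cols], n))
  }
  invisible(x)
}

#' @method summary lnc_windows
#' @export
summary.lnc_windows <- function(object, ...) {
  w <- object$windows
  out <- list(
    n_windows = nrow(w),
    n_transcripts_kept = object$n_transcripts_kept,
    hits_total = sum(w$hits),
    span_bp = sum(w$end - w$start),
    top_window = if (nrow(w)) w[1L, ] else NULL
  )
  class(out) <- "summary.lnc_windows"
  out
}

#' @export
print.summary.lnc_windows <- function(x, ...) {
  cat(sprintf("%d windows; %d transcripts assigned; %s bp total window span\n",
              x$n_windows, x$hits_total, format(x$span_bp, big.mark = ",")))
  if (!is.null(x$top_window))
    cat(sprintf("Rank-1 window: %s:%s-%s (hits %d)\n",
                x$top_window$chrom,
                format(x$top_window$start, scientific = FALSE),
                format(x$top_window$end, scientific = FALSE),
                x$top_window$hits))
  invisible(x)
}
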