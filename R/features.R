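#' Classify lncRNAs by exon structure, orientation, and segment proximity
#'
#' Each transcript is called mono- or multi-exonic (multi = >= 2 exons) and
#' sense or antisense relative to a stated reference strand (the coding
#' orientation of the locus under study, e.g. the minus strand for the mouse
#' Igh locus). Transcript spans are related to gene segments by overlap (any
#' shared base) or proximity (no shared base and a gap of at most
#' `proximity_bp`, inclusive at exactly the threshold; adjacency under
#' half-open coordinates is proximity at distance 0).
#'
#' @param transcripts Transcript data.frame (must carry `exon_starts` list
#'   column; see [simulate_transcriptome()]).
#' @param segments Gene-segment data.frame: `segment_id`, `chrom`, `start`,
#'   `end`, `strand`, and logical `used` (see [read_segments_bed()]).
#' @param reference_strand `"+"` or `"-"`: the strand against which sense /
#'   antisense is defined.
#' @param proximity_bp Proximity threshold in bp (default 500, inclusive).
#' @return A data.frame with one row per transcript: `transcript_id`,
#'   `exonic_class` (`"mono"`/`"multi"`), `orientation`
#'   (`"sense"`/`"antisense"`), and list-columns `overlapping_segments`
#'   (segment ids) and `proximal_segments` (named numeric vectors of gap
#'   distances, names = segment ids).
#' @export
classify_features <- function(transcripts, segments,
                              reference_strand = c("-", "+"),
                              proximity_bp = 500) {
  reference_strand <- match.arg(reference_strand)
  check_transcripts(transcripts)
  stop_if_not_scalar_number(proximity_bp, "proximity_bp", min = 0)
  n_exons <- vapply(transcripts$exon_starts, length, integer(1))
  calls <- data.frame(
    transcript_id = transcripts$transcript_id,
    exonic_class = ifelse(n_exons >= 2L, "multi", "mono"),
    orientation = ifelse(transcripts$strand == reference_strand,
                         "sense", "antisense"),
    stringsAsFactors = FALSE
  )
  tx_gr <- GenomicRanges::GRanges(
    transcripts$chrom,
    IRanges::IRanges(transcripts$start + 1L, transcripts$end))
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(segments$start + 1L, segments$end))
  ov <- GenomicRanges::findOverlaps(tx_gr, seg_gr, ignore.strand = TRUE)
  # maxgap = proximity_bp also recovers pairs separated by <= proximity_bp.
  near <- GenomicRanges::findOverlaps(tx_gr, seg_gr, maxgap = proximity_bp,
                                      ignore.strand = TRUE)
  ov_key <- paste(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
  near_key <- paste(S4Vectors::queryHits(near), S4Vectors::subjectHits(near))
  prox <- near[!(near_key %in% ov_key)]
  gap <- GenomicRanges::distance(tx_gr[S4Vectors::queryHits(prox)],
                                 seg_gr[S4Vectors::subjectHits(prox)])
  calls$overlapping_segments <- I(unname(split(
    segments$segment_id[S4Vectors::subjectHits(ov)],
    factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(transcripts))))))
  qh <- S4Vectors::queryHits(prox)
  prox_list <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts)))
    prox_list[[i]] <- stats::setNames(numeric(), character())
  for (k in seq_along(qh)) {
    d <- gap[k]
    names(d) <- segments$segment_id[S4Vectors::subjectHits(prox)[k]]
    prox_list[[qh[k]]] <- c(prox_list[[qh[k]]], d)
  }
  calls$proximal_segments <- I(prox_list)
  calls
}

#' Tabulate the association between segment overlap and recombination usage
#'
#' Builds the 2x2 table of gene segments cross-classified as overlapped by at
#' least one lncRNA (vs not) and used in recombination (vs not), with the
#' sample odds ratio (Haldane-Anscombe 0.5 correction when any cell is zero)
#' and a two-sided Fisher exact p-value. The question this answers: does
#' lncRNA overlap of a V segment predict its usage in recombination?
#'
#' @param calls Output of [classify_features()].
#' @param segments The gene-segment data.frame used for the calls (must carry
#'   logical `used`).
#' @return A list of class `usage_association`: `table` (2x2 matrix, rows
#'   overlapped/not, columns used/not), `odds_ratio`, `fisher_p`.
#' @export
usage_association <- function(calls, segments) {
  if (nrow(segments) < 1L) stop("need at least one segment", call. = FALSE)
  if (!is.logical(segments$used))
    stop("segments$used must be logical", call. = FALSE)
  overlapped_ids <- unique(unlist(calls$overlapping_segments))
  overlapped <- segments$segment_id %in% overlapped_ids
  tab <- matrix(c(
    sum(overlapped & segments$used), sum(overlapped & !segments$used),
    sum(!overlapped & segments$used), sum(!overlapped & !segments$used)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("overlapped", "not_overlapped"),
                  c("used", "not_used")))
  structure(list(
    table = tab,
    odds_ratio = odds_ratio_haldane(tab),
    fisher_p = stats::fisher.test(tab)$p.value
  ), class = "usage_association")
}

# Sample odds ratio with Haldane-Anscombe 0.5 correction if any cell is 0.
odds_ratio_haldane <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' @export
print.usage_association <- function(x, ...) {
  cat("Segment overlap x recombination usage\n")
  print(x$table)
  cat(sprintf("odds ratio %.3f (Haldane-corrected if any zero cell); Fisher exact p = %.4g\n",
              x$odds_ratio, x$fisher_p))
  invisible(x)
}

#' Compare expression between mono- and multi-exonic lncRNAs
#'
#' Rank-based two-sample (Mann-Whitney U) comparison of expression values
#' (TPM) between the two exonic classes: exact enumeration when both groups
#' have at most 20 observations and no ties, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param mono_tpm,multi_tpm Non-empty numeric vectors of expression values.
#' @return A list: `statistic` (U for the mono group), `p_two_sided`,
#'   `median_mono`, `median_multi`.
#' @export
compare_expression <- function(mono_tpm, multi_tpm) {
  if (!length(mono_tpm) || !length(multi_tpm))
    stop("both expression groups must be non-empty", call. = FALSE)
  exact <- length(mono_tpm) <= 20 && length(multi_tpm) <= 20 &&
    !anyDuplicated(c(mono_tpm, multi_tpm))
  wt <- suppressWarnings(stats::wilcox.test(mono_tpm, multi_tpm,
                                            exact = exact))
  list(statistic = unname(wt$statistic),
       p_two_sided = wt$p.value,
       median_mono = median(mono_tpm),
       median_multi = median(multi_tpm))
}
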