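#' Read and write chromosome sizes
#'
#' Two-column whitespace-separated text: chromosome name, length in bp.
#'
#' @param path File path.
#' @return `read_chrom_sizes()`: named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  check_chrom_sizes(stats::setNames(as.numeric(df$length), df$chrom))
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes Named numeric vector.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  check_chrom_sizes(chrom_sizes)
  utils::write.table(
    data.frame(names(chrom_sizes), format(chrom_sizes, scientific = FALSE,
                                          trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read assembled transcripts with expression attributes from GTF
#'
#' Expects transcript and exon features carrying `transcript_id` and an
#' expression attribute (`FPKM` by default; `TPM` read too when present), the
#' layout emitted by transcript assemblers. GTF's 1-based inclusive
#' coordinates are converted to the package's 0-based half-open convention.
#'
#' @param path GTF file path.
#' @param expression_attr Attribute holding the expression value used as
#'   FPKM (default `"FPKM"`; assemblers sometimes emit `"cov"`).
#' @return A transcript data.frame (see [simulate_transcriptome()] for the
#'   column contract).
#' @export
read_transcripts_gtf <- function(path, expression_attr = "FPKM") {
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  is_tx <- mc$type == "transcript"
  is_ex <- mc$type == "exon"
  if (!any(is_tx)) stop("no transcript features in ", path, call. = FALSE)
  if (!expression_attr %in% names(mc))
    stop("GTF lacks expression attribute '", expression_attr, "'",
         call. = FALSE)
  tx <- gr[is_tx]
  txm <- S4Vectors::mcols(tx)
  ex <- gr[is_ex]
  exm <- S4Vectors::mcols(ex)
  ex_by_tx <- split(ex, exm$transcript_id)
  ids <- txm$transcript_id
  exon_starts <- vector("list", length(tx))
  exon_ends <- vector("list", length(tx))
  for (i in seq_along(tx)) {
    e <- ex_by_tx[[ids[i]]]
    if (is.null(e) || !length(e)) {
      exon_starts[[i]] <- GenomicRanges::start(tx)[i] - 1L
      exon_ends[[i]] <- GenomicRanges::end(tx)[i]
    } else {
      o <- order(GenomicRanges::start(e))
      exon_starts[[i]] <- GenomicRanges::start(e)[o] - 1L
      exon_ends[[i]] <- GenomicRanges::end(e)[o]
    }
  }
  out <- data.frame(
    transcript_id = ids,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    start = GenomicRanges::start(tx) - 1L,
    end = GenomicRanges::end(tx),
    strand = ifelse(as.character(GenomicRanges::strand(tx)) == "-", "-", "+"),
    exon_starts = I(exon_starts), exon_ends = I(exon_ends),
    mature_length = vapply(seq_along(tx), function(i)
      sum(exon_ends[[i]] - exon_starts[[i]]), numeric(1)),
    fpkm = as.numeric(txm[[expression_attr]]),
    stringsAsFactors = FALSE
  )
  if ("TPM" %in% names(txm)) out$tpm <- as.numeric(txm$TPM)
  out
}

#' @rdname read_transcripts_gtf
#' @param transcripts Transcript data.frame.
#' @export
write_transcripts_gtf <- function(transcripts, path) {
  check_transcripts(transcripts)
  n_ex <- vapply(transcripts$exon_starts, length, integer(1))
  tx_gr <- GenomicRanges::GRanges(
    transcripts$chrom,
    IRanges::IRanges(transcripts$start + 1L, transcripts$end),
    strand = transcripts$strand,
    type = "transcript",
    transcript_id = transcripts$transcript_id,
    FPKM = sprintf("%.6g", transcripts$fpkm),
    TPM = sprintf("%.6g", if ("tpm" %in% names(transcripts))
      transcripts$tpm else transcripts$fpkm))
  ex_gr <- GenomicRanges::GRanges(
    rep(transcripts$chrom, n_ex),
    IRanges::IRanges(unlist(transcripts$exon_starts) + 1L,
                     unlist(transcripts$exon_ends)),
    strand = rep(transcripts$strand, n_ex),
    type = "exon",
    transcript_id = rep(transcripts$transcript_id, n_ex),
    FPKM = rep(sprintf("%.6g", transcripts$fpkm), n_ex),
    TPM = rep(sprintf("%.6g", if ("tpm" %in% names(transcripts))
      transcripts$tpm else transcripts$fpkm), n_ex))
  rtracklayer::export(c(tx_gr, ex_gr), path, format = "gtf")
  invisible(path)
}

#' Read and write gene segments as BED6+1
#'
#' BED6 plus a seventh column carrying the recombination-usage flag (0/1).
#'
#' @param path File path.
#' @return `read_segments_bed()`: data.frame with `segment_id`, `chrom`,
#'   `start`, `end`, `strand`, `used`.
#' @export
read_segments_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 7)
    stop("expected BED6+1 (usage flag in column 7)", call. = FALSE)
  data.frame(segment_id = df[[4]], chrom = df[[1]], start = df[[2]],
             end = df[[3]], strand = df[[6]], used = df[[7]] != 0,
             stringsAsFactors = FALSE)
}

#' @rdname read_segments_bed
#' @param segments Segment data.frame.
#' @export
write_segments_bed <- function(segments, path) {
  utils::write.table(
    data.frame(segments$chrom, segments$start, segments$end,
               segments$segment_id, 0L, segments$strand,
               as.integer(segments$used)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write contact matrices as text dumps
#'
#' Two dialects: a dense TSV (N rows by N columns) or a sparse 3-column
#' `bin_i bin_j count` dump with 0-based indices relative to the region
#' start. Either is accompanied by a bin table (`chrom`, `start`, `end`,
#' `bin_index`) defining the grid.
#'
#' @param path Matrix file path.
#' @param bins_path Bin-table TSV path.
#' @param sparse Logical: write/read the sparse dialect.
#' @return `read_contact_matrix()`: a [contact_matrix()].
#' @export
read_contact_matrix <- function(path, bins_path, sparse = FALSE) {
  bins <- utils::read.table(bins_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  n <- nrow(bins)
  bin_size <- bins$end[1] - bins$start[1]
  if (sparse) {
    sp <- utils::read.table(path, header = FALSE, sep = "\t",
                            col.names = c("i", "j", "count"))
    counts <- matrix(0, n, n)
    counts[cbind(sp$i + 1L, sp$j + 1L)] <- sp$count
    counts[cbind(sp$j + 1L, sp$i + 1L)] <- sp$count
  } else {
    counts <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  }
  contact_matrix(counts, chrom = bins$chrom[1], start = bins$start[1],
                 bin_size = bin_size)
}

#' @rdname read_contact_matrix
#' @param m A `contact_matrix`.
#' @export
write_contact_matrix <- function(m, path, bins_path, sparse = FALSE) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- nrow(m$counts)
  bins <- data.frame(
    chrom = m$chrom,
    start = m$start + (seq_len(n) - 1L) * m$bin_size,
    end = m$start + seq_len(n) * m$bin_size,
    bin_index = seq_len(n) - 1L)
  utils::write.table(bins, bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (sparse) {
    ut <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
                arr.ind = TRUE)
    sp <- data.frame(i = ut[, 1L] - 1L, j = ut[, 2L] - 1L,
                     count = m$counts[ut])
    utils::write.table(sp, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(m$counts, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read and write ENCODE narrowPeak peak calls
#'
#' The score used downstream is the caller's -log10(p-value), carried in the
#' `pValue` column (column 8) of the narrowPeak file.
#'
#' @param path File path.
#' @return `read_narrowpeak()`: data.frame with `chrom`, `start`, `end`,
#'   `name`, `score_raw`.
#' @export
read_narrowpeak <- function(path) {
  gr <- rtracklayer::import(path, format = "narrowPeak")
  mc <- S4Vectors::mcols(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(mc$name)) mc$name else
      sprintf("peak%d", seq_along(gr)),
    score_raw = as.numeric(mc$pValue),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_narrowpeak
#' @param peaks Peak data.frame (with `score_raw`; `spm` written into the
#'   signalValue column when present).
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(
    peaks$chrom, peaks$start, peaks$end, peaks$name,
    pmin(1000L, as.integer(round(peaks$score_raw * 10))), ".",
    if ("spm" %in% names(peaks)) sprintf("%.6g", peaks$spm) else "0",
    sprintf("%.6g", peaks$score_raw), "-1", "-1")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a virtual-4C profile as bedGraph
#'
#' @param profile A `virtual4c_profile`.
#' @param path Output path.
#' @export
write_v4c_bedgraph <- function(profile, path) {
  n <- length(profile$values)
  ok <- !is.na(profile$values)
  df <- data.frame(
    chrom = profile$chrom,
    start = profile$start + (seq_len(n) - 1L) * profile$bin_size,
    end = profile$start + seq_len(n) * profile$bin_size,
    value = profile$values)[ok, , drop = FALSE]
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               score = df$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write ranked windows as TSV and BED
#'
#' @param x An `lnc_windows` object or ranked window data.frame.
#' @param tsv_path,bed_path Output paths (`NULL` to skip one).
#' @export
write_windows <- function(x, tsv_path = NULL, bed_path = NULL) {
  w <- if (inherits(x, "lnc_windows")) x$windows else x
  if (!is.null(tsv_path))
    utils::write.table(w, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bed_path) && nrow(w)) {
    bed <- data.frame(
      w$chrom, format(w$start, scientific = FALSE, trim = TRUE),
      format(w$end, scientific = FALSE, trim = TRUE),
      sprintf("window_rank%04d", w$overall_rank),
      pmin(1000L, as.integer(w$overall_score)), ".")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(x)
}
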