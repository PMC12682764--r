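#' Configuration for the synthetic transcriptome generator
#'
#' Defines the genome, the uniform background transcript density, and an
#' optional planted locus in which both transcript density and expression are
#' multiplied. The defaults describe the simulation conditions used throughout
#' the package's validation: a small multi-chromosome genome with a sparse
#' lncRNA-like background and one strongly enriched 3-Mb locus, emulating a
#' recombination-poised antigen-receptor locus standing out against the
#' genomic background.
#'
#' @param chrom_sizes Named numeric vector, chromosome name -> length in bp.
#' @param background_density Background transcripts per Mb (>= 0).
#' @param planted_locus `NULL`, or a list/vector with `chrom`, `start`, `end`
#'   (0-based half-open) naming the enriched locus.
#' @param planted_multiplier Density fold-increase inside the planted locus
#'   (>= 1).
#' @param planted_expr_multiplier Expression fold-increase inside the planted
#'   locus (>= 1).
#' @param length_meanlog,length_sdlog Log-normal parameters for mature
#'   transcript length in bp (floored at 50 bp).
#' @param expr_meanlog,expr_sdlog Log-normal parameters for expression (FPKM).
#' @param multi_exon_prob Probability a transcript has >= 2 exons.
#' @param antisense_prob Probability of minus-strand assignment.
#' @param seed Integer seed; the generator is deterministic given the config.
#' @param max_expected Guard: error if the expected total transcript count
#'   exceeds this cap.
#'
#' @return A validated list of class `transcriptome_sim_config`.
#' @export
transcriptome_sim_config <- function(chrom_sizes,
                                     background_density = 0.5,
                                     planted_locus = NULL,
                                     planted_multiplier = 40,
                                     planted_expr_multiplier = 5,
                                     length_meanlog = log(1500),
                                     length_sdlog = 0.8,
                                     expr_meanlog = 0,
                                     expr_sdlog = 1,
                                     multi_exon_prob = 0.1,
                                     antisense_prob = 0.5,
                                     seed = 1L,
                                     max_expected = 1e6) {
  check_chrom_sizes(chrom_sizes)
  stop_if_not_scalar_number(background_density, "background_density", min = 0)
  stop_if_not_scalar_number(planted_multiplier, "planted_multiplier", min = 1)
  stop_if_not_scalar_number(planted_expr_multiplier, "planted_expr_multiplier",
                            min = 1)
  stop_if_not_prob(multi_exon_prob, "multi_exon_prob")
  stop_if_not_prob(antisense_prob, "antisense_prob")
  stop_if_not_scalar_number(max_expected, "max_expected", min = 0,
                            allow_min = FALSE)
  if (!is.null(planted_locus)) {
    planted_locus <- as.list(planted_locus)
    pl <- planted_locus
    if (!all(c("chrom", "start", "end") %in% names(pl)))
      stop("'planted_locus' needs chrom, start, end", call. = FALSE)
    pl$start <- as.numeric(pl$start); pl$end <- as.numeric(pl$end)
    if (!pl$chrom %in% names(chrom_sizes))
      stop("planted locus chromosome '", pl$chrom, "' not in chrom_sizes",
           call. = FALSE)
    if (pl$start < 0 || pl$end > chrom_sizes[[pl$chrom]] || pl$end <= pl$start)
      stop("planted locus must lie within its chromosome", call. = FALSE)
    planted_locus <- pl
  }
  structure(list(
    chrom_sizes = chrom_sizes, background_density = background_density,
    planted_locus = planted_locus, planted_multiplier = planted_multiplier,
    planted_expr_multiplier = planted_expr_multiplier,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
    multi_exon_prob = multi_exon_prob, antisense_prob = antisense_prob,
    seed = as.integer(seed), max_expected = max_expected
  ), class = "transcriptome_sim_config")
}

# One homogeneous region: Poisson transcript count, uniform placement.
simulate_region <- function(chrom, region_start, region_end, density_per_mb,
                            expr_mult, cfg, origin) {
  len <- region_end - region_start
  n <- rpois(1L, density_per_mb * len / 1e6)
  if (n == 0L) return(NULL)
  mature <- pmax(50, round(rlnorm(n, cfg$length_meanlog, cfg$length_sdlog)))
  n_exons <- ifelse(runif(n) < cfg$multi_exon_prob,
                    sample(2:6, n, replace = TRUE), 1L)
  # Genomic span: mature length for mono-exonic; introns inflate multi-exonic
  # spans by a uniform 1-5x factor.
  span <- ifelse(n_exons == 1L, mature, round(mature * runif(n, 1, 5)))
  # A k-exon transcript needs at least k-1 bp of intron.
  span <- pmax(span, mature + (n_exons - 1L))
  span <- pmin(span, len)  # cannot exceed the region
  mature <- pmin(mature, span - (n_exons - 1L))
  start <- region_start + floor(runif(n) * pmax(1, len - span))
  end <- start + span
  strand <- ifelse(runif(n) < cfg$antisense_prob, "-", "+")
  fpkm <- rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog) * expr_mult
  blocks <- make_exon_blocks(start, span, mature, n_exons)
  data.frame(
    transcript_id = NA_character_, chrom = chrom, start = start, end = end,
    strand = strand,
    exon_starts = I(blocks$starts), exon_ends = I(blocks$ends),
    mature_length = vapply(seq_len(n), function(i)
      sum(blocks$ends[[i]] - blocks$starts[[i]]), numeric(1)),
    fpkm = fpkm, origin = origin,
    stringsAsFactors = FALSE
  )
}

# Partition `mature` bp of exon among `k` exons and `span - mature` bp of
# intron among k-1 gaps, anchored at the transcript span ends.
make_exon_blocks <- function(start, span, mature, n_exons) {
  n <- length(start)
  starts <- vector("list", n); ends <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_exons[i]
    if (k == 1L) {
      starts[[i]] <- start[i]
      ends[[i]] <- start[i] + mature[i]
      next
    }
    exon_len <- random_composition(mature[i], k)
    intron_len <- random_composition(span[i] - mature[i], k - 1L)
    s <- numeric(k); e <- numeric(k)
    pos <- start[i]
    for (j in seq_len(k)) {
      s[j] <- pos
      e[j] <- pos + exon_len[j]
      pos <- e[j] + if (j < k) intron_len[j] else 0
    }
    # Anchor last exon end at span end (rounding slack goes into last intron).
    shift <- (start[i] + span[i]) - e[k]
    s[k] <- s[k] + shift; e[k] <- e[k] + shift
    starts[[i]] <- s; ends[[i]] <- e
  }
  list(starts = starts, ends = ends)
}

# Split `total` into `k` positive integer parts, uniformly at random.
random_composition <- function(total, k) {
  total <- max(total, k)
  if (k == 1L) return(total)
  cuts <- sort(sample.int(total - 1L, k - 1L))
  diff(c(0L, cuts, total))
}

#' Simulate a transcriptome with a planted enriched locus
#'
#' Draws background transcripts at uniform genomic density (Poisson counts,
#' uniform placement, log-normal mature lengths and FPKM) and, inside the
#' planted locus, multiplies both density and expression. TPM is derived from
#' FPKM by per-run renormalization to one million.
#'
#' @param cfg A [transcriptome_sim_config()].
#' @return A data.frame of transcript records (one row per transcript) with
#'   columns `transcript_id`, `chrom`, `start`, `end`, `strand`,
#'   `exon_starts`/`exon_ends` (list-columns of absolute coordinates),
#'   `mature_length`, `fpkm`, `tpm` and `origin`
#'   (`"background"`/`"planted"`). The config is attached as attribute
#'   `"sim_config"`.
#' @export
simulate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "transcriptome_sim_config"))
  exp_total <- cfg$background_density * sum(cfg$chrom_sizes) / 1e6
  if (!is.null(cfg$planted_locus)) {
    pl_len <- (cfg$planted_locus$end - cfg$planted_locus$start) / 1e6
    exp_total <- exp_total +
      cfg$background_density * (cfg$planted_multiplier - 1) * pl_len
  }
  if (exp_total > cfg$max_expected)
    stop("expected transcript count ", round(exp_total),
         " exceeds max_expected (", cfg$max_expected, ")", call. = FALSE)

  with_seed(child_seed(cfg$seed, 1L), {
    out <- list()
    for (chrom in names(cfg$chrom_sizes)) {
      L <- cfg$chrom_sizes[[chrom]]
      pl <- cfg$planted_locus
      if (!is.null(pl) && pl$chrom == chrom) {
        out[[length(out) + 1L]] <- simulate_region(
          chrom, 0, pl$start, cfg$background_density, 1, cfg, "background")
        out[[length(out) + 1L]] <- simulate_region(
          chrom, pl$start, pl$end,
          cfg$background_density * cfg$planted_multiplier,
          cfg$planted_expr_multiplier, cfg, "planted")
        out[[length(out) + 1L]] <- simulate_region(
          chrom, pl$end, L, cfg$background_density, 1, cfg, "background")
      } else {
        out[[length(out) + 1L]] <- simulate_region(
          chrom, 0, L, cfg$background_density, 1, cfg, "background")
      }
    }
    out <- out[!vapply(out, is.null, logical(1))]
    tx <- if (length(out)) do.call(rbind, out) else
      data.frame(transcript_id = character(), chrom = character(),
                 start = numeric(), end = numeric(), strand = character(),
                 exon_starts = I(list()), exon_ends = I(list()),
                 mature_length = numeric(), fpkm = numeric(),
                 origin = character(), stringsAsFactors = FALSE)
    if (nrow(tx)) {
      tx$transcript_id <- sprintf("SIMT%05d", seq_len(nrow(tx)))
      tx$tpm <- tx$fpkm / sum(tx$fpkm) * 1e6
    } else tx$tpm <- numeric()
    rownames(tx) <- NULL
    attr(tx, "sim_config") <- cfg
    tx
  })
}

#' Simulate gene-segment annotations within a locus
#'
#' Places `n_segments` short, non-overlapping gene segments (V-segment-like)
#' uniformly within an interval, each flagged as used or unused in
#' recombination with probability `used_prob`.
#'
#' @param chrom,start,end Interval to populate (0-based half-open).
#' @param n_segments Number of segments.
#' @param segment_width Width of each segment in bp.
#' @param used_prob Probability a segment carries the usage flag.
#' @param strand Strand assigned to every segment (gene segments of one locus
#'   share the coding orientation).
#' @param seed Integer seed.
#' @return A data.frame with columns `segment_id`, `chrom`, `start`, `end`,
#'   `strand`, `used` (logical).
#' @export
simulate_gene_segments <- function(chrom, start, end, n_segments = 100,
                                   segment_width = 500, used_prob = 0.8,
                                   strand = "-", seed = 1L) {
  stop_if_not_prob(used_prob, "used_prob")
  slot <- floor((end - start) / n_segments)
  if (slot <= segment_width)
    stop("interval too small for ", n_segments, " non-overlapping segments",
         call. = FALSE)
  with_seed(child_seed(seed, 2L), {
    offs <- floor(runif(n_segments) * (slot - segment_width))
    s <- start + (seq_len(n_segments) - 1L) * slot + offs
    data.frame(
      segment_id = sprintf("SEG%03d", seq_len(n_segments)),
      chrom = chrom, start = s, end = s + segment_width, strand = strand,
      used = runif(n_segments) < used_prob,
      stringsAsFactors = FALSE
    )
  })
}
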