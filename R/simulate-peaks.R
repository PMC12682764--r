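#' Configuration for the synthetic multi-sample peak generator
#'
#' Emulates replicate ATAC-seq peak sets: a set of true peaks shared across
#' samples (each present in a given sample with probability
#' `1 - dropout_prob`) plus sample-specific noise peaks. Peak scores are
#' -log10(p)-like gamma draws. Noise intervals are kept disjoint from true
#' peaks and from each other across all samples, so ground truth for
#' reproducibility filtering is unambiguous.
#'
#' @param n_true_peaks Number of shared true peaks.
#' @param n_samples Number of samples (>= 2).
#' @param noise_peaks_per_sample Sample-specific noise peaks per sample.
#' @param score_shape,score_scale Gamma parameters for the -log10(p) scores.
#' @param dropout_prob Probability a true peak is missing from a sample.
#' @param jitter_bp Maximum absolute start/end jitter applied per sample to a
#'   true peak (default 0: identical intervals across samples).
#' @param peak_width Peak width in bp.
#' @param chrom,chrom_length Chromosome the peaks are placed on.
#' @param seed Integer seed.
#' @return A validated list of class `peak_sim_config`.
#' @export
peak_sim_config <- function(n_true_peaks = 100, n_samples = 3,
                            noise_peaks_per_sample = 50,
                            score_shape = 2, score_scale = 10,
                            dropout_prob = 0.2, jitter_bp = 0,
                            peak_width = 400, chrom = "chrSim",
                            chrom_length = NULL, seed = 1L) {
  stop_if_not_scalar_number(n_true_peaks, "n_true_peaks", min = 0)
  stop_if_not_scalar_number(n_samples, "n_samples", min = 2)
  stop_if_not_scalar_number(noise_peaks_per_sample, "noise_peaks_per_sample",
                            min = 0)
  stop_if_not_prob(dropout_prob, "dropout_prob")
  stop_if_not_scalar_number(jitter_bp, "jitter_bp", min = 0)
  n_slots <- n_true_peaks + n_samples * noise_peaks_per_sample
  if (is.null(chrom_length)) chrom_length <- (n_slots + 1) * peak_width * 4
  if (chrom_length < n_slots * peak_width * 2)
    stop("chrom_length too small for the requested number of disjoint peaks",
         call. = FALSE)
  structure(list(
    n_true_peaks = as.integer(n_true_peaks), n_samples = as.integer(n_samples),
    noise_peaks_per_sample = as.integer(noise_peaks_per_sample),
    score_shape = score_shape, score_scale = score_scale,
    dropout_prob = dropout_prob, jitter_bp = jitter_bp,
    peak_width = as.integer(peak_width), chrom = chrom,
    chrom_length = chrom_length, seed = as.integer(seed)
  ), class = "peak_sim_config")
}

#' Simulate replicate peak sets with shared true peaks
#'
#' @param cfg A [peak_sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{samples}{Named list of per-sample data.frames with columns
#'       `chrom`, `start`, `end`, `name`, `score_raw` (-log10 p) and
#'       `truth` (`"true"`/`"noise"`).}
#'     \item{manifest}{Ground-truth data.frame: one row per (peak, sample)
#'       occurrence plus `type` and `true_id`, and per-true-peak presence
#'       counts in `n_samples_present`.}
#'   }
#' @export
simulate_peak_samples <- function(cfg) {
  stopifnot(inherits(cfg, "peak_sim_config"))
  with_seed(child_seed(cfg$seed, 4L), {
    n_slots <- cfg$n_true_peaks + cfg$n_samples * cfg$noise_peaks_per_sample
    # Disjoint slots across the chromosome; one interval per slot.
    slot_width <- floor(cfg$chrom_length / max(n_slots, 1L))
    jitter_room <- slot_width - cfg$peak_width - 2L * cfg$jitter_bp
    if (n_slots > 0L && jitter_room < 1L)
      stop("peaks (with jitter) do not fit in disjoint slots", call. = FALSE)
    slot_order <- if (n_slots) sample.int(n_slots) else integer()
    slot_start <- function(k) {
      (k - 1L) * slot_width + cfg$jitter_bp +
        floor(runif(length(k)) * jitter_room)
    }
    true_starts <- slot_start(slot_order[seq_len(cfg$n_true_peaks)])
    noise_slots <- slot_order[-seq_len(cfg$n_true_peaks)]

    samples <- vector("list", cfg$n_samples)
    names(samples) <- sprintf("sample%02d", seq_len(cfg$n_samples))
    manifest <- list()
    present <- matrix(FALSE, cfg$n_true_peaks, cfg$n_samples)
    for (s in seq_len(cfg$n_samples)) {
      keep <- runif(cfg$n_true_peaks) >= cfg$dropout_prob
      present[, s] <- keep
      jit <- function(n) {
        if (cfg$jitter_bp == 0) rep(0L, n) else
          sample(seq(-cfg$jitter_bp, cfg$jitter_bp), n, replace = TRUE)
      }
      ts <- true_starts[keep] + jit(sum(keep))
      true_df <- data.frame(
        chrom = rep(cfg$chrom, sum(keep)), start = ts,
        end = ts + cfg$peak_width,
        name = sprintf("true%04d_s%02d", which(keep), s),
        score_raw = rgamma(sum(keep), cfg$score_shape,
                           scale = cfg$score_scale),
        truth = rep("true", sum(keep)),
        true_id = sprintf("true%04d", which(keep)),
        stringsAsFactors = FALSE
      )
      idx <- noise_slots[(s - 1L) * cfg$noise_peaks_per_sample +
                           seq_len(cfg$noise_peaks_per_sample)]
      ns <- slot_start(idx)
      nn <- cfg$noise_peaks_per_sample
      noise_df <- data.frame(
        chrom = rep(cfg$chrom, nn), start = ns, end = ns + cfg$peak_width,
        name = sprintf("noise_s%02d_%04d", s, seq_len(nn)),
        score_raw = rgamma(nn, cfg$score_shape, scale = cfg$score_scale),
        truth = rep("noise", nn), true_id = rep(NA_character_, nn),
        stringsAsFactors = FALSE
      )
      df <- rbind(true_df, noise_df)
      df <- df[order(df$start), , drop = FALSE]
      rownames(df) <- NULL
      manifest[[s]] <- cbind(df, sample_id = names(samples)[s])
      samples[[s]] <- df[, c("chrom", "start", "end", "name", "score_raw",
                             "truth")]
    }
    manifest <- do.call(rbind, manifest)
    rownames(manifest) <- NULL
    true_summary <- data.frame(
      true_id = sprintf("true%04d", seq_len(cfg$n_true_peaks)),
      chrom = cfg$chrom, start = true_starts,
      end = true_starts + cfg$peak_width,
      n_samples_present = rowSums(present),
      stringsAsFactors = FALSE
    )
    list(samples = samples, manifest = manifest,
         true_peaks = true_summary, config = cfg)
  })
}
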