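#' Assemble a pipeline run configuration
#'
#' Collects stage toggles, stage parameters, input paths and the master seed
#' into a single validated object. Configurations can be read from a YAML
#' file; explicit arguments override file values, which override defaults.
#'
#' @param config `NULL`, a YAML file path, or a named list with any of the
#'   elements `stages`, `seed`, `out_dir`, `locus`, `transcriptome`,
#'   `segments`, `contacts`, `peaks`, `inputs`, `params`.
#' @param ... Named overrides applied on top of `config`.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(config = NULL, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  overrides <- list(...)
  config[names(overrides)] <- overrides
  defaults <- list(
    stages = c("simulate", "windows", "features", "v4c", "atac"),
    seed = 1L,
    out_dir = tempfile("lociscape_run_"),
    locus = NULL,
    transcriptome = list(), segments = list(), contacts = list(),
    peaks = list(), inputs = list(),
    params = list()
  )
  cfg <- utils::modifyList(defaults, config)
  default_params <- list(
    bin_size = 100000, max_gap_bins = 2, min_length = 300, min_fpkm = 0.3,
    score_mode = "rank_sum", proximity_bp = 500, reference_strand = "-",
    fraction = 0.15, scc_threshold = 0.9, min_samples = 2, min_spm = 2,
    viewpoint = NULL, window_bp = 30000
  )
  cfg$params <- utils::modifyList(default_params, cfg$params)
  bad <- setdiff(cfg$stages, c("simulate", "windows", "features", "v4c",
                               "atac"))
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

pipeline_log <- function(con, ...) {
  msg <- sprintf(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

require_input <- function(path, what) {
  if (is.null(path))
    stop("no simulated data in this run and no '", what,
         "' input path configured", call. = FALSE)
  if (!file.exists(path))
    stop("input file for '", what, "' does not exist: ", path, call. = FALSE)
  path
}

manifest_row <- function(stage, files, params) {
  files <- files[file.exists(files)]
  data.frame(
    stage = stage,
    file = if (length(files)) basename(files) else NA_character_,
    md5 = if (length(files)) unname(tools::md5sum(files)) else NA_character_,
    params = paste(names(params), vapply(params, function(p)
      paste(format(p), collapse = ","), character(1)),
      sep = "=", collapse = "; "),
    stringsAsFactors = FALSE
  )
}

#' Run the full synthetic-to-report analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate (transcriptome,
#' gene segments, replicate contact matrices, replicate peak sets), window
#' ranking, lncRNA feature classification, virtual-4C interaction calling,
#' and ATAC SPM normalization/filtering. Each stage writes its outputs under
#' `out_dir` plus a manifest of file checksums and parameters; a combined
#' report relates the designated locus's window rank, feature tallies, and
#' replicate-intersected interaction calls. A stage failure aborts the run
#' with the stage name and leaves a `FAILED` marker; outputs already written
#' are retained.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @return Invisibly, a list with the per-stage results and the report path.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(cfg$out_dir, "run.log"), open = "wt")
  on.exit(close(log_con))
  pipeline_log(log_con, "stages: %s; seed: %d",
               paste(cfg$stages, collapse = ", "), as.integer(cfg$seed))
  for (p in names(cfg$params))
    pipeline_log(log_con, "param %s = %s", p,
                 paste(format(cfg$params[[p]]), collapse = ","))

  results <- list()
  manifest <- list()
  report <- character()
  fail <- function(stage, err) {
    writeLines(paste("FAILED at stage:", stage),
               file.path(cfg$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(err), call. = FALSE)
  }

  # --- simulate ------------------------------------------------------------
  if ("simulate" %in% cfg$stages) {
    res <- tryCatch({
      tcfg <- do.call(transcriptome_sim_config, utils::modifyList(list(
        chrom_sizes = stats::setNames(rep(5e7, 5), paste0("chr", 1:5)),
        planted_locus = list(chrom = "chr3", start = 2e7, end = 2.3e7),
        seed = cfg$seed), cfg$transcriptome))
      tx <- simulate_transcriptome(tcfg)
      pl <- tcfg$planted_locus
      seg <- if (!is.null(pl))
        do.call(simulate_gene_segments, utils::modifyList(list(
          chrom = pl$chrom, start = pl$start, end = pl$end,
          seed = cfg$seed), cfg$segments)) else NULL
      ccfg1 <- do.call(contact_sim_config, utils::modifyList(
        list(seed = cfg$seed), cfg$contacts))
      ccfg2 <- do.call(contact_sim_config, utils::modifyList(
        list(seed = cfg$seed + 1000L), cfg$contacts))
      reps <- list(simulate_contacts(ccfg1), simulate_contacts(ccfg2))
      pcfg <- do.call(peak_sim_config, utils::modifyList(
        list(seed = cfg$seed), cfg$peaks))
      pk <- simulate_peak_samples(pcfg)
      gtf <- file.path(cfg$out_dir, "transcripts.gtf")
      write_transcripts_gtf(tx, gtf)
      cs_path <- file.path(cfg$out_dir, "chrom.sizes")
      write_chrom_sizes(tcfg$chrom_sizes, cs_path)
      if (!is.null(seg))
        write_segments_bed(seg, file.path(cfg$out_dir, "segments.bed"))
      for (r in 1:2)
        write_contact_matrix(reps[[r]],
                             file.path(cfg$out_dir,
                                       sprintf("contacts_rep%d.tsv", r)),
                             file.path(cfg$out_dir, "contact_bins.tsv"))
      for (s in names(pk$samples))
        write_narrowpeak(pk$samples[[s]],
                         file.path(cfg$out_dir,
                                   paste0(s, ".narrowPeak")))
      utils::write.table(pk$manifest,
                         file.path(cfg$out_dir, "peak_truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (is.null(cfg$locus) && !is.null(pl)) cfg$locus <- pl
      list(transcripts = tx, segments = seg, contact_reps = reps,
           peaks = pk, chrom_sizes = tcfg$chrom_sizes,
           transcriptome_cfg = tcfg)
    }, error = function(e) fail("simulate", e))
    manifest[[length(manifest) + 1L]] <- manifest_row(
      "simulate", file.path(cfg$out_dir,
                            c("transcripts.gtf", "chrom.sizes",
                              "segments.bed", "contacts_rep1.tsv",
                              "contacts_rep2.tsv")),
      list(seed = cfg$seed))
    results$simulate <- res
    pipeline_log(log_con, "simulate: %d transcripts, %d segments",
                 nrow(res$transcripts),
                 if (is.null(res$segments)) 0L else nrow(res$segments))
  }

  # --- windows -------------------------------------------------------------
  if ("windows" %in% cfg$stages) {
    res <- tryCatch({
      tx <- if (!is.null(results$simulate))
        results$simulate$transcripts else
          read_transcripts_gtf(require_input(cfg$inputs$gtf, "gtf"))
      cs <- if (!is.null(results$simulate))
        results$simulate$chrom_sizes else
          read_chrom_sizes(require_input(cfg$inputs$chrom_sizes, "chrom_sizes"))
      lw <- rank_windows(tx, cs, bin_size = cfg$params$bin_size,
                         max_gap_bins = cfg$params$max_gap_bins,
                         min_length = cfg$params$min_length,
                         min_fpkm = cfg$params$min_fpkm,
                         score_mode = cfg$params$score_mode)
      write_windows(lw, tsv_path = file.path(cfg$out_dir, "windows.tsv"),
                    bed_path = file.path(cfg$out_dir, "windows.bed"))
      lw
    }, error = function(e) fail("windows", e))
    manifest[[length(manifest) + 1L]] <- manifest_row(
      "windows", file.path(cfg$out_dir, c("windows.tsv", "windows.bed")),
      cfg$params[c("bin_size", "max_gap_bins", "min_length", "min_fpkm",
                   "score_mode")])
    results$windows <- res
    pipeline_log(log_con, "windows: %d ranked windows", nrow(res$windows))
    if (!is.null(cfg$locus)) {
      loc <- locate_locus(res, cfg$locus$chrom, cfg$locus$start,
                          cfg$locus$end)
      results$locus_report <- loc
      report <- c(report, "## Locus window rank", sprintf(
        "Locus %s:%s-%s: best overlapping window rank %s of %d; single window: %s",
        cfg$locus$chrom, format(cfg$locus$start, scientific = FALSE),
        format(cfg$locus$end, scientific = FALSE),
        if (nrow(loc$windows)) loc$windows$overall_rank[1L] else "none",
        nrow(res$windows), loc$single_window), "")
    }
  }

  # --- features ------------------------------------------------------------
  if ("features" %in% cfg$stages) {
    res <- tryCatch({
      tx <- if (!is.null(results$simulate))
        results$simulate$transcripts else
          read_transcripts_gtf(require_input(cfg$inputs$gtf, "gtf"))
      seg <- if (!is.null(results$simulate))
        results$simulate$segments else
          read_segments_bed(require_input(cfg$inputs$segments, "segments"))
      tx <- filter_transcripts(tx, cfg$params$min_length, cfg$params$min_fpkm)
      calls <- classify_features(tx, seg,
                                 reference_strand = cfg$params$reference_strand,
                                 proximity_bp = cfg$params$proximity_bp)
      assoc <- usage_association(calls, seg)
      expr_col <- if ("tpm" %in% names(tx)) tx$tpm else tx$fpkm
      mono <- expr_col[calls$exonic_class == "mono"]
      multi <- expr_col[calls$exonic_class == "multi"]
      cmp <- if (length(mono) && length(multi))
        compare_expression(mono, multi) else NULL
      ft <- calls
      ft$n_overlapping <- vapply(ft$overlapping_segments, length, integer(1))
      ft$n_proximal <- vapply(ft$proximal_segments, length, integer(1))
      utils::write.table(
        ft[, c("transcript_id", "exonic_class", "orientation",
               "n_overlapping", "n_proximal")],
        file.path(cfg$out_dir, "features.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      list(calls = calls, association = assoc, expression = cmp)
    }, error = function(e) fail("features", e))
    manifest[[length(manifest) + 1L]] <- manifest_row(
      "features", file.path(cfg$out_dir, "features.tsv"),
      cfg$params[c("proximity_bp", "reference_strand")])
    results$features <- res
    tal <- table(res$calls$exonic_class)
    ori <- table(res$calls$orientation)
    report <- c(report, "## lncRNA features", sprintf(
      "mono-exonic: %d; multi-exonic: %d; sense: %d; antisense: %d",
      if ("mono" %in% names(tal)) tal[["mono"]] else 0L,
      if ("multi" %in% names(tal)) tal[["multi"]] else 0L,
      if ("sense" %in% names(ori)) ori[["sense"]] else 0L,
      if ("antisense" %in% names(ori)) ori[["antisense"]] else 0L),
      sprintf("segment overlap x usage: odds ratio %.3f, Fisher p %.3g",
              res$association$odds_ratio, res$association$fisher_p), "")
    pipeline_log(log_con, "features: %d calls", nrow(res$calls))
  }

  # --- v4c -----------------------------------------------------------------
  if ("v4c" %in% cfg$stages) {
    res <- tryCatch({
      reps <- if (!is.null(results$simulate))
        results$simulate$contact_reps else
          list(read_contact_matrix(require_input(cfg$inputs$matrix1, "matrix1"),
               require_input(cfg$inputs$bins, "bins")),
               read_contact_matrix(require_input(cfg$inputs$matrix2, "matrix2"),
                    require_input(cfg$inputs$bins, "bins")))
      sccv <- scc(reps[[1L]], reps[[2L]])$scc
      merged <- merge_replicates(reps[[1L]], reps[[2L]],
                                 scc_threshold = cfg$params$scc_threshold)
      vp <- cfg$params$viewpoint
      if (is.null(vp))
        vp <- reps[[1L]]$start +
          (nrow(reps[[1L]]$counts) %/% 2L) * reps[[1L]]$bin_size
      profs <- lapply(reps, function(m)
        virtual_4c(balance(m), vp, window_bp = cfg$params$window_bp))
      calls <- call_top_interactions(profs, fraction = cfg$params$fraction)
      prof_merged <- virtual_4c(balance(merged), vp,
                                window_bp = cfg$params$window_bp)
      write_v4c_bedgraph(prof_merged,
                         file.path(cfg$out_dir, "v4c_merged.bedGraph"))
      called <- calls$intersection
      if (length(called)) {
        bed <- data.frame(
          prof_merged$chrom,
          format(prof_merged$start + (called - 1L) * prof_merged$bin_size,
                 scientific = FALSE, trim = TRUE),
          format(prof_merged$start + called * prof_merged$bin_size,
                 scientific = FALSE, trim = TRUE),
          sprintf("call%03d", seq_along(called)))
        utils::write.table(bed, file.path(cfg$out_dir, "v4c_calls.bed"),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
      list(scc = sccv, calls = calls, profile = prof_merged, viewpoint = vp)
    }, error = function(e) fail("v4c", e))
    manifest[[length(manifest) + 1L]] <- manifest_row(
      "v4c", file.path(cfg$out_dir, c("v4c_merged.bedGraph",
                                      "v4c_calls.bed")),
      cfg$params[c("fraction", "scc_threshold", "window_bp")])
    results$v4c <- res
    report <- c(report, "## Virtual 4C", sprintf(
      "replicate SCC %.3f; %d replicate-intersected top-%.0f%% interaction bins",
      res$scc, length(res$calls$intersection), 100 * cfg$params$fraction), "")
    pipeline_log(log_con, "v4c: SCC %.3f, %d intersected calls", res$scc,
                 length(res$calls$intersection))
  }

  # --- atac ----------------------------------------------------------------
  if ("atac" %in% cfg$stages) {
    res <- tryCatch({
      sets <- if (!is.null(results$simulate))
        results$simulate$peaks$samples else {
          paths <- cfg$inputs$peak_files
          for (pp in paths) require_input(pp, "peak_files")
          stats::setNames(lapply(paths, read_narrowpeak),
                          sub("\\.narrowPeak$", "", basename(paths)))
        }
      sets <- lapply(sets, to_spm)
      merged <- merge_peak_sets(sets)
      kept <- reproducibility_filter(merged,
                                     min_samples = cfg$params$min_samples,
                                     min_spm = cfg$params$min_spm)
      write_narrowpeak(kept$consensus,
                       file.path(cfg$out_dir, "consensus.narrowPeak"))
      utils::write.table(kept$support,
                         file.path(cfg$out_dir, "consensus_support.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(merged = merged, filtered = kept)
    }, error = function(e) fail("atac", e))
    manifest[[length(manifest) + 1L]] <- manifest_row(
      "atac", file.path(cfg$out_dir, c("consensus.narrowPeak",
                                       "consensus_support.tsv")),
      cfg$params[c("min_samples", "min_spm")])
    results$atac <- res
    report <- c(report, "## ATAC consensus peaks", sprintf(
      "%d consensus peaks; %d pass the >=%d-sample SPM>=%g filter",
      nrow(res$merged$consensus), nrow(res$filtered$consensus),
      cfg$params$min_samples, cfg$params$min_spm), "")
    pipeline_log(log_con, "atac: %d/%d peaks pass",
                 nrow(res$filtered$consensus), nrow(res$merged$consensus))
  }

  if (length(manifest))
    utils::write.table(do.call(rbind, manifest),
                       file.path(cfg$out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  report_path <- file.path(cfg$out_dir, "report.md")
  writeLines(c("# lociscape run report", "", report), report_path)
  pipeline_log(log_con, "report written to %s", report_path)
  invisible(c(results, list(report_path = report_path, config = cfg)))
}
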