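#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois rlnorm rgamma runif median cor sd fisher.test
#'   wilcox.test quantile setNames
#' @importFrom utils read.table write.table head
#' @importFrom methods is
NULL

# Scalar validation helpers -----------------------------------------------

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                      allow_min = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  ok <- if (allow_min) x >= min else x > min
  if (!ok || x > max)
    stop(sprintf("'%s' = %s is outside the allowed range", name, format(x)),
         call. = FALSE)
  invisible(x)
}

stop_if_not_prob <- function(x, name) {
  stop_if_not_scalar_number(x, name, min = 0, max = 1)
}

# Run an expression under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stream-specific child seed so independent generators seeded from
# one master seed do not share an RNG stream.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream)) %% 2147483647L
}

# Validate a chrom_sizes object: named numeric vector of positive lengths.
check_chrom_sizes <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("'chrom_sizes' must be a named vector (chromosome -> length)",
         call. = FALSE)
  if (!is.numeric(chrom_sizes) || any(chrom_sizes <= 0) || anyNA(chrom_sizes))
    stop("'chrom_sizes' lengths must be positive numbers", call. = FALSE)
  invisible(chrom_sizes)
}

# Transcripts are plain data.frames with list-columns for exon blocks.
check_transcripts <- function(tx) {
  need <- c("transcript_id", "chrom", "start", "end", "strand",
            "exon_starts", "exon_ends", "mature_length", "fpkm")
  miss <- setdiff(need, names(tx))
  if (length(miss))
    stop("transcript table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(tx) && any(tx$end <= tx$start))
    stop("transcript spans must satisfy end > start", call. = FALSE)
  invisible(tx)
}
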