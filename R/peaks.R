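#' Call short-fragment peaks against a Poisson local background
#'
#' Transparent re-implementation of local-lambda Poisson peak calling on
#' sub-nucleosomal fragment midpoints. Midpoints are piled into
#' `cfg$short_bin_bp` bins; each bin's expected count is the maximum of the
#' genome-wide mean per bin and local means over centered windows (default 5kb
#' and 10kb, truncated at chromosome ends). A bin is significant when the
#' upper-tail Poisson probability `P(X >= observed | lambda)` is below
#' `cfg$peak_pvalue`. Significant bins are merged across gaps of at most
#' `merge_gap_bp`; merged regions narrower than `min_width_bp` are dropped.
#' The summit is the center of the maximum-pileup bin (leftmost on ties), the
#' score is `-log10` of the smallest bin p-value, and duplicates are retained
#' throughout (no deduplication, no fragment-model shifting).
#'
#' @param short Fragment table containing only sub-nucleosomal fragments; a
#'   fragment of length `>= cfg$short_threshold_bp` raises an error (this
#'   guards pipeline wiring).
#' @param genome [genome_table()].
#' @param cfg [analysis_config()].
#' @param local_windows Window widths in bp for the local lambda estimates.
#' @param merge_gap_bp Merge significant bins separated by at most this gap.
#' @param min_width_bp Drop merged regions narrower than this.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `summit`,
#'   `score`, `short_count` (fragment midpoints in `[start, end)`), sorted by
#'   coordinate.
#' @export
call_short_fragment_peaks <- function(short, genome, cfg = analysis_config(),
                                      local_windows = c(5000L, 10000L),
                                      merge_gap_bp = 30L, min_width_bp = 50L) {
  if (nrow(short) && any(fragment_lengths(short) >= cfg$short_threshold_bp)) {
    stop("call_short_fragment_peaks: input contains fragments of length >= ",
         cfg$short_threshold_bp, " bp; partition by size first", call. = FALSE)
  }
  .check_chroms(short$chrom, genome)
  bs <- cfg$short_bin_bp
  n_bins_per_chrom <- ceiling(unclass(genome) / bs)
  total_bins <- sum(n_bins_per_chrom)
  lambda_genome <- if (total_bins > 0) nrow(short) / total_bins else 0

  mids <- fragment_midpoints(short)
  log10_p_cut <- log10(cfg$peak_pvalue)

  out <- lapply(names(genome), function(chrom) {
    n_bins <- n_bins_per_chrom[[chrom]]
    sel <- short$chrom == chrom
    counts <- tabulate(mids[sel] %/% bs + 1L, nbins = n_bins)
    if (!any(counts > 0L)) return(NULL)

    lambda <- rep(lambda_genome, n_bins)
    cs <- c(0, cumsum(counts))
    for (w in local_windows) {
      h <- (w %/% bs) %/% 2L
      i <- seq_len(n_bins)
      lo <- pmax(i - h, 1L)
      hi <- pmin(i + h, n_bins)
      local_mean <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
      lambda <- pmax(lambda, local_mean)
    }

    log10p <- stats::ppois(counts - 1L, lambda, lower.tail = FALSE,
                           log.p = TRUE) / log(10)
    sig <- which(log10p < log10_p_cut & counts > 0L)
    if (!length(sig)) return(NULL)

    # merge significant bins whose gap (in bp) is <= merge_gap_bp
    gap_bins <- merge_gap_bp %/% bs
    brk <- which(diff(sig) > gap_bins + 1L)
    run_start <- sig[c(1L, brk + 1L)]
    run_end <- sig[c(brk, length(sig))]

    peaks <- lapply(seq_along(run_start), function(j) {
      b0 <- run_start[j]; b1 <- run_end[j]
      start <- (b0 - 1L) * bs
      end <- min(b1 * bs, genome[[chrom]])
      if (end - start < min_width_bp) return(NULL)
      in_run <- b0:b1
      max_bin <- in_run[which.max(counts[in_run])]
      summit <- (max_bin - 1L) * bs + bs %/% 2L
      n_in <- sum(mids[sel] >= start & mids[sel] < end)
      data.frame(chrom = chrom, start = start, end = end, summit = summit,
                 score = -min(log10p[in_run]), short_count = n_in,
                 stringsAsFactors = FALSE)
    })
    peaks <- peaks[!vapply(peaks, is.null, logical(1))]
    if (!length(peaks)) return(NULL)
    do.call(rbind, peaks)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      summit = integer(0), score = numeric(0),
                      short_count = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Retain peaks reproducible across biological replicates
#'
#' Returns the peaks of replicate 1 that overlap (by at least 1bp) at least
#' one peak in every other replicate; replicate 1's coordinates are reported.
#'
#' @param per_replicate List (length >= 2) of peak `data.frame`s as returned
#'   by [call_short_fragment_peaks()].
#' @return Peak `data.frame`, a subset of `per_replicate[[1]]`.
#' @export
reproducible_peaks <- function(per_replicate) {
  if (!is.list(per_replicate) || length(per_replicate) < 2L) {
    stop("reproducible_peaks: need >= 2 replicates", call. = FALSE)
  }
  ref <- per_replicate[[1L]]
  if (!nrow(ref)) return(ref)
  gr_ref <- GenomicRanges::GRanges(ref$chrom,
                                   IRanges::IRanges(ref$start + 1L, ref$end))
  keep <- rep(TRUE, nrow(ref))
  for (other in per_replicate[-1L]) {
    if (!nrow(other)) return(ref[integer(0), , drop = FALSE])
    gr_other <- GenomicRanges::GRanges(other$chrom,
                                       IRanges::IRanges(other$start + 1L, other$end))
    keep <- keep & (GenomicRanges::countOverlaps(gr_ref, gr_other) > 0L)
  }
  ref[keep, , drop = FALSE]
}

#' Write peaks in narrowPeak-style BED6+ columns
#'
#' Columns: chrom, start, end, name, score (x10, integer), strand (`.`),
#' summit offset from start, p-value exponent (the score itself).
#'
#' @param peaks Peak `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   paste0("peak_", seq_len(nrow(peaks))),
                   as.integer(round(pmin(peaks$score, 1000) * 10)), ".",
                   peaks$summit - peaks$start, signif(peaks$score, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
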