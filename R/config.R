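#' Global analysis configuration
#'
#' Bundles the tunable parameters shared across the pipeline: the fragment-size
#' threshold separating sub-nucleosomal from nucleosomal fragments, the bin
#' sizes used for all-fragment and short-fragment coverage, the raw p-value
#' cutoff of the Poisson peak caller, the window half-widths for per-peak
#' profiles and meta-domain flanks, the minimum width of a broad domain, and
#' the seed for every stochastic step.
#'
#' @param short_threshold_bp Fragments strictly shorter than this are treated
#'   as sub-nucleosomal ("short"); default 120.
#' @param all_bin_bp Bin size in bp for all-fragment coverage tracks (default 25).
#' @param short_bin_bp Bin size in bp for short-fragment pileups (default 10).
#' @param peak_pvalue Raw upper-tail Poisson p-value cutoff for peak calling
#'   (default 1e-4). No multiple-testing correction is applied.
#' @param flank_bp Half-width in bp of per-peak windows (heatmaps, V-plots,
#'   flank ratios); default 1000.
#' @param meta_flank_bp Native-scale flank in bp added on each side of
#'   meta-domain profiles; default 3000.
#' @param domain_min_bp Minimum width in bp of a reported broad domain;
#'   default 3000.
#' @param seed Integer seed used by stochastic operations.
#'
#' @return An object of class `analysis_config` (a validated list).
#' @examples
#' cfg <- analysis_config()
#' cfg$short_threshold_bp
#' @export
analysis_config <- function(short_threshold_bp = 120L,
                            all_bin_bp = 25L,
                            short_bin_bp = 10L,
                            peak_pvalue = 1e-4,
                            flank_bp = 1000L,
                            meta_flank_bp = 3000L,
                            domain_min_bp = 3000L,
                            seed = 1L) {
  cfg <- list(
    short_threshold_bp = as.integer(short_threshold_bp),
    all_bin_bp = as.integer(all_bin_bp),
    short_bin_bp = as.integer(short_bin_bp),
    peak_pvalue = as.numeric(peak_pvalue),
    flank_bp = as.integer(flank_bp),
    meta_flank_bp = as.integer(meta_flank_bp),
    domain_min_bp = as.integer(domain_min_bp),
    seed = as.integer(seed)
  )
  for (fld in c("short_threshold_bp", "all_bin_bp", "short_bin_bp",
                "flank_bp", "meta_flank_bp", "domain_min_bp")) {
    if (!is.finite(cfg[[fld]]) || cfg[[fld]] <= 0L) {
      stop("analysis_config: field '", fld, "' must be a positive size", call. = FALSE)
    }
  }
  if (!is.finite(cfg$peak_pvalue) || cfg$peak_pvalue <= 0 || cfg$peak_pvalue >= 1) {
    stop("analysis_config: field 'peak_pvalue' must lie in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("CUT&RUN analysis configuration\n")
  cat(sprintf("  short fragment threshold : < %d bp\n", x$short_threshold_bp))
  cat(sprintf("  coverage bins            : %d bp (all) / %d bp (short)\n",
              x$all_bin_bp, x$short_bin_bp))
  cat(sprintf("  peak p-value             : %g\n", x$peak_pvalue))
  cat(sprintf("  peak flank / meta flank  : %d / %d bp\n", x$flank_bp, x$meta_flank_bp))
  cat(sprintf("  minimum domain width     : %d bp\n", x$domain_min_bp))
  cat(sprintf("  seed                     : %d\n", x$seed))
  invisible(x)
}
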