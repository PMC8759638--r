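#' Quantify fragment signal in named regions across samples
#'
#' Counts fragments whose midpoint falls inside each region (midpoint-in-region
#' counting is additive across adjacent regions), normalizes each sample's
#' counts per million fragments, and reports the percent change of every
#' non-control sample versus the designated control:
#' `100 * (sample - control) / control` on the normalized scale. Regions with
#' zero control signal are flagged and their percent change left undefined.
#'
#' @param frag_sets Named list of fragment tables, one per sample. For
#'   replicate-resolved input, pool or downsample first (see
#'   [downsample_fragments()]).
#' @param regions `data.frame` with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param control Name of the control sample in `frag_sets`.
#' @param genome Optional [genome_table()] to validate region coordinates.
#' @return `data.frame` with one row per (region, sample): `region`, `sample`,
#'   `count`, `cpm`, `percent_change` (`NA` for the control row and for
#'   flagged regions), `control_zero` flag.
#' @export
quantify_regions <- function(frag_sets, regions, control, genome = NULL) {
  stopifnot(is.list(frag_sets), !is.null(names(frag_sets)))
  if (!control %in% names(frag_sets)) {
    stop("quantify_regions: control sample '", control, "' not found", call. = FALSE)
  }
  if (!is.null(genome)) {
    .check_chroms(regions$chrom, genome, "region")
    if (any(regions$start < 0 | regions$end > genome[regions$chrom])) {
      stop("quantify_regions: region outside chromosome", call. = FALSE)
    }
  }
  totals <- vapply(frag_sets, nrow, integer(1))
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    counts <- vapply(frag_sets, function(fr) {
      m <- fragment_midpoints(fr)
      sum(fr$chrom == regions$chrom[r] & m >= regions$start[r] & m < regions$end[r])
    }, numeric(1))
    cpm <- ifelse(totals > 0, counts / totals * 1e6, 0)
    ctrl_cpm <- cpm[[control]]
    pc <- if (ctrl_cpm > 0) 100 * (cpm - ctrl_cpm) / ctrl_cpm else rep(NA_real_, length(cpm))
    pc[names(cpm) == control] <- NA_real_
    rows[[r]] <- data.frame(region = regions$name[r], sample = names(frag_sets),
                            count = as.integer(counts), cpm = as.numeric(cpm),
                            percent_change = as.numeric(pc),
                            control_zero = ctrl_cpm == 0,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Meta-domain coverage profile
#'
#' Averages normalized coverage over a domain set after rescaling each domain
#' body to 100 bins (values linearly interpolated between track bin midpoints)
#' and adding native-scale flanks of `cfg$meta_flank_bp` at 100bp resolution
#' on each side. The profile length is `100 + 2 * meta_flank_bp / 100`.
#' Domains narrower than 100bp are skipped with a warning; flank positions
#' beyond chromosome ends contribute zero.
#'
#' @param track A `coverage_track`.
#' @param domains Domain `data.frame` with at least one row.
#' @param cfg [analysis_config()] (supplies `meta_flank_bp`).
#' @return List of class `meta_domain_profile`: `profile` (mean coverage per
#'   bin), `flank_bins`, `body_bins` (= 100), `n_domains`.
#' @export
meta_domain_profile <- function(track, domains, cfg = analysis_config()) {
  if (!nrow(domains)) stop("meta_domain_profile: need >= 1 domain", call. = FALSE)
  body_bins <- 100L
  flank_bin_bp <- 100L
  flank_bins <- cfg$meta_flank_bp %/% flank_bin_bp
  usable <- domains$end - domains$start >= 100L
  if (any(!usable)) {
    warning(sum(!usable), " domain(s) narrower than 100bp skipped")
    domains <- domains[usable, , drop = FALSE]
  }
  if (!nrow(domains)) stop("meta_domain_profile: no usable domains", call. = FALSE)

  profiles <- vapply(seq_len(nrow(domains)), function(i) {
    chrom <- domains$chrom[i]
    v <- track$values[[chrom]]
    bs <- track$bin_size
    bin_mids <- (seq_along(v) - 0.5) * bs
    left <- vapply(seq_len(flank_bins), function(j) {
      a <- domains$start[i] - cfg$meta_flank_bp + (j - 1L) * flank_bin_bp
      track_interval_sum(track, chrom, a, a + flank_bin_bp) / flank_bin_bp
    }, numeric(1))
    body_x <- domains$start[i] + (seq_len(body_bins) - 0.5) / body_bins *
      (domains$end[i] - domains$start[i])
    body <- stats::approx(bin_mids, v, xout = body_x, rule = 2)$y
    right <- vapply(seq_len(flank_bins), function(j) {
      a <- domains$end[i] + (j - 1L) * flank_bin_bp
      track_interval_sum(track, chrom, a, a + flank_bin_bp) / flank_bin_bp
    }, numeric(1))
    c(left, body, right)
  }, numeric(flank_bins * 2L + body_bins))

  structure(list(profile = rowMeans(profiles),
                 flank_bins = flank_bins, body_bins = body_bins,
                 n_domains = nrow(domains)),
            class = "meta_domain_profile")
}

#' CUT&RUN-qPCR fold enrichment
#'
#' Double-normalized fold enrichment of an antibody-targeted CUT&RUN signal at
#' a locus: relative to a whole-MNase control (tissue digested with free
#' nuclease, no antibody targeting) and relative to a reference locus depleted
#' in the assayed mark (default `Sas10`):
#' \deqn{fold = 2^{Ct_{MNase}(locus) - Ct_{CutRun}(locus)} /
#'              2^{Ct_{MNase}(ref) - Ct_{CutRun}(ref)}}
#' Technical duplicates are averaged on the Ct scale. The reference locus has
#' fold 1 by construction, and adding a constant to all Ct values leaves the
#' result unchanged.
#'
#' @param table `data.frame` with columns `locus`, `assay` (`"cutrun"` or
#'   `"mnase"`), `ct` (cycle-threshold values, > 0); one or more rows
#'   (technical duplicates) per (locus, assay).
#' @param locus Locus to quantify.
#' @param reference Reference locus (default `"Sas10"`).
#' @return Scalar fold enrichment.
#' @export
qpcr_fold_enrichment <- function(table, locus, reference = "Sas10") {
  stopifnot(all(c("locus", "assay", "ct") %in% names(table)))
  if (any(table$ct <= 0)) stop("qpcr_fold_enrichment: Ct values must be > 0", call. = FALSE)
  cell <- function(loc, assay) {
    ct <- table$ct[table$locus == loc & table$assay == assay]
    if (!length(ct)) {
      stop("qpcr_fold_enrichment: missing Ct for locus '", loc,
           "', assay '", assay, "'", call. = FALSE)
    }
    mean(ct)
  }
  d_locus <- cell(locus, "mnase") - cell(locus, "cutrun")
  d_ref <- cell(reference, "mnase") - cell(reference, "cutrun")
  2^d_locus / 2^d_ref
}
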