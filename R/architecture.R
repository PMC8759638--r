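#' Log2 ratio of 3' versus 5' flanking signal at a peak summit
#'
#' Sums per-base track signal over the 3' flank (the `flank_bp` bases above
#' the summit) and the 5' flank (the `flank_bp` bases below it) — 3' and 5'
#' refer to genome coordinate orientation, not transcript strand — and returns
#' `log2((3' + 1) / (5' + 1))`. The pseudocount keeps the ratio defined on
#' sparse tracks (zero coverage on both sides gives 0). Sorting peaks by this
#' ratio separates 5'-border, 3'-border and domain-internal elements.
#'
#' @param peak One-row peak `data.frame` (or list) with `chrom` and `summit`.
#' @param track A `coverage_track`.
#' @param flank_bp Flank width in bp; the window `summit +/- flank_bp` must
#'   lie within the chromosome.
#' @return Scalar log2 ratio.
#' @export
flank_ratio <- function(peak, track, flank_bp = 1000L) {
  chrom <- as.character(peak$chrom)[1L]
  summit <- as.numeric(peak$summit)[1L]
  chrlen <- track$genome[[chrom]]
  if (is.null(chrlen)) stop("flank_ratio: unknown chromosome ", chrom, call. = FALSE)
  if (summit - flank_bp < 0 || summit + flank_bp + 1 > chrlen) {
    stop("flank_ratio: flank of ", flank_bp, " bp around summit ", summit,
         " exceeds chromosome bounds", call. = FALSE)
  }
  s3 <- track_interval_sum(track, chrom, summit + 1, summit + 1 + flank_bp)
  s5 <- track_interval_sum(track, chrom, summit - flank_bp, summit)
  log2((s3 + 1) / (s5 + 1))
}

#' Classify peaks relative to broad domains
#'
#' Labels each peak by the position of its summit relative to a disjoint,
#' sorted domain set: within `border_slack_bp` of a domain's lower edge
#' (inside or outside) it is a `five_prime_border`; within slack of the upper
#' edge, a `three_prime_border`; strictly inside beyond the slack, `internal`;
#' anywhere else, `outside`. On a domain narrow enough for both edges to claim
#' the summit, the lower edge wins. Labels are mutually exclusive and
#' exhaustive.
#'
#' @param peaks Peak `data.frame` (needs `chrom`, `summit`).
#' @param domains Domain `data.frame`; overlapping domains raise an error.
#' @param border_slack_bp Distance from a domain edge still counted as
#'   "at the border" (default 1000, the same scale as the per-peak heatmap
#'   flank; broad domains span 3-240kb, and segmented edges carry up to one
#'   segmentation bin of uncertainty).
#' @param track Optional `coverage_track`; when supplied, a
#'   `flank_log2_ratio` column (see [flank_ratio()]) is added.
#' @param flank_bp Flank width for the ratio (default 1000).
#' @return `peaks` with added columns `label` (and `flank_log2_ratio` if a
#'   track was given).
#' @export
classify_peaks <- function(peaks, domains, border_slack_bp = 1000L,
                           track = NULL, flank_bp = 1000L) {
  if (nrow(domains) > 1L) {
    gr <- GenomicRanges::GRanges(domains$chrom,
                                 IRanges::IRanges(domains$start + 1L, domains$end))
    if (any(GenomicRanges::countOverlaps(gr, gr) > 1L)) {
      stop("classify_peaks: domains must be disjoint", call. = FALSE)
    }
  }
  label <- rep("outside", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    s <- peaks$summit[i]
    dom <- domains[domains$chrom == peaks$chrom[i], , drop = FALSE]
    for (k in seq_len(nrow(dom))) {
      if (abs(s - dom$start[k]) <= border_slack_bp) {
        label[i] <- "five_prime_border"; break
      }
      if (abs(s - dom$end[k]) <= border_slack_bp) {
        label[i] <- "three_prime_border"; break
      }
      if (s > dom$start[k] + border_slack_bp && s < dom$end[k] - border_slack_bp) {
        label[i] <- "internal"; break
      }
    }
  }
  peaks$label <- label
  if (!is.null(track) && nrow(peaks)) {
    peaks$flank_log2_ratio <- vapply(seq_len(nrow(peaks)), function(i) {
      flank_ratio(peaks[i, , drop = FALSE], track, flank_bp)
    }, numeric(1))
  }
  peaks
}

#' Per-peak coverage profile matrix
#'
#' Builds the heatmap matrix of normalized coverage around peak summits: one
#' row per peak, columns covering `summit +/- cfg$flank_bp` at the track's bin
#' size (column count `2 * flank_bp / bin_size`), each cell the mean per-base
#' track value over that column's interval (zero beyond chromosome ends).
#' Rows can be sorted by descending 3'/5' flank log2 ratio, the ordering that
#' stratifies border versus internal elements. Column means are returned
#' overall and, when classification labels are supplied, per label (the
#' average profiles).
#'
#' @param peaks Peak `data.frame` with at least one row.
#' @param track A `coverage_track`.
#' @param cfg [analysis_config()] (supplies `flank_bp`).
#' @param sort_by `"flank_ratio"` (default) or `"none"`.
#' @param labels Optional character vector of per-peak classification labels
#'   (same order as `peaks`).
#' @return List of class `profile_matrix`: `matrix` (rows in output order),
#'   `order` (row indices into `peaks`), `flank_log2_ratio`, `colmeans`, and
#'   `label_means` (named list, if labels were given).
#' @export
profile_matrix <- function(peaks, track, cfg = analysis_config(),
                           sort_by = c("flank_ratio", "none"), labels = NULL) {
  sort_by <- match.arg(sort_by)
  if (!nrow(peaks)) stop("profile_matrix: need >= 1 peak", call. = FALSE)
  flank <- cfg$flank_bp
  bs <- track$bin_size
  n_col <- (2L * flank) %/% bs
  mat <- t(vapply(seq_len(nrow(peaks)), function(i) {
    chrom <- peaks$chrom[i]
    left <- peaks$summit[i] - flank
    vapply(seq_len(n_col), function(j) {
      a <- left + (j - 1L) * bs
      track_interval_sum(track, chrom, a, a + bs) / bs
    }, numeric(1))
  }, numeric(n_col)))
  ratios <- vapply(seq_len(nrow(peaks)), function(i) {
    flank_ratio(peaks[i, , drop = FALSE], track, flank)
  }, numeric(1))
  ord <- if (sort_by == "flank_ratio") order(ratios, decreasing = TRUE) else seq_len(nrow(peaks))
  out <- list(matrix = mat[ord, , drop = FALSE],
              order = ord,
              flank_log2_ratio = ratios[ord],
              colmeans = colMeans(mat))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(peaks))
    out$label_means <- lapply(split(seq_len(nrow(peaks)), labels), function(idx) {
      colMeans(mat[idx, , drop = FALSE])
    })
  }
  structure(out, class = "profile_matrix")
}

#' Fragment midpoint-versus-length matrix (V-plot)
#'
#' Two-dimensional histogram of fragment midpoint offset from the nearest peak
#' summit (x, binned at `x_bin` bp over `+/- cfg$flank_bp`) against fragment
#' length (y, binned at `y_bin` bp over `[0, y_max)`). Each fragment whose
#' midpoint lies within `flank_bp` of its nearest summit (on the same
#' chromosome) contributes exactly one count, so the matrix total equals the
#' number of in-window fragments. Sub-nucleosomal footprints appear as a
#' compact cluster of 50-130bp fragments centered on the summit, flanked by
#' nucleosome-sized (>=147bp) fragments on either side.
#'
#' @param frags Fragment table (any sizes).
#' @param summits `data.frame` with `chrom` and `summit` columns, or a numeric
#'   vector of summits (then all fragments must be on one chromosome).
#' @param cfg [analysis_config()] (supplies `flank_bp`).
#' @param x_bin,y_bin Bin sizes in bp (defaults 10 and 5).
#' @param y_max Upper bound (exclusive) on fragment length (default 300).
#' @return List of class `vplot_matrix`: `counts` (rows = length bins, columns
#'   = offset bins), `x_mids`, `y_mids`, `total`.
#' @export
vplot <- function(frags, summits, cfg = analysis_config(),
                  x_bin = 10L, y_bin = 5L, y_max = 300L) {
  flank <- cfg$flank_bp
  n_x <- (2L * flank) %/% x_bin
  n_y <- y_max %/% y_bin
  x_mids <- -flank + (seq_len(n_x) - 0.5) * x_bin
  y_mids <- (seq_len(n_y) - 0.5) * y_bin
  counts <- matrix(0L, nrow = n_y, ncol = n_x)
  empty <- structure(list(counts = counts, x_mids = x_mids, y_mids = y_mids,
                          total = 0L), class = "vplot_matrix")
  if (is.numeric(summits) && !is.data.frame(summits)) {
    chr <- unique(frags$chrom)
    if (length(chr) > 1L) {
      stop("vplot: numeric summits require single-chromosome fragments", call. = FALSE)
    }
    summits <- data.frame(chrom = rep(chr[1L] %||% "chr", length(summits)),
                          summit = summits)
  }
  if (!nrow(summits) || !nrow(frags)) return(empty)

  mids <- fragment_midpoints(frags)
  lens <- fragment_lengths(frags)
  dx <- rep(NA_real_, nrow(frags))
  for (chr in unique(summits$chrom)) {
    s <- sort(summits$summit[summits$chrom == chr])
    sel <- which(frags$chrom == chr)
    if (!length(sel)) next
    # nearest summit for each midpoint
    pos <- findInterval(mids[sel], s)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(s))
    d_lo <- abs(mids[sel] - s[lo])
    d_hi <- abs(mids[sel] - s[hi])
    nearest <- ifelse(d_lo <= d_hi, s[lo], s[hi])
    dx[sel] <- mids[sel] - nearest
  }
  keep <- !is.na(dx) & abs(dx) <= flank & lens < y_max & lens >= 0L
  if (!any(keep)) return(empty)
  xi <- pmin(floor((dx[keep] + flank) / x_bin) + 1L, n_x)
  yi <- lens[keep] %/% y_bin + 1L
  counts <- matrix(tabulate((xi - 1L) * n_y + yi, nbins = n_x * n_y), nrow = n_y)
  structure(list(counts = counts, x_mids = x_mids, y_mids = y_mids,
                 total = sum(keep)), class = "vplot_matrix")
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a
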