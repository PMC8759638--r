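# Independent reference implementations used as oracles. These are written as
# plain per-element loops, deliberately sharing no code with the package.

# --- Poisson peak scan oracle ------------------------------------------------
# Exhaustive per-bin scan: for every bin, count midpoints by explicit
# comparison, compute each local lambda by summing the window bin counts, test
# the upper Poisson tail, then merge and filter with explicit loops.
oracle_peak_scan <- function(short, genome, cfg,
                             windows = c(5000L, 10000L),
                             merge_gap = 30L, min_width = 50L) {
  bs <- cfg$short_bin_bp
  mids <- short$start + (short$end - short$start) %/% 2L
  total_bins <- sum(ceiling(unclass(genome) / bs))
  lambda_bg <- nrow(short) / total_bins
  out <- NULL
  for (chrom in names(genome)) {
    n_bins <- ceiling(genome[[chrom]] / bs)
    m <- mids[short$chrom == chrom]
    counts <- integer(n_bins)
    for (x in m) counts[x %/% bs + 1L] <- counts[x %/% bs + 1L] + 1L
    sig <- logical(n_bins)
    minus_log10p <- numeric(n_bins)
    for (i in seq_len(n_bins)) {
      lam <- lambda_bg
      for (w in windows) {
        h <- (w %/% bs) %/% 2L
        lo <- max(1L, i - h); hi <- min(n_bins, i + h)
        lam <- max(lam, sum(counts[lo:hi]) / (hi - lo + 1L))
      }
      lp <- stats::ppois(counts[i] - 1L, lam, lower.tail = FALSE, log.p = TRUE) / log(10)
      minus_log10p[i] <- -lp
      sig[i] <- counts[i] > 0L && lp < log10(cfg$peak_pvalue)
    }
    idx <- which(sig)
    if (!length(idx)) next
    regions <- list()
    cur <- c(idx[1L], idx[1L])
    for (i in idx[-1L]) {
      gap_bp <- (i - cur[2L] - 1L) * bs
      if (gap_bp <= merge_gap) cur[2L] <- i
      else { regions[[length(regions) + 1L]] <- cur; cur <- c(i, i) }
    }
    regions[[length(regions) + 1L]] <- cur
    for (r in regions) {
      start <- (r[1L] - 1L) * bs
      end <- min(r[2L] * bs, genome[[chrom]])
      if (end - start < min_width) next
      best <- r[1L]
      for (i in r[1L]:r[2L]) if (counts[i] > counts[best]) best <- i
      out <- rbind(out, data.frame(
        chrom = chrom, start = start, end = end,
        summit = (best - 1L) * bs + bs %/% 2L,
        score = max(minus_log10p[r[1L]:r[2L]]),
        short_count = sum(m >= start & m < end),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      summit = integer(0), score = numeric(0),
                      short_count = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# --- naive IUPAC motif oracle ------------------------------------------------
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVNacgt", "TGCAYRSWMKVHDBNtgca", s),
                     "")[[1]]), collapse = "")
}

# per-offset scan; a position matches when the IUPAC sets intersect
oracle_scan <- function(seq, motif, both_strands = TRUE) {
  seq <- toupper(seq); motif <- toupper(motif)
  sc <- strsplit(seq, "")[[1]]
  hits <- NULL
  pats <- list(`+` = motif)
  if (both_strands) pats[["-"]] <- .oracle_revcomp(motif)
  for (strand in names(pats)) {
    mc <- strsplit(pats[[strand]], "")[[1]]
    k <- length(mc)
    for (off in 0:(length(sc) - k)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!length(intersect(.iupac_sets[[mc[j]]], .iupac_sets[[sc[off + j]]]))) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        hits <- rbind(hits, data.frame(start = off, end = off + k,
                                       strand = strand, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(hits)) {
    hits <- data.frame(start = integer(0), end = integer(0),
                       strand = character(0), stringsAsFactors = FALSE)
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

# --- small generators --------------------------------------------------------
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# short fragments with midpoints given explicitly (clamped away from the
# chromosome start so coordinates stay valid)
short_frags_at <- function(mids, chrom = "c1", len = 80L) {
  start <- pmax(as.integer(mids) - len %/% 2L, 0L)
  fragments(rep(chrom, length(mids)), start, start + len)
}

# build a coverage_track directly from bin values (bin-aligned constructions)
make_track <- function(values, bin_size = 25L, chrom = "c1", norm_factor = 1) {
  chrlen <- length(values) * bin_size
  structure(list(bin_size = as.integer(bin_size), norm_factor = norm_factor,
                 genome = genome_table(stats::setNames(chrlen, chrom)),
                 values = stats::setNames(list(values), chrom)),
            class = "coverage_track")
}
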