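#' Construct a fragment table
#'
#' Fragments are paired-end sequenced DNA particles represented as genomic
#' intervals in 0-based half-open coordinates, tagged with a sample and a
#' replicate identifier. The table is an ordinary `data.frame` with columns
#' `chrom`, `start`, `end`, `sample`, `replicate`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based inclusive start, exclusive end.
#' @param sample,replicate Identifiers (recycled).
#' @param genome Optional [genome_table()]; when given, chromosome names and
#'   bounds are validated.
#' @return A `data.frame` of fragments.
#' @examples
#' fragments("chr2L", 100, 180)
#' @export
fragments <- function(chrom, start, end, sample = "sample1", replicate = "rep1",
                      genome = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) && any(end <= start)) {
    stop("fragments: end must be > start (0-based half-open)", call. = FALSE)
  }
  if (length(chrom) && any(start < 0L)) {
    stop("fragments: start must be >= 0", call. = FALSE)
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   sample = rep_len(as.character(sample), length(chrom)),
                   replicate = rep_len(as.character(replicate), length(chrom)),
                   stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    .check_chroms(df$chrom, genome)
    too_far <- df$end > genome[df$chrom]
    if (any(too_far)) {
      stop("fragments: ", sum(too_far), " fragment(s) extend beyond chromosome end",
           call. = FALSE)
    }
  }
  df
}

#' Fragment lengths in bp
#' @param frags Fragment table.
#' @return Integer vector `end - start`.
#' @export
fragment_lengths <- function(frags) frags$end - frags$start

#' Fragment midpoints
#'
#' The midpoint of a fragment of length L starting at `start` is
#' `start + L %/% 2` (for even L this is exactly `start + L/2`).
#'
#' @param frags Fragment table.
#' @return Integer vector of 0-based midpoint coordinates.
#' @export
fragment_midpoints <- function(frags) {
  frags$start + (frags$end - frags$start) %/% 2L
}

#' Read paired-end fragments from disk
#'
#' Supported dialects:
#' * `"bed"` — BED3/BED6; one fragment per line, coordinates used as-is
#'   (already 0-based half-open).
#' * `"bedpe"` — BEDPE; each mate pair becomes one fragment spanning the
#'   outermost coordinates of the two mates (both mates must map to the same
#'   chromosome).
#' * `"sam"` — headered SAM ("SAM-lite"): for each properly paired line with a
#'   positive template length (TLEN), one fragment `[POS-1, POS-1+TLEN)` is
#'   emitted, so each pair is counted once. Only the columns QNAME..TLEN are
#'   consulted.
#'
#' Input order is preserved. Malformed lines raise an error naming the line
#' number; with a `genome`, unknown chromosomes raise an error naming them.
#'
#' @param path File path.
#' @param format One of `"bed"`, `"bedpe"`, `"sam"`.
#' @param genome Optional [genome_table()] for validation.
#' @param sample,replicate Identifiers attached to every fragment.
#' @return A fragment `data.frame` (see [fragments()]).
#' @export
read_fragments <- function(path, format = c("bed", "bedpe", "sam"),
                           genome = NULL, sample = "sample1", replicate = "rep1") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("fragment file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  if (format == "sam") keep <- keep & !startsWith(lines, "@")
  idx <- which(keep)
  if (!length(idx)) {
    return(fragments(character(0), integer(0), integer(0), sample, replicate))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)

  .bad <- function(i, why) {
    stop(sprintf("%s: parse error at line %d: %s", basename(path), idx[i], why),
         call. = FALSE)
  }
  .num <- function(x, i, what) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) .bad(i, paste("non-numeric", what))
    v
  }

  n <- length(fields)
  chrom <- character(n); start <- numeric(n); end <- numeric(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (format == "bed") {
      if (length(f) < 3L) .bad(i, "expected >= 3 BED columns")
      chrom[i] <- f[1L]
      start[i] <- .num(f[2L], i, "start")
      end[i] <- .num(f[3L], i, "end")
    } else if (format == "bedpe") {
      if (length(f) < 6L) .bad(i, "expected >= 6 BEDPE columns")
      if (f[1L] != f[4L]) .bad(i, "mates on different chromosomes")
      s1 <- .num(f[2L], i, "start1"); e1 <- .num(f[3L], i, "end1")
      s2 <- .num(f[5L], i, "start2"); e2 <- .num(f[6L], i, "end2")
      chrom[i] <- f[1L]
      start[i] <- min(s1, s2)
      end[i] <- max(e1, e2)
    } else { # sam
      if (length(f) < 9L) .bad(i, "expected >= 9 SAM columns")
      tlen <- .num(f[9L], i, "TLEN")
      if (tlen <= 0) { chrom[i] <- NA_character_; next } # rightmost mate: skip
      pos <- .num(f[4L], i, "POS")
      chrom[i] <- f[3L]
      start[i] <- pos - 1
      end[i] <- pos - 1 + tlen
    }
    if (end[i] <= start[i]) .bad(i, "end <= start")
  }
  used <- !is.na(chrom)
  frags <- fragments(chrom[used], start[used], end[used], sample, replicate,
                     genome = genome)
  frags
}

#' Write fragments as BED
#'
#' @param frags Fragment table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(frags, path) {
  df <- data.frame(frags$chrom, frags$start, frags$end,
                   paste(frags$sample, frags$replicate, sep = "."))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Partition fragments by size
#'
#' Splits a fragment set into the sub-nucleosomal ("short") view — fragments
#' strictly shorter than `threshold` — and the complete ("all") view used for
#' histone-modification coverage. The all-fragment view deliberately retains
#' the short fragments (libraries are dominated by, not restricted to,
#' nucleosome-sized fragments); a nucleosomal-only view (length >= threshold)
#' is also returned for callers that want it, but is not used by default.
#'
#' @param frags Fragment table.
#' @param threshold Size threshold in bp (strict `<`); default 120.
#' @return A list with elements `short`, `all`, and `nucleosomal`.
#' @examples
#' fr <- fragments("c", c(0, 0, 0, 0), c(80, 119, 120, 150))
#' fragment_lengths(partition_by_size(fr)$short)  # 80, 119
#' @export
partition_by_size <- function(frags, threshold = 120L) {
  if (threshold <= 0) stop("partition_by_size: threshold must be > 0", call. = FALSE)
  len <- fragment_lengths(frags)
  list(short = frags[len < threshold, , drop = FALSE],
       all = frags,
       nucleosomal = frags[len >= threshold, , drop = FALSE])
}

#' Downsample fragment sets to a common depth
#'
#' Uniform sampling without replacement, deterministic under a fixed seed, so
#' that samples can be compared at identical read count (the alternative to
#' per-million scaling).
#'
#' @param frag_sets Named list of fragment tables (one per sample/library).
#' @param target Integer count, or `"min"` to use the smallest set size.
#' @param seed Integer seed.
#' @return Named list of downsampled fragment tables, in the input order.
#' @export
downsample_fragments <- function(frag_sets, target = "min", seed = 1L) {
  stopifnot(is.list(frag_sets), length(frag_sets) >= 1L)
  sizes <- vapply(frag_sets, nrow, integer(1))
  if (identical(target, "min")) target <- min(sizes)
  target <- as.integer(target)
  if (any(target > sizes)) {
    stop("downsample_fragments: target (", target,
         ") exceeds set size (", min(sizes), ")", call. = FALSE)
  }
  with_seed(seed, {
    lapply(frag_sets, function(fr) {
      keep <- sort(sample.int(nrow(fr), target))
      fr[keep, , drop = FALSE]
    })
  })
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
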