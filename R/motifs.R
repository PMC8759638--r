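#' Reverse complement of a DNA string
#'
#' IUPAC-aware reverse complementation (e.g. `R` <-> `Y`, `N` <-> `N`).
#' Invalid characters raise an error. The DRE consensus `TATCGATA` is its own
#' reverse complement.
#'
#' @param seq A DNA string (IUPAC alphabet).
#' @return The reverse-complemented string.
#' @examples
#' revcomp("TATCGATA")
#' @export
revcomp <- function(seq) {
  .check_dna(seq, "revcomp")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.check_dna <- function(seq, caller) {
  bad <- setdiff(strsplit(toupper(seq), "")[[1]],
                 strsplit("ACGTRYSWKMBDHVN", "")[[1]])
  if (length(bad)) {
    stop(caller, ": invalid DNA character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Exact consensus matching at every offset: a position matches when the
#' IUPAC base sets of motif and sequence letter intersect (for plain ACGT
#' sequences this is perfect-match consensus scanning). With
#' `both_strands = TRUE`, minus-strand occurrences — offsets where the
#' reverse complement of the sequence window matches the motif — are reported
#' at forward coordinates with strand `"-"`. A palindromic motif therefore
#' yields coincident `+`/`-` matches that are counted separately; this is the
#' convention under which the 14bp palindrome `TATCGATATCGATA` carries four
#' matches of the 8bp DRE consensus `TATCGATA` (offsets 0 and 6 on each
#' strand).
#'
#' @param seq A DNA string, or a named character vector / `DNAStringSet` of
#'   sequences (e.g. promoter sequences read with
#'   `Biostrings::readDNAStringSet()` from FASTA).
#' @param motif IUPAC consensus string, no longer than the sequence.
#' @param both_strands Scan both strands (default `TRUE`).
#' @param seqname Name used for an unnamed single sequence.
#' @return `data.frame` with columns `seqname`, `start` (0-based), `end`
#'   (half-open), `strand`, `motif`, `match` (forward-strand subsequence),
#'   sorted by sequence, start and strand.
#' @examples
#' scan_motif("TATCGATATCGATA", "TATCGATA")  # 4 matches
#' @export
scan_motif <- function(seq, motif, both_strands = TRUE, seqname = "seq") {
  .check_dna(motif, "scan_motif")
  nms <- names(seq)
  seqs <- as.character(seq)  # as.character drops names; restore them
  names(seqs) <- nms
  if (is.null(names(seqs))) {
    names(seqs) <- if (length(seqs) == 1L) seqname else paste0(seqname, seq_along(seqs))
  }
  motif <- toupper(motif)
  res <- lapply(names(seqs), function(nm) {
    s <- toupper(seqs[[nm]])
    .check_dna(s, "scan_motif")
    if (nchar(motif) > nchar(s)) {
      stop("scan_motif: motif longer than sequence '", nm, "'", call. = FALSE)
    }
    subject <- Biostrings::DNAString(s)
    hit_df <- function(pattern, strand) {
      m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                    fixed = FALSE)
      if (!length(m)) return(NULL)
      data.frame(seqname = nm, start = BiocGenerics::start(m) - 1L,
                 end = BiocGenerics::end(m), strand = strand, motif = motif,
                 match = as.character(m), stringsAsFactors = FALSE)
    }
    parts <- list(hit_df(motif, "+"))
    if (both_strands) parts <- c(parts, list(hit_df(revcomp(motif), "-")))
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts)) return(NULL)
    do.call(rbind, parts)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(seqname = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      motif = character(0), match = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$seqname, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimal interval covering a set of motif matches
#'
#' The smallest single interval spanning every match on one sequence — e.g.
#' the 14bp region covering the four overlapping DRE matches, the span
#' deleted in the corresponding promoter-mutant transgene.
#'
#' @param matches Match `data.frame` from [scan_motif()]; must be non-empty
#'   and on a single sequence.
#' @return One-row `data.frame` with `seqname`, `start`, `end`, `width`.
#' @examples
#' match_span(scan_motif("TATCGATATCGATA", "TATCGATA"))  # width 14
#' @export
match_span <- function(matches) {
  if (!nrow(matches)) stop("match_span: no matches", call. = FALSE)
  if (length(unique(matches$seqname)) != 1L) {
    stop("match_span: matches span multiple sequences", call. = FALSE)
  }
  start <- min(matches$start)
  end <- max(matches$end)
  data.frame(seqname = matches$seqname[1L], start = start, end = end,
             width = end - start, stringsAsFactors = FALSE)
}

#' Write motif matches as BED6
#'
#' @param matches Match `data.frame` from [scan_motif()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches_bed <- function(matches, path) {
  df <- data.frame(matches$seqname, matches$start, matches$end,
                   matches$motif, 0L, matches$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
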