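#' Genome table (chromosome sizes)
#'
#' A genome table is a named numeric vector mapping chromosome names to their
#' lengths in bp, in a fixed order. Names must be unique and lengths at least 1.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp.
#' @return A validated named numeric vector of class `genome_table`.
#' @examples
#' gt <- genome_table(c(chr2L = 100000, chrX = 50000))
#' @export
genome_table <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
    stop("genome_table: chromosome names are required", call. = FALSE)
  }
  if (anyDuplicated(names(lengths))) {
    stop("genome_table: chromosome names must be unique", call. = FALSE)
  }
  lengths <- vapply(lengths, as.numeric, numeric(1))
  if (any(!is.finite(lengths)) || any(lengths < 1)) {
    stop("genome_table: chromosome lengths must be >= 1", call. = FALSE)
  }
  structure(lengths, class = c("genome_table", "numeric"))
}

#' Read a chrom.sizes file
#'
#' Tab-separated two-column file: chromosome name, length in bp.
#'
#' @param path File path.
#' @return A [genome_table()].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome_table(stats::setNames(tab$length, tab$chrom))
}

# internal: error if chrom absent from a genome table
.check_chroms <- function(chroms, genome, what = "fragment") {
  unknown <- setdiff(unique(chroms), names(genome))
  if (length(unknown)) {
    stop(what, " on unknown chromosome: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
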