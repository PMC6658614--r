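#' Genomic interval
#'
#' A minimal genomic interval record. All internal coordinates in this package
#' are 0-based half-open (`[start, end)`); conversion to and from 1-based
#' conventions happens only at I/O boundaries (GFF3, SAM, BED block maths).
#'
#' @param chrom Chromosome/contig identifier.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval` (a named list).
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end) {
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(
    list(chrom = as.character(chrom), start = start, end = end, strand = strand),
    class = "genomic_interval"
  )
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:[%d,%d)/%s\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

interval_width <- function(x) x$end - x$start

# Overlap width between [s1,e1) and [s2,e2); 0 when disjoint.
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}
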