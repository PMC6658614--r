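#' Gene model: ordered exons and derived introns of one gene
#'
#' Holds the exon structure of a single multi-exon gene and the introns derived
#' from it. Exons are stored in transcript (5' to 3') order; each interval keeps
#' genomic `start < end` regardless of strand, so on the minus strand the exon
#' list runs right-to-left along the genome. Exon/intron numbering is 1-based in
#' all reports (exon 7, intron 10), matching field usage.
#'
#' @param gene_id Gene label.
#' @param chrom Chromosome/contig identifier.
#' @param exon_starts,exon_ends 0-based half-open exon coordinates in transcript
#'   order.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `gene_model` with elements `gene_id`, `chrom`,
#'   `strand`, `span` (c(start, end)), `exons` and `introns` (data frames with
#'   `start`, `end` in transcript order).
#' @export
gene_model <- function(gene_id, chrom, exon_starts, exon_ends, strand = "+") {
  stopifnot(length(exon_starts) == length(exon_ends))
  n <- length(exon_starts)
  if (n < 2L) stop("gene model requires >= 2 exons, got ", n)
  exon_starts <- as.numeric(exon_starts)
  exon_ends <- as.numeric(exon_ends)
  if (any(is.na(exon_starts)) || any(is.na(exon_ends)) ||
      any(exon_starts < 0) || any(exon_starts >= exon_ends)) {
    stop("exon intervals must satisfy 0 <= start < end")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")

  # transcript order means genomically increasing on '+', decreasing on '-'
  genomic_sorted <- if (strand == "+") {
    all(diff(exon_starts) > 0)
  } else {
    all(diff(exon_starts) < 0)
  }
  if (!genomic_sorted) {
    bad <- if (strand == "+") which(diff(exon_starts) <= 0)[1] else which(diff(exon_starts) >= 0)[1]
    stop("exons not sorted in transcript order consistent with strand ",
         strand, ": exon ", bad, " vs exon ", bad + 1L)
  }
  # pairwise non-overlap & no zero-length introns: check in genomic order
  ord <- order(exon_starts)
  gs <- exon_starts[ord]; ge <- exon_ends[ord]
  gap <- gs[-1] - ge[-length(ge)]
  if (any(gap < 0)) {
    bad <- which(gap < 0)[1]
    stop("exons overlap: exon intervals ", bad, " and ", bad + 1L,
         " in genomic order")
  }
  if (any(gap == 0)) {
    bad <- which(gap == 0)[1]
    stop("abutting exons produce a zero-length intron between genomic exons ",
         bad, " and ", bad + 1L)
  }

  exons <- data.frame(start = exon_starts, end = exon_ends)
  model <- structure(
    list(
      gene_id = as.character(gene_id),
      chrom = as.character(chrom),
      strand = strand,
      span = c(start = min(exon_starts), end = max(exon_ends)),
      exons = exons,
      introns = NULL
    ),
    class = "gene_model"
  )
  model$introns <- derive_introns(model)
  model
}

#' Derive introns from a gene model
#'
#' Intron i spans exactly the genomic gap between exon i and exon i+1 in
#' transcript order: `[end(exon i), start(exon i+1))` on the plus strand,
#' `[end(exon i+1), start(exon i))` on the minus strand. A gene with n exons
#' has n - 1 introns.
#'
#' @param model A `gene_model`.
#' @return A data frame with columns `start`, `end`, one row per intron in
#'   transcript order.
#' @export
derive_introns <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (model$strand == "+") {
    data.frame(start = ex$end[-n], end = ex$start[-1])
  } else {
    data.frame(start = ex$end[-1], end = ex$start[-n])
  }
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s' (%s:%d-%d, %s): %d exons, %d introns\n",
              x$gene_id, x$chrom, x$span["start"], x$span["end"], x$strand,
              nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

n_exons <- function(model) nrow(model$exons)

#' Load a gene model from BED12 or GFF3
#'
#' BED12 blocks are taken as exons; GFF3 `exon` features are grouped by their
#' `Parent` (or, failing that, `gene_id`/`ID`) attribute. GFF3's 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention; BED is already 0-based half-open.
#'
#' @param path Path to a BED12 or GFF3 file.
#' @param gene_id Identifier of the gene/transcript to load.
#' @param format `"bed"`, `"gff3"`, or `"auto"` (by file extension).
#' @return A validated `gene_model`.
#' @export
load_gene_model <- function(path, gene_id, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    hit <- which(as.character(gr$name) == gene_id)
    if (length(hit) == 0L) stop("gene '", gene_id, "' not found in ", path)
    gr <- gr[hit[1]]
    blocks <- gr$blocks[[1]]  # 1-based within the BED record
    chrom_start <- GenomicRanges::start(gr) - 1L  # back to BED 0-based
    starts <- chrom_start + IRanges::start(blocks) - 1L
    ends <- chrom_start + IRanges::end(blocks)
    strand <- as.character(GenomicRanges::strand(gr))
    if (!strand %in% c("+", "-")) strand <- "+"
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    ex <- gr[tolower(as.character(gr$type)) == "exon"]
    parent <- if (!is.null(ex$Parent)) {
      vapply(as.list(ex$Parent), function(p) if (length(p)) p[[1]] else NA_character_, "")
    } else rep(NA_character_, length(ex))
    keys <- cbind(parent,
                  if (!is.null(ex$gene_id)) as.character(ex$gene_id) else NA,
                  if (!is.null(ex$ID)) as.character(ex$ID) else NA)
    hit <- apply(keys, 1L, function(k) any(!is.na(k) & k == gene_id))
    if (!any(hit)) stop("gene '", gene_id, "' not found in ", path)
    ex <- ex[hit]
    starts <- GenomicRanges::start(ex) - 1L  # 1-based inclusive -> 0-based
    ends <- GenomicRanges::end(ex)           # inclusive end -> exclusive end
    strand <- as.character(GenomicRanges::strand(ex))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    chrom_start <- NULL
    ord <- order(starts)
    starts <- starts[ord]; ends <- ends[ord]
    gr <- ex
  }
  if (length(starts) < 2L) stop("gene '", gene_id, "' has fewer than 2 exons")
  # genomic order -> transcript order
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  if (strand == "-") { starts <- rev(starts); ends <- rev(ends) }
  chrom <- as.character(GenomicRanges::seqnames(gr))[1]
  gene_model(gene_id, chrom, starts, ends, strand = strand)
}

#' Write a gene model as BED12
#'
#' @param model A `gene_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed12 <- function(model, path) {
  ex <- model$exons[order(model$exons$start), , drop = FALSE]  # genomic order
  span <- model$span
  line <- paste(
    model$chrom, span["start"], span["end"], model$gene_id, 0, model$strand,
    span["start"], span["end"], "0,0,0", nrow(ex),
    paste0(paste(ex$end - ex$start, collapse = ","), ","),
    paste0(paste(ex$start - span["start"], collapse = ","), ","),
    sep = "\t"
  )
  writeLines(line, path)
  invisible(path)
}

#' Write derived introns as BED6
#'
#' @param model A `gene_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_introns_bed6 <- function(model, path) {
  intr <- model$introns
  lines <- sprintf("%s\t%d\t%d\t%s_intron_%d\t0\t%s",
                   model$chrom, intr$start, intr$end,
                   model$gene_id, seq_len(nrow(intr)), model$strand)
  writeLines(lines, path)
  invisible(path)
}

# Genomic gap between transcript-adjacent-or-skipping exons i < j (transcript
# order indices): the reference segment removed by that splice.
junction_gap <- function(model, i, j) {
  ex <- model$exons
  if (model$strand == "+") c(ex$end[i], ex$start[j]) else c(ex$end[j], ex$start[i])
}
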