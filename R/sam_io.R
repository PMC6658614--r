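#' Read a SAM text file into an alignment record table
#'
#' Parses the mandatory SAM fields. Positions are converted to the internal
#' 0-based convention (`pos0 = POS - 1`). Header lines are retained as an
#' attribute. Only the fields the pipeline consumes are kept.
#'
#' @param path Path to a SAM file (uncompressed text).
#' @return A data frame with columns `qname`, `flag`, `rname`, `pos0`, `mapq`,
#'   `cigar`, `rnext`, `pnext0`, `tlen`, `seq`; attribute `header` holds the
#'   raw header lines.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L) {
    out <- data.frame(qname = character(), flag = integer(), rname = character(),
                      pos0 = numeric(), mapq = integer(), cigar = character(),
                      rnext = character(), pnext0 = numeric(), tlen = numeric(),
                      seq = character(), stringsAsFactors = FALSE)
    attr(out, "header") <- hdr
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("malformed SAM record at line ", which(nf < 11L)[1], ": fewer than 11 fields")
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  out <- data.frame(
    qname = get(1), flag = as.integer(get(2)), rname = get(3),
    pos0 = as.numeric(get(4)) - 1, mapq = as.integer(get(5)), cigar = get(6),
    rnext = get(7), pnext0 = as.numeric(get(8)) - 1, tlen = as.numeric(get(9)),
    seq = get(10), stringsAsFactors = FALSE
  )
  attr(out, "header") <- hdr
  out
}

#' Write an alignment record table as SAM text
#'
#' @param records A data frame as returned by [read_sam()] or
#'   [simulate_reads()].
#' @param path Output path.
#' @param seqinfo Named numeric vector of reference lengths for `@SQ` lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, seqinfo = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted")
  if (!is.null(seqinfo)) {
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(seqinfo), as.integer(seqinfo)))
  } else if (!is.null(attr(records, "header"))) {
    hdr <- attr(records, "header")
  }
  qual <- strrep("I", nchar(records$seq))
  qual[records$seq == "*"] <- "*"
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  records$qname, records$flag, records$rname,
                  as.integer(records$pos0 + 1), records$mapq, records$cigar,
                  records$rnext, as.integer(records$pnext0 + 1),
                  as.integer(records$tlen), records$seq, qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# SAM flag helpers
flag_has <- function(flag, bit) bitwAnd(flag, bit) != 0L
is_unmapped <- function(flag) flag_has(flag, 0x4L)
is_secondary <- function(flag) flag_has(flag, 0x100L)
is_supplementary <- function(flag) flag_has(flag, 0x800L)
is_first_mate <- function(flag) flag_has(flag, 0x40L)

# Keep mapped primary alignments only (the default counting universe).
primary_mapped <- function(records, keep_secondary = FALSE) {
  keep <- !is_unmapped(records$flag)
  if (!keep_secondary) {
    keep <- keep & !is_secondary(records$flag) & !is_supplementary(records$flag)
  }
  records[keep, , drop = FALSE]
}

#' Parse a CIGAR string into operation lengths and codes
#'
#' @param cigar A single CIGAR string.
#' @return A data frame with columns `len` (integer) and `op` (character).
#' @keywords internal
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(data.frame(len = integer(), op = character()))
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    consumed <- paste(toks, collapse = "")
    bad <- substr(cigar, nchar(consumed) + 1L, nchar(cigar))
    stop("malformed CIGAR '", cigar, "': unparseable token near '", bad, "'")
  }
  data.frame(
    len = as.integer(substr(toks, 1L, nchar(toks) - 1L)),
    op = substr(toks, nchar(toks), nchar(toks)),
    stringsAsFactors = FALSE
  )
}

# Reference-consuming aligned blocks (M/=/X/D runs between N gaps) of one
# alignment: matrix with columns start, end (0-based half-open). N splits
# blocks; S/H/I/P consume no reference.
aligned_blocks <- function(pos0, cigar) {
  ops <- parse_cigar(cigar)
  ref_pos <- pos0
  blocks <- list()
  cur_start <- NA_real_
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X", "D")) {
      if (is.na(cur_start)) cur_start <- ref_pos
      ref_pos <- ref_pos + len
    } else if (op == "N") {
      if (!is.na(cur_start)) {
        blocks[[length(blocks) + 1L]] <- c(cur_start, ref_pos)
        cur_start <- NA_real_
      }
      ref_pos <- ref_pos + len
    }
    # S, H, I, P: no reference consumed
  }
  if (!is.na(cur_start)) blocks[[length(blocks) + 1L]] <- c(cur_start, ref_pos)
  if (length(blocks) == 0L) {
    return(matrix(numeric(), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  m <- do.call(rbind, blocks)
  colnames(m) <- c("start", "end")
  m
}
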