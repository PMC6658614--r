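#' Extract splice-junction observations from one alignment
#'
#' Each `N` operation in the CIGAR yields one junction observation whose gap is
#' the skipped reference segment, obtained by walking the reference-consuming
#' operations (M, D, N, =, X); soft/hard clips and insertions consume no
#' reference. Overhangs are the aligned (M/=/X) nucleotides in the blocks
#' immediately flanking the gap.
#'
#' @param rec A one-row data frame or list with at least `qname`, `pos0`,
#'   `cigar` (see [read_sam()]).
#' @return A data frame with columns `read_id`, `gap_start`, `gap_end`,
#'   `left_overhang`, `right_overhang`; zero rows when the CIGAR has no N.
#' @export
extract_junctions <- function(rec) {
  ops <- parse_cigar(rec$cigar)
  empty <- data.frame(read_id = character(), gap_start = numeric(),
                      gap_end = numeric(), left_overhang = integer(),
                      right_overhang = integer(), stringsAsFactors = FALSE)
  if (nrow(ops) == 0L || !any(ops$op == "N")) return(empty)

  ref_pos <- rec$pos0
  seg_aligned <- 0L                 # M/=/X nt in the current inter-gap segment
  gaps <- list()                    # each: c(start, end, left_overhang)
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      seg_aligned <- seg_aligned + len
      ref_pos <- ref_pos + len
    } else if (op == "D") {
      ref_pos <- ref_pos + len
    } else if (op == "N") {
      gaps[[length(gaps) + 1L]] <- c(ref_pos, ref_pos + len, seg_aligned)
      seg_aligned <- 0L
      ref_pos <- ref_pos + len
    }
  }
  g <- do.call(rbind, gaps)
  right <- c(g[-1, 3], seg_aligned)  # each gap's right overhang is the next segment
  data.frame(
    read_id = rep(as.character(rec$qname), nrow(g)),
    gap_start = g[, 1], gap_end = g[, 2],
    left_overhang = as.integer(g[, 3]), right_overhang = as.integer(right),
    stringsAsFactors = FALSE
  )
}

#' Classify a junction gap against a gene model
#'
#' Matches the gap boundaries against annotated exon boundaries within
#' `tolerance` nucleotides. A gap spanning exactly the segment between exon i
#' and exon i+1 (transcript order) is `adjacent`; between exon i and exon i+2,
#' `skip` (one exon skipped); everything else — multi-exon skips, unannotated
#' donors/acceptors — is `other`, never dropped silently.
#'
#' @param gap_start,gap_end 0-based half-open gap coordinates.
#' @param model A `gene_model`.
#' @param tolerance Maximum boundary mismatch in nt (default 0, exact match).
#' @return A list with `kind` (`"adjacent"`, `"skip"`, `"other"`),
#'   `upstream_exon`, `downstream_exon` (1-based transcript indices; NA for
#'   `other`).
#' @export
classify_junction <- function(gap_start, gap_end, model, tolerance = 0) {
  n <- n_exons(model)
  for (step in 1:2) {
    kind <- if (step == 1L) "adjacent" else "skip"
    for (i in seq_len(n - step)) {
      gap <- junction_gap(model, i, i + step)
      if (abs(gap_start - gap[1]) <= tolerance && abs(gap_end - gap[2]) <= tolerance) {
        return(list(kind = kind, upstream_exon = i, downstream_exon = i + step))
      }
    }
  }
  list(kind = "other", upstream_exon = NA_integer_, downstream_exon = NA_integer_)
}

#' Count correct-splice and exon-skip junction events per adjacent exon pair
#'
#' Walks every mapped primary alignment, extracts junction observations,
#' discards those with either overhang below `min_overhang`, classifies the
#' rest against the gene model, and accumulates counts: `adjacent(i, i+1)`
#' increments `n_correct` of row i; `skip(i, i+2)` increments `n_skip` of row
#' i. `other` events are tallied in the `n_other` attribute. The result is
#' independent of record order.
#'
#' @param records Alignment record data frame (see [read_sam()]).
#' @param model A `gene_model`.
#' @param min_overhang Minimum aligned nt on each side of a junction
#'   (default 5).
#' @param tolerance Boundary-match tolerance in nt (default 0).
#' @param library_id Label stored in the `library` column.
#' @param keep_secondary Count secondary/supplementary alignments too
#'   (default FALSE; prevents double counting).
#' @return A data frame with one row per adjacent exon pair `1..(n_exons-1)`:
#'   columns `upstream_exon`, `library`, `n_correct`, `n_skip`; attributes
#'   `n_other` (classified other) and `n_filtered` (failed the overhang
#'   filter).
#' @export
count_junctions <- function(records, model, min_overhang = 5, tolerance = 0,
                            library_id = "library", keep_secondary = FALSE) {
  records <- primary_mapped(records, keep_secondary = keep_secondary)
  records <- records[records$rname == model$chrom, , drop = FALSE]
  nrows <- n_exons(model) - 1L
  tab <- data.frame(upstream_exon = seq_len(nrows),
                    library = library_id,
                    n_correct = 0, n_skip = 0,
                    stringsAsFactors = FALSE)
  n_other <- 0L; n_filtered <- 0L; n_obs <- 0L
  for (r in seq_len(nrow(records))) {
    obs <- extract_junctions(records[r, ])
    for (j in seq_len(nrow(obs))) {
      if (obs$left_overhang[j] < min_overhang || obs$right_overhang[j] < min_overhang) {
        n_filtered <- n_filtered + 1L
        next
      }
      n_obs <- n_obs + 1L
      cls <- classify_junction(obs$gap_start[j], obs$gap_end[j], model, tolerance)
      if (cls$kind == "adjacent") {
        tab$n_correct[cls$upstream_exon] <- tab$n_correct[cls$upstream_exon] + 1
      } else if (cls$kind == "skip") {
        tab$n_skip[cls$upstream_exon] <- tab$n_skip[cls$upstream_exon] + 1
      } else {
        n_other <- n_other + 1L
      }
    }
  }
  if (n_obs + n_filtered == 0L) {
    warning("no usable junction observations in library '", library_id, "'")
  }
  attr(tab, "n_other") <- n_other
  attr(tab, "n_filtered") <- n_filtered
  attr(tab, "gene_id") <- model$gene_id
  tab
}

#' Fraction of incorrect (exon-skipping) splicing events
#'
#' Defined as `n_skip / (n_correct + n_skip)` — a proper proportion in
#' \[0, 1\], the quantity the binomial mixture model treats as a success rate
#' with `n = n_correct + n_skip` trials. When both counts are zero the
#' fraction is undefined and `NA` is returned.
#'
#' @param n_correct,n_skip Non-negative event counts (vectorised).
#' @return `n_skip / (n_correct + n_skip)`, or `NA` where both are zero.
#' @export
skip_fraction <- function(n_correct, n_skip) {
  stopifnot(all(n_correct >= 0, na.rm = TRUE), all(n_skip >= 0, na.rm = TRUE))
  tot <- n_correct + n_skip
  ifelse(tot >= 1, n_skip / tot, NA_real_)
}

#' Per-position raw-read coverage over a region
#'
#' `depth[p]` is the number of alignments whose reference-consuming blocks
#' cover position p; N gaps contribute no coverage.
#'
#' @param records Alignment record data frame.
#' @param chrom,start,end Region (0-based half-open).
#' @param keep_secondary Include secondary/supplementary alignments.
#' @return A list of class `coverage_profile`: `chrom`, `start`, `end`,
#'   `depth` (numeric vector of length `end - start`).
#' @export
coverage_profile <- function(records, chrom, start, end, keep_secondary = FALSE) {
  stopifnot(start >= 0, end > start)
  records <- primary_mapped(records, keep_secondary = keep_secondary)
  records <- records[records$rname == chrom, , drop = FALSE]
  depth <- numeric(end - start)
  for (r in seq_len(nrow(records))) {
    blocks <- aligned_blocks(records$pos0[r], records$cigar[r])
    for (b in seq_len(nrow(blocks))) {
      s <- max(blocks[b, 1], start); e <- min(blocks[b, 2], end)
      if (s < e) {
        idx <- (s - start + 1):(e - start)
        depth[idx] <- depth[idx] + 1
      }
    }
  }
  structure(list(chrom = chrom, start = start, end = end, depth = depth),
            class = "coverage_profile")
}
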