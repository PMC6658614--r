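# Detection of candidate stable intronic sequence RNAs (sisRNAs): read pairs
# are kept when at least one mate overlaps a single intron by more than a
# minimum number of nucleotides; per-intron evidence and coverage then drive
# candidate-interval calling and polyA-signal scanning.

# Overlap of one record's aligned blocks with each intron: numeric vector,
# one entry per intron (transcript order).
record_intron_overlap <- function(pos0, cigar, model) {
  blocks <- aligned_blocks(pos0, cigar)
  intr <- model$introns
  vapply(seq_len(nrow(intr)), function(i) {
    sum(overlap_width(blocks[, 1], blocks[, 2], intr$start[i], intr$end[i]))
  }, numeric(1))
}

#' Intron-overlap filter for a read pair
#'
#' Implements the paired-read mapping rule for intronic transcription: a pair
#' is accepted when at least one mate's aligned blocks overlap a single intron
#' by more than `min_overlap` nucleotides (strictly greater: the default
#' `min_overlap = 10` accepts overlaps of 11 nt and rejects 10 nt); the other
#' mate can have any location. The pair is attributed to the intron of
#' maximal overlap (ties to the lower intron index).
#'
#' @param rec1,rec2 One-row alignment records (mates of one fragment).
#' @param model A `gene_model`.
#' @param min_overlap Overlap must exceed this many nt (default 10).
#' @return A list: `accepted` (logical), `intron_id` (1-based or NA),
#'   `reason` (`"ok"`, `"different_chromosomes"`, `"insufficient_overlap"`).
#' @export
intron_overlap_filter <- function(rec1, rec2, model, min_overlap = 10) {
  mapped <- list(rec1, rec2)
  mapped <- mapped[!vapply(mapped, function(r) is_unmapped(r$flag), logical(1))]
  if (length(mapped) == 0L) {
    return(list(accepted = FALSE, intron_id = NA_integer_, reason = "unmapped"))
  }
  chroms <- unique(vapply(mapped, function(r) r$rname, ""))
  if (length(chroms) > 1L) {
    return(list(accepted = FALSE, intron_id = NA_integer_,
                reason = "different_chromosomes"))
  }
  if (chroms != model$chrom) {
    return(list(accepted = FALSE, intron_id = NA_integer_, reason = "other_chromosome"))
  }
  # per-mate overlaps, not summed across mates: the rule is about one read
  per_mate <- vapply(mapped, function(r) record_intron_overlap(r$pos0, r$cigar, model),
                     numeric(nrow(model$introns)))
  per_mate <- matrix(per_mate, nrow = nrow(model$introns))
  best_per_intron <- apply(per_mate, 1L, max)
  if (max(best_per_intron) > min_overlap) {
    list(accepted = TRUE, intron_id = which.max(best_per_intron), reason = "ok")
  } else {
    list(accepted = FALSE, intron_id = NA_integer_, reason = "insufficient_overlap")
  }
}

#' Per-intron read-pair evidence and coverage
#'
#' Groups primary alignments into pairs by read name, applies
#' [intron_overlap_filter()], and accumulates per-intron qualifying-pair
#' counts plus coverage profiles over each intron from the accepted pairs'
#' aligned blocks. Every accepted pair is attributed to exactly one intron.
#'
#' @param records Alignment record data frame (both mates present).
#' @param model A `gene_model`.
#' @param min_overlap Strict overlap threshold in nt (default 10).
#' @return A list: `evidence` (data frame `intron_id`, `qualifying_pairs`),
#'   `coverage` (list of `coverage_profile`, one per intron, from accepted
#'   pairs), `accepted` (character vector of accepted read names),
#'   `n_examined`, `n_rejected`.
#' @export
intron_read_counts <- function(records, model, min_overlap = 10) {
  records <- primary_mapped(records)
  n_intr <- nrow(model$introns)
  counts <- integer(n_intr)
  accepted_names <- character(0)
  pairs <- split(seq_len(nrow(records)), records$qname)
  for (idx in pairs) {
    r1 <- records[idx[1], ]
    r2 <- if (length(idx) > 1L) records[idx[2], ] else r1
    res <- intron_overlap_filter(r1, r2, model, min_overlap)
    if (res$accepted) {
      counts[res$intron_id] <- counts[res$intron_id] + 1L
      accepted_names <- c(accepted_names, r1$qname)
    }
  }
  acc <- records[records$qname %in% accepted_names, , drop = FALSE]
  coverage <- lapply(seq_len(n_intr), function(i) {
    coverage_profile(acc, model$chrom, model$introns$start[i], model$introns$end[i])
  })
  list(
    evidence = data.frame(intron_id = seq_len(n_intr), qualifying_pairs = counts),
    coverage = coverage,
    accepted = accepted_names,
    n_examined = length(pairs),
    n_rejected = length(pairs) - length(accepted_names)
  )
}

#' Call candidate sisRNA intervals from a coverage profile
#'
#' Maximal runs of positions with `depth >= min_depth`, allowing internal
#' low-coverage gaps of at most `max_gap` positions, kept when the run length
#' reaches `min_length`. Intervals are reported in genomic order with their
#' mean depth.
#'
#' @param coverage A `coverage_profile`.
#' @param min_depth Depth threshold (raw reads per position).
#' @param min_length Minimum candidate length in nt (default 100).
#' @param max_gap Maximum internal below-threshold gap in nt (default 50).
#' @return A data frame: `start`, `end` (genomic, 0-based half-open),
#'   `length`, `mean_depth`.
#' @export
call_candidate_regions <- function(coverage, min_depth, min_length = 100,
                                   max_gap = 50) {
  stopifnot(inherits(coverage, "coverage_profile"), min_depth > 0)
  above <- coverage$depth >= min_depth
  if (!any(above)) {
    return(data.frame(start = numeric(), end = numeric(), length = numeric(),
                      mean_depth = numeric()))
  }
  pos <- which(above)
  # merge consecutive above-threshold positions separated by <= max_gap + 1
  brk <- c(TRUE, diff(pos) > max_gap + 1)
  grp <- cumsum(brk)
  out <- lapply(split(pos, grp), function(p) {
    s <- min(p); e <- max(p) + 1L
    data.frame(start = coverage$start + s - 1,
               end = coverage$start + e - 1,
               length = e - s,
               mean_depth = mean(coverage$depth[s:(e - 1L)]))
  })
  out <- do.call(rbind, out)
  out <- out[out$length >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' Default candidate-calling depth threshold
#'
#' Five times the median intronic coverage (the background against which a
#' sisRNA must stand out), floored at 2 reads.
#'
#' @param coverage A `coverage_profile` over the gene span.
#' @param model A `gene_model` (its introns define the background positions).
#' @return A numeric threshold.
#' @export
default_min_depth <- function(coverage, model) {
  intr <- model$introns
  idx <- unlist(lapply(seq_len(nrow(intr)), function(i) {
    s <- max(intr$start[i], coverage$start); e <- min(intr$end[i], coverage$end)
    if (s < e) (s - coverage$start + 1):(e - coverage$start) else integer(0)
  }))
  max(2, 5 * stats::median(coverage$depth[idx]))
}

#' Scan for the canonical polyA signal near a sequence 3' end
#'
#' Finds every occurrence (overlapping ones included) of the hexamer
#' `AATAAA` whose start lies within the final `window` nucleotides of the
#' given, already strand-oriented, sequence. `N` positions never match.
#'
#' @param sequence Nucleotide string over `{A, C, G, T, N}` (sense strand).
#' @param window Size of the 3'-terminal window in nt (default 50).
#' @return Integer vector of 0-based start positions within `sequence`.
#' @export
scan_polya_signal <- function(sequence, window = 50) {
  len <- nchar(sequence)
  stopifnot(window <= len)
  hits <- Biostrings::matchPattern("AATAAA", Biostrings::DNAString(sequence),
                                   fixed = TRUE)
  starts0 <- IRanges::start(hits) - 1L
  sort(starts0[starts0 >= len - window])
}

#' Abundance ratio between two sisRNA candidates
#'
#' @param pairs_a,pairs_b Supporting-pair counts of the two candidates.
#' @return A list: `ratio` (a/b; `Inf` with `infinite = TRUE` when b = 0),
#'   `pairs_a`, `pairs_b`.
#' @export
abundance_ratio <- function(pairs_a, pairs_b) {
  stopifnot(pairs_a >= 0, pairs_b >= 0)
  if (pairs_b == 0) {
    return(list(ratio = Inf, infinite = TRUE, pairs_a = pairs_a, pairs_b = pairs_b))
  }
  list(ratio = pairs_a / pairs_b, infinite = FALSE,
       pairs_a = pairs_a, pairs_b = pairs_b)
}

#' Write candidate intervals as BED6
#'
#' @param candidates Data frame from [call_candidate_regions()].
#' @param chrom Chromosome name.
#' @param path Output path.
#' @param strand Strand of the host gene.
#' @return `path`, invisibly.
#' @export
write_candidates_bed6 <- function(candidates, chrom, path, strand = "+") {
  lines <- sprintf("%s\t%d\t%d\tsisRNA_candidate_%d\t%d\t%s",
                   chrom, candidates$start, candidates$end,
                   seq_len(nrow(candidates)),
                   pmin(1000L, as.integer(round(candidates$mean_depth))),
                   strand)
  writeLines(lines, path)
  invisible(path)
}
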