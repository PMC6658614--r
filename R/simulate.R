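# Seeded simulator: a multi-exon gene transcribed as correctly spliced mRNA,
# minor single-exon-skip isoforms, polyadenylated intronic (sisRNA)
# transcripts, and unspliced pre-mRNA, sequenced as paired-end fragments and
# emitted as spliced SAM alignments with a full ground-truth ledger. The
# defaults emulate a 14-exon retinal gene: junction-level skip rates in the
# half-percent-to-7% range concentrated on exons 2, 3 and 7, a dominant
# polyadenylated sisRNA at the 5' end of the longest intron (intron 10) and a
# 10-fold less abundant one in the last intron.

#' Simulation configuration
#'
#' @param n_exons Number of exons (>= 2).
#' @param exon_lengths,intron_lengths Lengths in nt (introns: `n_exons - 1`).
#' @param skip_rates Per-exon single-exon-skip probability, length `n_exons`;
#'   terminal exons must be 0. Entry e is the probability that a transcript
#'   molecule lacks exon e.
#' @param sisrna_specs List of sisRNA specifications, each a list with
#'   `intron_id`, `start_offset` (nt into the intron), `length`,
#'   `relative_abundance` (transcript abundance relative to mRNA = 1), and
#'   `polyadenylated` flag.
#' @param premrna_fraction Probability a fragment derives from unspliced
#'   pre-mRNA.
#' @param n_fragments Number of read pairs to generate.
#' @param fragment_mean,fragment_sd Fragment length distribution (normal,
#'   truncated below at `read_length`).
#' @param read_length Read length in nt.
#' @param seed Integer seed (mandatory; the whole bundle is deterministic
#'   under it).
#' @param gene_offset Genomic start of exon 1.
#' @param chrom,gene_id Labels.
#' @param polya_window 3'-terminal window within which the planted AATAAA is
#'   the only occurrence for each polyadenylated sisRNA.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_exons = 14L,
                       exon_lengths = c(120, 140, 110, 130, 120, 150, 110,
                                        140, 120, 100, 130, 120, 110, 600),
                       intron_lengths = c(300, 280, 260, 320, 300, 340, 280,
                                          260, 420, 660, 260, 240, 200),
                       skip_rates = NULL,
                       sisrna_specs = list(
                         list(intron_id = 10L, start_offset = 20, length = 460,
                              relative_abundance = 0.5, polyadenylated = TRUE),
                         list(intron_id = 13L, start_offset = 10, length = 150,
                              relative_abundance = 0.05, polyadenylated = TRUE)
                       ),
                       premrna_fraction = 0.02,
                       n_fragments = 5000L,
                       fragment_mean = 250, fragment_sd = 30,
                       read_length = 100L,
                       seed,
                       gene_offset = 500L, chrom = "chrS", gene_id = "simgene",
                       polya_window = 50L) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(skip_rates)) {
    skip_rates <- numeric(n_exons)
    if (n_exons >= 8L) {
      skip_rates[c(2L, 3L, 7L)] <- c(0.040, 0.055, 0.070)
      skip_rates[c(4L, min(12L, n_exons - 2L))] <- 0.005
    } else if (n_exons > 2L) {
      skip_rates[2L] <- 0.05
    }
  }
  stopifnot(n_exons >= 2L,
            length(exon_lengths) == n_exons,
            length(intron_lengths) == n_exons - 1L,
            all(exon_lengths > 0), all(intron_lengths > 0),
            length(skip_rates) == n_exons,
            all(skip_rates >= 0), all(skip_rates <= 1),
            skip_rates[1] == 0, skip_rates[n_exons] == 0,
            sum(skip_rates) <= 1,
            premrna_fraction >= 0, premrna_fraction <= 1,
            n_fragments >= 1, fragment_mean > 0, fragment_sd >= 0,
            read_length >= 20)
  for (s in sisrna_specs) {
    stopifnot(all(c("intron_id", "start_offset", "length",
                    "relative_abundance", "polyadenylated") %in% names(s)))
    if (s$intron_id < 1 || s$intron_id > n_exons - 1L) {
      stop("sisRNA spec references intron ", s$intron_id, " outside the gene")
    }
    if (s$start_offset + s$length > intron_lengths[s$intron_id]) {
      stop("sisRNA in intron ", s$intron_id, " exceeds the intron bounds (",
           s$start_offset, " + ", s$length, " > ",
           intron_lengths[s$intron_id], ")")
    }
    if (s$length < read_length) {
      stop("sisRNA in intron ", s$intron_id, " is shorter than the read length")
    }
  }
  structure(list(
    n_exons = as.integer(n_exons), exon_lengths = exon_lengths,
    intron_lengths = intron_lengths, skip_rates = skip_rates,
    sisrna_specs = sisrna_specs, premrna_fraction = premrna_fraction,
    n_fragments = as.integer(n_fragments), fragment_mean = fragment_mean,
    fragment_sd = fragment_sd, read_length = as.integer(read_length),
    seed = as.integer(seed), gene_offset = as.integer(gene_offset),
    chrom = chrom, gene_id = gene_id, polya_window = as.integer(polya_window)
  ), class = "sim_config")
}

# Genomic interval of a sisRNA spec given the model (plus strand).
sisrna_interval <- function(model, spec) {
  intr <- model$introns[spec$intron_id, ]
  c(start = intr$start + spec$start_offset,
    end = intr$start + spec$start_offset + spec$length)
}

#' Simulate the gene model and genomic sequence
#'
#' Builds the gene model from the configured exon/intron lengths and draws a
#' random genomic sequence, deterministic under the seed. For every
#' polyadenylated sisRNA, the hexamer AATAAA is planted ending exactly at the
#' candidate's 3' end and scrubbed from the rest of that candidate's
#' 3'-terminal window, so motif-scanning results are unambiguous by
#' construction. Simulation is on the plus strand.
#'
#' @param config A `sim_config`.
#' @return A list: `model` (a `gene_model`), `sequence` (character, the full
#'   chromosome), `chrom_len`.
#' @export
simulate_gene <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_exons
  starts <- numeric(n); ends <- numeric(n)
  pos <- config$gene_offset
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + config$exon_lengths[i]
    pos <- ends[i] + if (i < n) config$intron_lengths[i] else 0
  }
  model <- gene_model(config$gene_id, config$chrom, starts, ends, strand = "+")
  chrom_len <- ends[n] + 500L

  seqv <- with_seed(config$seed, {
    sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  })
  for (spec in config$sisrna_specs) {
    if (!isTRUE(spec$polyadenylated)) next
    iv <- sisrna_interval(model, spec)
    win_start <- iv["end"] - config$polya_window  # 0-based
    planted_start <- iv["end"] - 6
    repeat {
      s <- paste(seqv[(win_start + 1):iv["end"]], collapse = "")
      m <- gregexpr("AATAAA", s, fixed = TRUE)[[1]]
      m <- m[m > 0]
      offending <- win_start + m - 1  # 0-based genomic starts
      offending <- offending[offending != planted_start]
      if (length(offending) == 0) break
      # mutate the first base of the offending match that lies outside the
      # planted hexamer
      for (o in offending) {
        mutable <- setdiff(o:(o + 5), planted_start:(planted_start + 5))
        seqv[mutable[1] + 1] <- "C"
      }
    }
    seqv[(planted_start + 1):(planted_start + 6)] <-
      c("A", "A", "T", "A", "A", "A")
    # re-check: planting may have created an upstream overlapper
    repeat {
      s <- paste(seqv[(win_start + 1):iv["end"]], collapse = "")
      m <- gregexpr("AATAAA", s, fixed = TRUE)[[1]]
      m <- m[m > 0]
      offending <- win_start + m - 1
      offending <- offending[offending != planted_start]
      if (length(offending) == 0) break
      for (o in offending) {
        mutable <- setdiff(o:(o + 5), planted_start:(planted_start + 5))
        seqv[mutable[1] + 1] <- "C"
      }
    }
  }
  list(model = model, sequence = paste(seqv, collapse = ""),
       chrom_len = chrom_len)
}

# Project a transcript-space interval [t_start, t_end) onto genomic blocks
# (matrix start/end) given the transcript's genomic blocks in transcript
# order; returns list(pos0, cigar, blocks).
project_to_genome <- function(t_start, t_end, blocks) {
  lens <- blocks[, 2] - blocks[, 1]
  cum <- c(0, cumsum(lens))
  segs <- list()
  for (b in seq_len(nrow(blocks))) {
    s <- max(t_start, cum[b]); e <- min(t_end, cum[b + 1])
    if (s < e) {
      segs[[length(segs) + 1L]] <- c(blocks[b, 1] + (s - cum[b]),
                                     blocks[b, 1] + (e - cum[b]))
    }
  }
  g <- do.call(rbind, segs)
  cig <- character(0)
  for (i in seq_len(nrow(g))) {
    if (i > 1L) cig <- c(cig, sprintf("%dN", as.integer(g[i, 1] - g[i - 1, 2])))
    cig <- c(cig, sprintf("%dM", as.integer(g[i, 2] - g[i, 1])))
  }
  list(pos0 = g[1, 1], cigar = paste(cig, collapse = ""), blocks = g)
}

#' Simulate paired-end spliced alignments with ground truth
#'
#' Each fragment is drawn from unspliced pre-mRNA (probability
#' `premrna_fraction`), a sisRNA transcript, or the mRNA pool (remaining mass,
#' split proportionally to the sisRNAs' relative abundances); within the mRNA
#' pool the molecule is the correctly spliced isoform or a single-exon-skip
#' isoform per `skip_rates`. Fragment coordinates are projected to genomic
#' space, producing CIGAR strings with N gaps at splice junctions. The truth
#' ledger records every fragment's origin, the per-junction true (k, n) as
#' observed per read (every junction a read spans with at least 1 aligned nt
#' on each side), and per-sisRNA fragment counts.
#'
#' @param model,sequence Output of [simulate_gene()].
#' @param config The same `sim_config`.
#' @return A list: `records` (SAM-style data frame, two rows per fragment),
#'   `truth` (list: `junctions` data frame `junction_id`, `k`, `n`;
#'   `sisrna` data frame `sisrna_id`, `intron_id`, `start`, `end`,
#'   `fragments`; `fragments` per-fragment origin table; `n_resampled`),
#'   `seqinfo` for [write_sam()].
#' @export
simulate_reads <- function(model, sequence, config) {
  stopifnot(inherits(config, "sim_config"))
  n_ex <- config$n_exons
  rl <- config$read_length
  ex <- model$exons

  # isoform catalogue: chains over exon indices, or contiguous genomic spans
  isoforms <- list()
  isoforms[["mRNA"]] <- list(kind = "chain", chain = seq_len(n_ex))
  for (e in which(config$skip_rates > 0)) {
    isoforms[[paste0("skip_exon", e)]] <- list(kind = "chain",
                                               chain = setdiff(seq_len(n_ex), e))
  }
  sis_ids <- character(0)
  for (i in seq_along(config$sisrna_specs)) {
    spec <- config$sisrna_specs[[i]]
    iv <- sisrna_interval(model, spec)
    id <- paste0("sisRNA_intron", spec$intron_id)
    sis_ids <- c(sis_ids, id)
    isoforms[[id]] <- list(kind = "span", start = iv["start"], end = iv["end"])
  }
  isoforms[["premRNA"]] <- list(kind = "span",
                                start = model$span["start"],
                                end = model$span["end"])

  # genomic blocks and lengths per isoform
  iso_blocks <- lapply(isoforms, function(iso) {
    if (iso$kind == "chain") {
      cbind(start = ex$start[iso$chain], end = ex$end[iso$chain])
    } else {
      cbind(start = unname(iso$start), end = unname(iso$end))
    }
  })
  iso_len <- vapply(iso_blocks, function(b) sum(b[, 2] - b[, 1]), numeric(1))

  # category probabilities
  rel <- vapply(config$sisrna_specs, `[[`, numeric(1), "relative_abundance")
  p_pre <- config$premrna_fraction
  wts <- c(mRNApool = 1, rel)
  p_cat <- c((1 - p_pre) * wts / sum(wts), premRNA = p_pre)
  names(p_cat) <- c("mRNApool", sis_ids, "premRNA")
  p_skip <- config$skip_rates
  p_normal <- 1 - sum(p_skip)

  out <- with_seed(config$seed + 1L, {
    n_frag <- config$n_fragments
    origin <- character(n_frag)
    n_resampled <- 0L
    nr <- 2L * n_frag
    v_qname <- character(nr); v_flag <- integer(nr); v_pos0 <- numeric(nr)
    v_cigar <- character(nr); v_pnext0 <- numeric(nr); v_tlen <- numeric(nr)
    v_seq <- character(nr)
    adj <- integer(n_ex - 1L); skp <- integer(n_ex - 1L)
    sis_count <- stats::setNames(integer(length(sis_ids)), sis_ids)

    cats <- sample(names(p_cat), n_frag, replace = TRUE, prob = p_cat)
    for (f in seq_len(n_frag)) {
      iso_name <- cats[f]
      if (iso_name == "mRNApool") {
        u <- stats::runif(1)
        if (u < p_normal || all(p_skip == 0)) {
          iso_name <- "mRNA"
        } else {
          cumr <- p_normal + cumsum(p_skip)
          e <- which(u <= cumr)[1]
          iso_name <- paste0("skip_exon", e)
        }
      }
      origin[f] <- iso_name
      blocks <- iso_blocks[[iso_name]]
      L <- iso_len[[iso_name]]

      flen <- round(stats::rnorm(1, config$fragment_mean, config$fragment_sd))
      tries <- 0L
      while ((flen > L || flen < rl) && tries < 10L) {
        flen <- round(stats::rnorm(1, config$fragment_mean, config$fragment_sd))
        tries <- tries + 1L
        n_resampled <- n_resampled + 1L
      }
      flen <- min(max(flen, rl), L)
      st <- floor(stats::runif(1, 0, L - flen + 1))
      mates <- list(c(st, st + rl), c(st + flen - rl, st + flen))

      if (iso_name %in% sis_ids) sis_count[iso_name] <- sis_count[iso_name] + 1L

      qname <- sprintf("frag%06d", f)
      proj <- vector("list", 2L)
      for (m in 1:2) {
        proj[[m]] <- project_to_genome(mates[[m]][1], mates[[m]][2], blocks)
        # junction truth per read (chain isoforms only)
        iso <- isoforms[[iso_name]]
        if (iso$kind == "chain") {
          lens <- blocks[, 2] - blocks[, 1]
          cum <- cumsum(lens)
          ch <- iso$chain
          for (j in seq_len(length(ch) - 1L)) {
            if (mates[[m]][1] < cum[j] && mates[[m]][2] > cum[j]) {
              up <- ch[j]; dn <- ch[j + 1L]
              if (dn == up + 1L) adj[up] <- adj[up] + 1L
              else if (dn == up + 2L) skp[up] <- skp[up] + 1L
            }
          }
        }
      }
      tl <- proj[[2]]$blocks[nrow(proj[[2]]$blocks), 2] - proj[[1]]$pos0
      for (m in 1:2) {
        p <- proj[[m]]
        sq <- paste(vapply(seq_len(nrow(p$blocks)), function(b) {
          substr(sequence, p$blocks[b, 1] + 1, p$blocks[b, 2])
        }, ""), collapse = "")
        i <- 2L * (f - 1L) + m
        v_qname[i] <- qname
        v_flag[i] <- if (m == 1L) 99L else 147L
        v_pos0[i] <- p$pos0
        v_cigar[i] <- p$cigar
        v_pnext0[i] <- proj[[if (m == 1L) 2L else 1L]]$pos0
        v_tlen[i] <- if (m == 1L) tl else -tl
        v_seq[i] <- sq
      }
    }
    recs <- data.frame(
      qname = v_qname, flag = v_flag, rname = config$chrom, pos0 = v_pos0,
      mapq = 60L, cigar = v_cigar, rnext = "=", pnext0 = v_pnext0,
      tlen = v_tlen, seq = v_seq, stringsAsFactors = FALSE
    )
    list(recs = recs, origin = origin, adj = adj, skp = skp,
         sis_count = sis_count, n_resampled = n_resampled)
  })

  records <- out$recs
  sis_truth <- do.call(rbind, lapply(seq_along(config$sisrna_specs), function(i) {
    spec <- config$sisrna_specs[[i]]
    iv <- sisrna_interval(model, spec)
    data.frame(sisrna_id = sis_ids[i], intron_id = spec$intron_id,
               start = unname(iv["start"]), end = unname(iv["end"]),
               fragments = unname(out$sis_count[sis_ids[i]]),
               stringsAsFactors = FALSE)
  }))
  truth <- list(
    junctions = data.frame(junction_id = seq_len(n_ex - 1L),
                           k = out$skp, n = out$adj + out$skp),
    sisrna = sis_truth,
    fragments = data.frame(fragment = seq_len(config$n_fragments),
                           origin = out$origin, stringsAsFactors = FALSE),
    n_resampled = out$n_resampled
  )
  seqinfo <- stats::setNames(nchar(sequence), config$chrom)
  list(records = records, truth = truth, seqinfo = seqinfo)
}

#' Simulate a complete analysis bundle on disk
#'
#' Runs [simulate_gene()] and [simulate_reads()] and writes SAM, FASTA, BED12
#' and truth TSV files under `dir`.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   `model` and `truth`.
#' @export
simulate_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gene <- simulate_gene(config)
  reads <- simulate_reads(gene$model, gene$sequence, config)
  paths <- list(
    sam = file.path(dir, "reads.sam"),
    fasta = file.path(dir, "genome.fa"),
    bed = file.path(dir, "gene.bed"),
    truth_junctions_tsv = file.path(dir, "truth_junctions.tsv"),
    truth_sisrna_tsv = file.path(dir, "truth_sisrna.tsv")
  )
  write_sam(reads$records, paths$sam, seqinfo = reads$seqinfo)
  utils::write.table(reads$truth$junctions, paths$truth_junctions_tsv,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(reads$truth$sisrna, paths$truth_sisrna_tsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  seqs <- Biostrings::DNAStringSet(stats::setNames(gene$sequence, config$chrom))
  Biostrings::writeXStringSet(seqs, paths$fasta)
  write_gene_bed12(gene$model, paths$bed)
  invisible(c(paths, list(model = gene$model, truth = reads$truth,
                          sequence = gene$sequence)))
}

#' Simulate per-sample expression summaries
#'
#' Draws sample-level raw-count summaries for correlation studies: exonic
#' depth is lognormal across samples; in `"coupled"` mode the intronic sisRNA
#' depth is proportional to the exonic depth with multiplicative noise of the
#' given coefficient of variation (emulating a sisRNA whose abundance tracks
#' its host mRNA), while in `"null"` mode it is drawn independently. Skip
#' counts are Poisson and independent of the sisRNA signal in both modes.
#'
#' @param n_samples Number of samples (default 16).
#' @param mode `"coupled"` or `"null"`.
#' @param seed Integer seed.
#' @param mean_exon_depth Median exonic depth across samples.
#' @param sdlog Log-scale spread of exonic depth.
#' @param cv Coefficient of variation of the proportionality noise.
#' @param sisrna_ratio sisRNA depth as a fraction of exonic depth (coupled
#'   mode).
#' @return A data frame: `sample_id`, `exon8_depth`, `sisrna_depth`,
#'   `exon7_skips`.
#' @export
simulate_sample_summaries <- function(n_samples = 16L,
                                      mode = c("coupled", "null"),
                                      seed = 1L,
                                      mean_exon_depth = 500,
                                      sdlog = 0.8, cv = 0.2,
                                      sisrna_ratio = 0.1) {
  mode <- match.arg(mode)
  with_seed(seed, {
    exon <- stats::rlnorm(n_samples, log(mean_exon_depth), sdlog)
    noise <- stats::rgamma(n_samples, shape = 1 / cv^2, rate = 1 / cv^2)
    sis <- if (mode == "coupled") {
      sisrna_ratio * exon * noise
    } else {
      stats::rlnorm(n_samples, log(mean_exon_depth * sisrna_ratio), sdlog)
    }
    skips <- stats::rpois(n_samples, 10)
    data.frame(sample_id = sprintf("s%02d", seq_len(n_samples)),
               exon8_depth = exon, sisrna_depth = sis, exon7_skips = skips,
               stringsAsFactors = FALSE)
  })
}
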