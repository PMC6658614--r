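# End-to-end orchestration: count -> compare -> mixture -> sisrna ->
# correlate, each stage writing a TSV under the configured output directory,
# plus a JSON run manifest (parameters and input checksums). Stages are also
# usable standalone on TSV intermediates; in particular a hand-written
# junction-count table can be injected with `counts`, bypassing alignment
# processing entirely.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

pipeline_error <- function(msg) {
  stop(structure(class = c("sisplice_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Run the full analysis pipeline
#'
#' @param config A named list:
#'   \describe{
#'     \item{out_dir}{Output directory (required).}
#'     \item{alignments}{Named character vector of SAM paths, one per library
#'       (1 or 2 libraries), or NULL when `counts` is given.}
#'     \item{annotation}{BED12/GFF3 path (required with `alignments`).}
#'     \item{gene_id}{Gene to load from the annotation.}
#'     \item{sequence}{FASTA path for polyA scanning (optional).}
#'     \item{counts}{TSV of `upstream_exon`, `library`, `n_correct`, `n_skip`
#'       — comparison + mixture stages only.}
#'     \item{summaries}{TSV of per-sample summaries for the correlate stage
#'       (optional); `pairings` a list of column pairs.}
#'     \item{min_overhang, tolerance, min_overlap, min_length, max_gap,
#'       mixture_C_max, mixture_B, alpha, seed}{Stage parameters; all have
#'       the package defaults.}
#'   }
#' @return Invisibly, a named list of written report paths.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(
    alignments = NULL, annotation = NULL, gene_id = NULL, sequence = NULL,
    counts = NULL, summaries = NULL,
    pairings = list(c("exon8_depth", "sisrna_depth"),
                    c("sisrna_depth", "exon7_skips")),
    min_overhang = 5, tolerance = 0, min_overlap = 10,
    min_length = 100, max_gap = 50,
    mixture_C_max = 5L, mixture_B = 199L, alpha = 0.05, seed = 1L,
    mixture_library = NULL, verbose = TRUE
  ), config)
  if (is.null(cfg$out_dir)) pipeline_error("out_dir is required")
  note <- function(...) if (isTRUE(cfg$verbose)) message("[sisplice] ", ...)

  # validate inputs before any stage runs
  inputs <- as.character(c(cfg$alignments, cfg$annotation, cfg$sequence,
                           cfg$counts, cfg$summaries))
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) {
    pipeline_error(paste("missing input file(s):",
                         paste(missing_in, collapse = ", ")))
  }
  if (is.null(cfg$counts) && (is.null(cfg$alignments) || is.null(cfg$annotation))) {
    pipeline_error("either `counts` or both `alignments` and `annotation` are required")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()

  # stage: count (or inject counts)
  model <- NULL
  if (!is.null(cfg$counts)) {
    note("counts: injecting ", cfg$counts)
    counts <- utils::read.delim(cfg$counts, stringsAsFactors = FALSE)
    tables <- split(counts, counts$library)
  } else {
    model <- load_gene_model(cfg$annotation, cfg$gene_id)
    tables <- list()
    for (lib in names(cfg$alignments)) {
      note("count: library ", lib)
      recs <- read_sam(cfg$alignments[[lib]])
      tab <- count_junctions(recs, model, min_overhang = cfg$min_overhang,
                             tolerance = cfg$tolerance, library_id = lib)
      tables[[lib]] <- tab
      reports[[paste0("counts_", lib)]] <-
        write_tsv(cbind(tab, fraction = skip_fraction(tab$n_correct, tab$n_skip)),
                  file.path(cfg$out_dir, paste0("counts_", lib, ".tsv")))
    }
  }

  # stage: compare (needs exactly 2 libraries)
  if (length(tables) == 2L) {
    note("compare: ", paste(names(tables), collapse = " vs "))
    ta <- tables[[1]]; tb <- tables[[2]]
    cmp <- compare_libraries(ta, tb)
    reports$comparison <- write_tsv(cmp, file.path(cfg$out_dir, "comparison.tsv"))
    reports$skip_table <- write_tsv(
      render_skip_table(cmp, labels = names(tables)),
      file.path(cfg$out_dir, "skip_table.tsv"))
  }

  # stage: mixture; `mixture_library` picks the library, default the last one
  mix_lib <- if (!is.null(cfg$mixture_library)) cfg$mixture_library else length(tables)
  mix_tab <- tables[[mix_lib]]
  if (is.null(mix_tab)) pipeline_error(paste("mixture_library not found:", mix_lib))
  obs <- data.frame(junction_id = mix_tab$upstream_exon,
                    k = mix_tab$n_skip,
                    n = mix_tab$n_correct + mix_tab$n_skip)
  obs <- obs[obs$n >= 1, , drop = FALSE]
  note("mixture: ", nrow(obs), " junction observations")
  fit <- select_classes(obs, C_max = cfg$mixture_C_max, alpha = cfg$alpha,
                        seed = cfg$seed, B = cfg$mixture_B)
  assign <- assign_classes(fit)
  assign$q_class <- fit$probs[assign$class]
  reports$mixture <- write_tsv(assign, file.path(cfg$out_dir, "mixture.tsv"))
  reports$mixture_trace <- write_tsv(
    data.frame(n_classes = fit$n_classes, log_likelihood = fit$log_likelihood,
               adequate = fit$adequate,
               q = paste(signif(fit$probs, 6), collapse = ","),
               w = paste(signif(fit$weights, 6), collapse = ",")),
    file.path(cfg$out_dir, "mixture_model.tsv"))

  # stage: sisrna (alignment mode only)
  if (!is.null(cfg$alignments) && !is.null(model)) {
    for (lib in names(cfg$alignments)) {
      note("sisrna: library ", lib)
      recs <- read_sam(cfg$alignments[[lib]])
      irc <- intron_read_counts(recs, model, min_overlap = cfg$min_overlap)
      reports[[paste0("introns_", lib)]] <-
        write_tsv(irc$evidence, file.path(cfg$out_dir, paste0("introns_", lib, ".tsv")))
      acc <- recs[recs$qname %in% irc$accepted, , drop = FALSE]
      cov <- coverage_profile(acc, model$chrom, model$span["start"], model$span["end"])
      cands <- call_candidate_regions(cov, default_min_depth(cov, model),
                                      min_length = cfg$min_length,
                                      max_gap = cfg$max_gap)
      if (nrow(cands) && !is.null(cfg$sequence)) {
        seqs <- Biostrings::readDNAStringSet(cfg$sequence)
        chrom_seq <- as.character(seqs[[model$chrom]])
        # scan to 10 nt past the called edge: coverage erosion can shave the
        # candidate boundary a few nt short of the true cleavage site
        cands$polya_hits <- vapply(seq_len(nrow(cands)), function(i) {
          e <- min(cands$end[i] + 10, nchar(chrom_seq))
          s <- substr(chrom_seq, cands$start[i] + 1, e)
          hits <- scan_polya_signal(s, window = min(60, nchar(s)))
          paste(hits + cands$start[i], collapse = ",")
        }, "")
      }
      # supporting pairs per candidate: qualifying pairs of the host intron
      cands$supporting_pairs <- vapply(seq_len(nrow(cands)), function(i) {
        ov <- overlap_width(cands$start[i], cands$end[i],
                            model$introns$start, model$introns$end)
        if (all(ov == 0)) 0L else irc$evidence$qualifying_pairs[which.max(ov)]
      }, integer(1))
      reports[[paste0("sisrna_", lib)]] <-
        write_tsv(cands, file.path(cfg$out_dir, paste0("sisrna_", lib, ".tsv")))
      if (nrow(cands)) {
        write_candidates_bed6(cands, model$chrom,
                              file.path(cfg$out_dir, paste0("sisrna_", lib, ".bed")),
                              strand = model$strand)
      }
    }
  }

  # stage: correlate (optional)
  if (!is.null(cfg$summaries)) {
    note("correlate: ", cfg$summaries)
    summ <- utils::read.delim(cfg$summaries, stringsAsFactors = FALSE)
    cors <- correlate_summaries(summ, cfg$pairings)
    reports$correlations <- write_tsv(cors, file.path(cfg$out_dir, "correlations.tsv"))
  }

  # manifest: every parameter affecting output + input checksums
  manifest <- list(
    package_version = as.character(utils::packageVersion("sisplice")),
    parameters = cfg[c("min_overhang", "tolerance", "min_overlap",
                       "min_length", "max_gap", "mixture_C_max", "mixture_B",
                       "alpha", "seed", "gene_id")],
    inputs = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  reports$manifest <- file.path(cfg$out_dir, "manifest.json")
  invisible(reports)
}
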