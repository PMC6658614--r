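test_that("the simulated gene satisfies all gene-model invariants", {
  cfg <- sim_config(seed = 2)
  g <- simulate_gene(cfg)
  expect_s3_class(g$model, "gene_model")
  expect_equal(nrow(g$model$exons), 14)
  expect_equal(nrow(g$model$introns), 13)
  expect_equal(nchar(g$sequence), g$chrom_len)

  # planted AATAAA is found by the scanner at each polyadenylated sisRNA 3'
  # end, and it is the only hit in the 3' window
  for (i in seq_along(cfg$sisrna_specs)) {
    spec <- cfg$sisrna_specs[[i]]
    intr <- g$model$introns[spec$intron_id, ]
    s <- intr$start + spec$start_offset
    e <- s + spec$length
    sis_seq <- substr(g$sequence, s + 1, e)
    expect_equal(scan_polya_signal(sis_seq, 50), spec$length - 6)
  }
})

test_that("infeasible geometry and missing seed are configuration errors", {
  expect_error(sim_config(seed = 1, sisrna_specs = list(
    list(intron_id = 10, start_offset = 600, length = 200,
         relative_abundance = 1, polyadenylated = TRUE))), "exceeds")
  expect_error(sim_config(seed = 1, sisrna_specs = list(
    list(intron_id = 99, start_offset = 0, length = 100,
         relative_abundance = 1, polyadenylated = TRUE))), "outside")
  expect_error(sim_config(), "seed is mandatory")
})

test_that("identical config and seed give byte-identical SAM output", {
  cfg <- sim_config(seed = 42, n_fragments = 150)
  g1 <- simulate_gene(cfg); r1 <- simulate_reads(g1$model, g1$sequence, cfg)
  g2 <- simulate_gene(cfg); r2 <- simulate_reads(g2$model, g2$sequence, cfg)
  expect_identical(g1$sequence, g2$sequence)
  f1 <- tempfile(); f2 <- tempfile()
  write_sam(r1$records, f1, r1$seqinfo)
  write_sam(r2$records, f2, r2$seqinfo)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("zero skip rate and no intronic transcription yield clean junctions", {
  cfg <- sim_config(seed = 8, n_fragments = 300, premrna_fraction = 0,
                    sisrna_specs = list(), skip_rates = numeric(14))
  g <- simulate_gene(cfg)
  sim <- simulate_reads(g$model, g$sequence, cfg)
  tab <- count_junctions(sim$records, g$model, min_overhang = 1)
  expect_true(all(tab$n_skip == 0))
  expect_true(all(sim$truth$junctions$k == 0))
})

test_that("the observed skip fraction tracks the configured rate", {
  # one skippable exon at 5%; enough fragments for > 2000 junction
  # observations at the flanking junction
  cfg <- sim_config(seed = 13, n_exons = 4,
                    exon_lengths = rep(150, 4), intron_lengths = rep(200, 3),
                    skip_rates = c(0, 0, 0.05, 0), sisrna_specs = list(),
                    premrna_fraction = 0, n_fragments = 6000)
  g <- simulate_gene(cfg)
  sim <- simulate_reads(g$model, g$sequence, cfg)
  truth <- sim$truth$junctions
  n2 <- truth$n[2]
  expect_gte(n2, 2000)
  frac <- truth$k[2] / n2
  se <- sqrt(0.05 * 0.95 / n2)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("emitted SAM parses back through the junction counter exactly", {
  cfg <- sim_config(seed = 21, n_fragments = 500)
  dir <- file.path(tempdir(), "bundle21")
  bundle <- simulate_bundle(cfg, dir)
  expect_true(all(file.exists(unlist(
    bundle[c("sam", "fasta", "bed", "truth_junctions_tsv", "truth_sisrna_tsv")]))))

  recs <- read_sam(bundle$sam)
  model <- load_gene_model(bundle$bed, cfg$gene_id)
  tab <- count_junctions(recs, model, min_overhang = 1, tolerance = 0)
  expect_equal(tab$n_skip, bundle$truth$junctions$k)
  expect_equal(tab$n_correct + tab$n_skip, bundle$truth$junctions$n)
})
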