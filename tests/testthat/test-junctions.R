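test_that("junction extraction walks the CIGAR reference-space correctly", {
  expect_equal(nrow(extract_junctions(rec("r", 1000, "50M"))), 0)

  j <- extract_junctions(rec("r", 100, "20M100N30M"))
  expect_equal(j$gap_start, 120)
  expect_equal(j$gap_end, 220)
  expect_equal(j$left_overhang, 20L)
  expect_equal(j$right_overhang, 30L)

  j2 <- extract_junctions(rec("r", 0, "10M5N10M3N10M"))
  expect_equal(j2$gap_start, c(10, 25))
  expect_equal(j2$gap_end, c(15, 28))
  expect_equal(j2$left_overhang, c(10L, 10L))
  expect_equal(j2$right_overhang, c(10L, 10L))

  # soft clips and insertions consume no reference; deletions do
  j3 <- extract_junctions(rec("r", 100, "5S10M2I3D50N10M"))
  expect_equal(j3$gap_start, 113)
  expect_equal(j3$gap_end, 163)
  expect_equal(j3$left_overhang, 10L)  # aligned M nt only; I and D excluded

  expect_error(extract_junctions(rec("r", 0, "10M5Q")), "malformed CIGAR")
})

test_that("CIGAR walk agrees with the GenomicAlignments reference-space oracle", {
  cigars <- c("50M", "20M100N30M", "10M5N10M3N10M", "5S10M2I3D50N10M",
              "3M1N3M1N3M1N3M", "100M500N100M")
  ga <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigars, ops = "N", pos = rep(101, length(cigars)))
  for (i in seq_along(cigars)) {
    j <- extract_junctions(rec("r", 100, cigars[i]))
    expect_equal(j$gap_start, BiocGenerics::start(ga[[i]]) - 1,
                 info = cigars[i])
    expect_equal(j$gap_end, BiocGenerics::end(ga[[i]]), info = cigars[i])
  }
})

test_that("gaps classify as adjacent, skip, or other against the model", {
  m <- toy_model()
  expect_equal(classify_junction(100, 200, m)[c("kind", "upstream_exon")],
               list(kind = "adjacent", upstream_exon = 1L))
  expect_equal(classify_junction(100, 400, m)[c("kind", "upstream_exon")],
               list(kind = "skip", upstream_exon = 1L))
  expect_equal(classify_junction(100, 450, m)$kind, "other")
  # tolerance admits near-boundary gaps
  expect_equal(classify_junction(102, 199, m, tolerance = 2)$kind, "adjacent")
  expect_equal(classify_junction(102, 199, m, tolerance = 0)$kind, "other")
})

test_that("count_junctions aggregates, filters overhangs, and preserves totals", {
  m <- toy_model()
  adj <- rec("a", 90, "10M100N10M")       # adjacent(1,2)
  skip <- rec("s", 90, "10M300N10M")      # skip(1,3)
  r <- recs(adj, adj, adj, skip)
  tab <- count_junctions(r, m, min_overhang = 5, library_id = "L")
  expect_equal(tab$n_correct, c(3, 0))
  expect_equal(tab$n_skip, c(1, 0))

  # a read with two N gaps increments two rows
  two <- rec("t", 95, "5M100N100M100N5M")
  tab2 <- count_junctions(two, m, min_overhang = 5)
  expect_equal(tab2$n_correct, c(1, 1))

  # overhang filter: 4 nt flank < min_overhang 5 excluded
  short <- rec("sh", 96, "4M100N30M")
  tab3 <- count_junctions(short, m, min_overhang = 5)
  expect_equal(sum(tab3$n_correct) + sum(tab3$n_skip), 0)
  expect_equal(attr(tab3, "n_filtered"), 1L)

  # empty stream: all-zero table with warning, not an error
  expect_warning(tab4 <- count_junctions(adj[0, ], m), "no usable")
  expect_equal(sum(tab4$n_correct) + sum(tab4$n_skip), 0)

  # unmatched junctions are tallied as other, never dropped silently
  other <- rec("o", 90, "10M310N10M")
  tab5 <- count_junctions(other, m, min_overhang = 5)
  expect_equal(attr(tab5, "n_other"), 1L)
  expect_equal(sum(tab5$n_correct) + sum(tab5$n_skip) + attr(tab5, "n_other"), 1)
})

test_that("counting is order-independent and conserves observations", {
  cfg <- sim_config(seed = 11, n_fragments = 400)
  g <- simulate_gene(cfg)
  sim <- simulate_reads(g$model, g$sequence, cfg)
  tab <- count_junctions(sim$records, g$model, min_overhang = 1)

  shuffled <- sim$records[sample(nrow(sim$records)), ]
  tab_sh <- count_junctions(shuffled, g$model, min_overhang = 1)
  expect_equal(tab_sh$n_correct, tab$n_correct)
  expect_equal(tab_sh$n_skip, tab$n_skip)

  # conservation: adjacent + skip + other = all observations passing filter
  n_gaps <- sum(vapply(seq_len(nrow(sim$records)), function(i) {
    nrow(extract_junctions(sim$records[i, ]))
  }, numeric(1)))
  expect_equal(sum(tab$n_correct) + sum(tab$n_skip) + attr(tab, "n_other") +
                 attr(tab, "n_filtered"), n_gaps)
})

test_that("skip_fraction is skip/(correct+skip), NA when both are zero", {
  expect_equal(skip_fraction(189, 11), 0.055)
  expect_equal(skip_fraction(100, 0), 0)
  expect_equal(skip_fraction(0, 7), 1)
  expect_true(is.na(skip_fraction(0, 0)))
  expect_equal(skip_fraction(c(189, 0), c(11, 0)), c(0.055, NA))
})

test_that("coverage excludes N gaps and reflects exon dominance", {
  cov <- coverage_profile(rec("r", 10, "5M"), "chr1", 0, 20)
  expect_equal(cov$depth, c(rep(0, 10), rep(1, 5), rep(0, 5)))

  cov2 <- coverage_profile(rec("r", 0, "5M5N5M"), "chr1", 0, 15)
  expect_equal(cov2$depth, c(rep(1, 5), rep(0, 5), rep(1, 5)))

  # pure mRNA simulation: exonic depth >> intronic depth (here exactly 0)
  cfg <- sim_config(seed = 5, n_fragments = 100, premrna_fraction = 0,
                    sisrna_specs = list())
  g <- simulate_gene(cfg)
  sim <- simulate_reads(g$model, g$sequence, cfg)
  cov3 <- coverage_profile(sim$records, g$model$chrom,
                           g$model$span["start"], g$model$span["end"])
  intronic <- unlist(lapply(seq_len(nrow(g$model$introns)), function(i) {
    (g$model$introns$start[i] - cov3$start + 1):(g$model$introns$end[i] - cov3$start)
  }))
  expect_true(all(cov3$depth[intronic] == 0))
  expect_gt(mean(cov3$depth[-intronic]), 0)
})
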