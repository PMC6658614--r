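test_that("the paired-read intron rule is strictly greater-than", {
  # toy intron 1 is [100, 200)
  m <- toy_model()
  mate_any <- rec("p", 20, "30M", flag = 99L)

  r11 <- rec("p", 90, "21M", flag = 147L)     # overlap [100,111) = 11 nt
  expect_true(intron_overlap_filter(mate_any, r11, m)$accepted)
  expect_equal(intron_overlap_filter(mate_any, r11, m)$intron_id, 1L)

  r10 <- rec("p", 90, "20M", flag = 147L)     # overlap 10 nt: rejected
  res10 <- intron_overlap_filter(mate_any, r10, m)
  expect_false(res10$accepted)
  expect_equal(res10$reason, "insufficient_overlap")

  # both mates fully exonic
  exonic <- intron_overlap_filter(rec("p", 10, "50M", flag = 99L),
                                  rec("p", 220, "50M", flag = 147L), m)
  expect_false(exonic$accepted)

  # mates on different chromosomes get a reason code
  far <- rec("p", 90, "30M", flag = 147L, rname = "chr2")
  expect_equal(intron_overlap_filter(mate_any, far, m)$reason,
               "different_chromosomes")

  # a spliced mate whose N gap spans the intron contributes no overlap
  spliced <- rec("p", 90, "10M100N10M", flag = 147L)
  expect_false(intron_overlap_filter(mate_any, spliced, m)$accepted)
})

test_that("per-intron evidence counts qualifying pairs exactly once", {
  m <- toy_model()
  # one pair overlapping intron 2 ([300, 400)) by 20 nt
  pair <- recs(rec("q1", 380, "30M", flag = 99L),
               rec("q1", 420, "30M", flag = 147L))
  irc <- intron_read_counts(pair, m)
  expect_equal(irc$evidence$qualifying_pairs, c(0L, 1L))
  expect_equal(irc$n_examined, 1L)
  expect_equal(irc$n_rejected, 0L)

  # pure mRNA: no intronic transcript, no pre-mRNA -> all counts zero
  cfg <- sim_config(seed = 9, n_fragments = 200, premrna_fraction = 0,
                    sisrna_specs = list())
  g <- simulate_gene(cfg)
  sim <- simulate_reads(g$model, g$sequence, cfg)
  irc0 <- intron_read_counts(sim$records, g$model)
  expect_true(all(irc0$evidence$qualifying_pairs == 0))
  # filter conservation: accepted + rejected = examined
  expect_equal(irc0$n_rejected + sum(irc0$evidence$qualifying_pairs),
               irc0$n_examined)
})

test_that("candidate regions follow the run-length oracle", {
  cov <- structure(list(chrom = "c", start = 0, end = 7,
                        depth = c(0, 0, 5, 6, 7, 0, 0)),
                   class = "coverage_profile")
  out <- call_candidate_regions(cov, min_depth = 3, min_length = 2, max_gap = 0)
  expect_equal(out$start, 2)
  expect_equal(out$end, 5)
  expect_equal(out$mean_depth, 6)

  # all zeros
  cov0 <- structure(list(chrom = "c", start = 0, end = 5, depth = rep(0, 5)),
                    class = "coverage_profile")
  expect_equal(nrow(call_candidate_regions(cov0, 1, 1, 0)), 0)

  # two runs separated by a gap <= max_gap merge
  covm <- structure(list(chrom = "c", start = 100, end = 110,
                         depth = c(5, 5, 5, 0, 0, 5, 5, 5, 0, 0)),
                    class = "coverage_profile")
  merged <- call_candidate_regions(covm, 3, min_length = 2, max_gap = 2)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(100, 108))
  split2 <- call_candidate_regions(covm, 3, min_length = 2, max_gap = 1)
  expect_equal(nrow(split2), 2)

  # property: agreement with the exhaustive brute-force caller
  set.seed(31)
  for (i in 1:25) {
    depth <- rpois(200, 0.8) * rbinom(200, 1, 0.4) * sample(0:6, 200, TRUE)
    cv <- structure(list(chrom = "c", start = 0, end = 200, depth = depth),
                    class = "coverage_profile")
    md <- sample(1:4, 1); ml <- sample(1:10, 1); mg <- sample(0:5, 1)
    got <- call_candidate_regions(cv, md, ml, mg)
    want <- brute_candidates(depth, md, ml, mg)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("polyA-signal scanning matches a brute-force windowed scan", {
  expect_equal(scan_polya_signal("GGGAATAAAGG", window = 11), 3)
  expect_equal(scan_polya_signal("GGGGGG", window = 6), integer(0))
  # overlapping matches are all reported
  expect_equal(scan_polya_signal("AATAAATAAA", window = 10), c(0, 4))
  # N positions never match
  expect_equal(scan_polya_signal("GGAATNAAGG", window = 10), integer(0))
  # only hits within the 3' window count
  expect_equal(scan_polya_signal("AATAAAGGGGGGGGGG", window = 5), integer(0))

  set.seed(17)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    w <- sample(c(50, 200, 2000), 1)
    expect_equal(scan_polya_signal(s, w), brute_polya(s, w))
  }
})

test_that("abundance ratios report counts and flag zero denominators", {
  expect_equal(abundance_ratio(40, 4)$ratio, 10)
  expect_equal(abundance_ratio(7, 7)$ratio, 1)
  z <- abundance_ratio(5, 0)
  expect_true(z$infinite)
  expect_equal(z$ratio, Inf)
})

test_that("planted sisRNAs are recovered with Jaccard >= 0.8 and ~10x abundance", {
  n_rep <- 20L
  jac <- numeric(n_rep)
  ratio <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(seed = 4000 + r, n_fragments = 1500)
    g <- simulate_gene(cfg)
    sim <- simulate_reads(g$model, g$sequence, cfg)
    irc <- intron_read_counts(sim$records, g$model)
    acc <- sim$records[sim$records$qname %in% irc$accepted, ]
    cov <- coverage_profile(acc, g$model$chrom,
                            g$model$span["start"], g$model$span["end"])
    cands <- call_candidate_regions(cov, default_min_depth(cov, g$model))
    top <- cands[which.max(cands$mean_depth), ]
    truth <- sim$truth$sisrna
    jac[r] <- jaccard(top$start, top$end, truth$start[1], truth$end[1])
    ratio[r] <- irc$evidence$qualifying_pairs[10] /
      irc$evidence$qualifying_pairs[13]
  }
  expect_true(all(jac >= 0.8))
  expect_true(all(ratio >= 5 & ratio <= 20))
})
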