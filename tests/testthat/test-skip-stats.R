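test_that("two-sided Fisher p matches enumeration and published checkpoints", {
  # full enumeration of the 5 tables with margins (4,4)/(4,4): 34/70
  expect_equal(fisher_two_sided(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(enum_fisher_p(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)

  expect_equal(fisher_two_sided(5, 5, 5, 5), 1)
  expect_equal(round(fisher_two_sided(27555, 112, 406, 2), 2), 0.68)
  expect_equal(fisher_two_sided(24773, 8, 208, 0), 1, tolerance = 1e-9)

  expect_warning(p <- fisher_two_sided(0, 0, 5, 5), "zero margin")
  expect_equal(p, 1)
})

test_that("Fisher p is invariant under row and column swaps", {
  set.seed(42)
  for (i in 1:50) {
    t <- rpois(4, 8) + 1
    p <- fisher_two_sided(t[1], t[2], t[3], t[4])
    expect_equal(fisher_two_sided(t[3], t[4], t[1], t[2]), p, tolerance = 1e-10)
    expect_equal(fisher_two_sided(t[2], t[1], t[4], t[3]), p, tolerance = 1e-10)
  }
})

test_that("one-sided tail is monotone in the observed cell at fixed margins", {
  # margins (10,10)/(8,12): hypergeometric lower tail shrinks as a moves
  # further above its expectation
  r1 <- 10; c1 <- 8; N <- 20
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  upper_tail <- vapply(xs, function(a) {
    sum(dhyper(a:min(r1, c1), c1, N - c1, r1))
  }, numeric(1))
  expect_true(all(diff(upper_tail) < 0))
})

test_that("library comparison reproduces published rows and handles edge cases", {
  human <- rpe65_skip_counts("Human RPE")
  arpe <- rpe65_skip_counts("ARPE-19 (4 months)")
  cmp <- compare_libraries(human, arpe)
  expect_equal(nrow(cmp), 12)
  expect_equal(cmp$upstream_exon, 1:12)

  # exons 11-12: (24773, 8) vs (208, 0) -> p = 1.00
  expect_equal(round(cmp$p_two_sided[cmp$upstream_exon == 11], 2), 1)
  # exons 3-4: (27555, 112) vs (406, 2) -> p = 0.68
  expect_equal(round(cmp$p_two_sided[cmp$upstream_exon == 3], 2), 0.68)
  # rows with zero skips in both libraries get p = 1
  expect_true(all(cmp$p_two_sided[cmp$a_skip == 0 & cmp$b_skip == 0] == 1))
  # Bonferroni column present and never below the raw p
  expect_true(all(cmp$p_bonferroni >= cmp$p_two_sided))

  # identical libraries: all p = 1 (up to tie handling at the mode)
  cmp_same <- compare_libraries(human, human)
  expect_equal(cmp_same$p_two_sided, rep(1, 12), tolerance = 1e-4)

  # mismatched junction sets are an error
  expect_error(compare_libraries(human, arpe[-1, ]), "different junction")
})

test_that("elevated skipping (0.01 vs 0.10, n = 200) is detected in >= 90% of replicates", {
  hits <- 0L
  n_rep <- 200L
  set.seed(20240901)
  for (i in seq_len(n_rep)) {
    k_a <- rbinom(1, 200, 0.01)
    k_b <- rbinom(1, 200, 0.10)
    p <- suppressWarnings(fisher_two_sided(200 - k_a, k_a, 200 - k_b, k_b))
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("skip table renders publication-style columns", {
  human <- rpe65_skip_counts("Human RPE")
  arpe <- rpe65_skip_counts("ARPE-19 (4 months)")
  cmp <- compare_libraries(human, arpe)
  tab <- render_skip_table(cmp, labels = c("Human RPE", "ARPE-19 (4 months)"))
  expect_equal(names(tab), c("exon_pair", "library", "n_correct", "n_skip",
                             "fraction", "p_value"))
  expect_equal(nrow(tab), 24)
  row11 <- tab[tab$exon_pair == "Exons 11-12 and 11-13" &
                 tab$library == "Human RPE", ]
  expect_equal(row11$fraction, "0.0003")
  row11b <- tab[tab$exon_pair == "Exons 11-12 and 11-13" &
                  tab$library == "ARPE-19 (4 months)", ]
  expect_equal(row11b$p_value, "1.00")
  expect_error(render_skip_table(cmp[0, ]), "empty")
})
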