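#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric two-sided p-value by the minimum-likelihood rule: the
#' sum of probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (the convention of
#' standard exact-test implementations; computed via [stats::fisher.test()]).
#' A table with a zero margin carries no information about association and
#' returns p = 1 with a warning.
#'
#' @param a,b,c,d Cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    warning("2x2 table has a zero margin; returning p = 1 by convention")
    return(1)
  }
  stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Compare exon-skipping fractions between two libraries per junction pair
#'
#' For each adjacent exon pair, builds the 2x2 table
#' `[[a_correct, a_skip], [b_correct, b_skip]]` and computes the two-sided
#' Fisher exact p-value. Rows where neither library has any skip (or where a
#' margin is zero) get p = 1. A Bonferroni-adjusted column across the
#' junction-pair comparisons is emitted alongside for convenience; the raw
#' p-values are the primary output.
#'
#' @param table_a,table_b Junction count tables from [count_junctions()] (or
#'   any data frame with `upstream_exon`, `n_correct`, `n_skip`, `library`),
#'   built against the same gene model.
#' @return A data frame sorted by exon index with columns `upstream_exon`,
#'   `a_correct`, `a_skip`, `b_correct`, `b_skip`, `fraction_a`, `fraction_b`,
#'   `p_two_sided`, `p_bonferroni`.
#' @export
compare_libraries <- function(table_a, table_b) {
  ga <- attr(table_a, "gene_id"); gb <- attr(table_b, "gene_id")
  if (!is.null(ga) && !is.null(gb) && !identical(ga, gb)) {
    stop("count tables come from different gene models: '", ga, "' vs '", gb, "'")
  }
  if (nrow(table_a) != nrow(table_b) ||
      !identical(sort(table_a$upstream_exon), sort(table_b$upstream_exon))) {
    stop("count tables cover different junction sets")
  }
  a <- table_a[order(table_a$upstream_exon), ]
  b <- table_b[order(table_b$upstream_exon), ]
  p <- vapply(seq_len(nrow(a)), function(i) {
    if (a$n_skip[i] == 0 && b$n_skip[i] == 0) return(1)
    suppressWarnings(
      fisher_two_sided(a$n_correct[i], a$n_skip[i], b$n_correct[i], b$n_skip[i])
    )
  }, numeric(1))
  data.frame(
    upstream_exon = a$upstream_exon,
    a_correct = a$n_correct, a_skip = a$n_skip,
    b_correct = b$n_correct, b_skip = b$n_skip,
    fraction_a = skip_fraction(a$n_correct, a$n_skip),
    fraction_b = skip_fraction(b$n_correct, b$n_skip),
    p_two_sided = p,
    p_bonferroni = pmin(1, p * nrow(a)),
    stringsAsFactors = FALSE
  )
}

#' Render a comparison as a publication-style skip table
#'
#' Columns: `exon_pair`, `library`, `n_correct`, `n_skip`, `fraction`,
#' `p_value` — one row per library per junction pair, fractions to three
#' decimals (sub-millesimal fractions shown at one significant figure so that
#' rare events are not rendered as zero), p-values to two significant figures
#' on the second library's row.
#'
#' @param comparisons Output of [compare_libraries()].
#' @param labels Character vector of length 2 naming the two libraries.
#' @return A data frame ready for TSV export.
#' @export
render_skip_table <- function(comparisons, labels = c("A", "B")) {
  if (nrow(comparisons) == 0L) stop("empty comparison list")
  # two significant figures, never scientific: "1.00", "0.68", "0.0046"
  fmt_p2 <- function(p) {
    p2 <- signif(p, 2)
    ifelse(p2 >= 0.095, sprintf("%.2f", p2), formatC(p2, format = "fg"))
  }
  fmt_frac <- function(x) {
    ifelse(is.na(x), "NA",
           ifelse(x > 0 & x < 0.0005, formatC(signif(x, 1), format = "fg"),
                  formatC(round(x, 3), format = "f", digits = 3)))
  }
  rows <- lapply(seq_len(nrow(comparisons)), function(i) {
    cmp <- comparisons[i, ]
    pair <- sprintf("Exons %d-%d and %d-%d", cmp$upstream_exon,
                    cmp$upstream_exon + 1, cmp$upstream_exon, cmp$upstream_exon + 2)
    data.frame(
      exon_pair = c(pair, pair),
      library = labels,
      n_correct = c(cmp$a_correct, cmp$b_correct),
      n_skip = c(cmp$a_skip, cmp$b_skip),
      fraction = c(fmt_frac(cmp$fraction_a), fmt_frac(cmp$fraction_b)),
      p_value = c("", fmt_p2(cmp$p_two_sided)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Published RPE65 junction counts (human RPE and 4-month ARPE-19)
#'
#' The transcribed per-junction counts of correct and exon-skipping splicing
#' events for the human RPE65 gene, as estimated from public RNA-seq libraries
#' of native human RPE/choroid and ARPE-19 cells differentiated for 4 months.
#' These counts are the desk-scale validation input for the comparison and
#' mixture stages.
#'
#' @param library Optional filter: `"Human RPE"` or `"ARPE-19 (4 months)"`.
#' @return A data frame with columns `upstream_exon`, `library`, `n_correct`,
#'   `n_skip`, carrying a `gene_id` attribute of `"RPE65"`.
#' @export
rpe65_skip_counts <- function(library = NULL) {
  path <- system.file("extdata", "rpe65_junction_counts.tsv", package = "sisplice")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(library)) {
    stopifnot(library %in% unique(tab$library))
    tab <- tab[tab$library == library, , drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "gene_id") <- "RPE65"
  tab
}
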