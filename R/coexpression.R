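# Co-expression of exonic and intronic signal across samples: raw read counts
# per designated exon, per intronic sisRNA region, and skip events per
# designated junction are correlated with Pearson's r.

#' Pearson correlation with a two-sided p-value
#'
#' Standard product-moment correlation; the two-sided p-value comes from the
#' t transform with n - 2 degrees of freedom (via [stats::cor.test()]). Zero
#' variance in either vector yields an undefined-r result with a reason
#' rather than an error.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list of class `correlation_result`: `r`, `p_value`, `n`,
#'   `variables`, `reason` (`"ok"` or `"zero_variance"`).
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired observations")
  vars <- c(deparse(substitute(x)), deparse(substitute(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, p_value = NA_real_, n = length(x),
                          variables = vars, reason = "zero_variance"),
                     class = "correlation_result"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
                 variables = vars, reason = "ok"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$reason != "ok") {
    cat(sprintf("r undefined (%s), n = %d\n", x$reason, x$n))
  } else {
    cat(sprintf("r = %.3f, p = %.3g, n = %d\n", x$r, x$p_value, x$n))
  }
  invisible(x)
}

#' Correlate per-sample expression summaries
#'
#' Takes one row per sample (library/replicate) of raw-count summaries and
#' computes one Pearson correlation per requested variable pair — e.g. exonic
#' depth vs intronic sisRNA depth, or intronic depth vs skip-event count.
#' Counts are used raw by default; set `normalize = TRUE` to divide each
#' variable by the sample's `library_size` column first (an optional
#' convenience, not part of the raw-count analysis).
#'
#' @param summaries Data frame, one row per sample, numeric summary columns.
#' @param pairings List of length-2 character vectors naming column pairs.
#' @param normalize Divide by `library_size` before correlating.
#' @return A data frame: `var_x`, `var_y`, `r`, `p_value`, `n`. Pairs with a
#'   missing variable are skipped with a warning.
#' @export
correlate_summaries <- function(summaries, pairings, normalize = FALSE) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 3L)
  out <- list()
  for (pr in pairings) {
    stopifnot(length(pr) == 2L)
    if (!all(pr %in% names(summaries))) {
      warning("variable(s) missing for pairing ", paste(pr, collapse = " ~ "),
              "; skipped")
      next
    }
    x <- summaries[[pr[1]]]; y <- summaries[[pr[2]]]
    if (normalize) {
      stopifnot("library_size" %in% names(summaries))
      x <- x / summaries$library_size
      y <- y / summaries$library_size
    }
    res <- pearson_correlation(x, y)
    out[[length(out) + 1L]] <- data.frame(
      var_x = pr[1], var_y = pr[2], r = res$r, p_value = res$p_value,
      n = res$n, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(var_x = character(), var_y = character(), r = numeric(),
                      p_value = numeric(), n = integer()))
  }
  do.call(rbind, out)
}
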