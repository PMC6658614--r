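# Shared fixtures and independent oracles.

# A toy 3-exon gene: exons [0,100), [200,300), [400,500) on chr1, plus strand.
toy_model <- function() {
  gene_model("toy", "chr1", c(0, 200, 400), c(100, 300, 500))
}

# One alignment record as the package's record row.
rec <- function(qname, pos0, cigar, flag = 0L, rname = "chr1", seq = "*") {
  data.frame(qname = qname, flag = flag, rname = rname, pos0 = pos0,
             mapq = 60L, cigar = cigar, rnext = "*", pnext0 = -1,
             tlen = 0, seq = seq, stringsAsFactors = FALSE)
}

recs <- function(...) do.call(rbind, list(...))

# Exhaustive-enumeration oracle for the two-sided (minimum-likelihood)
# Fisher exact p of [[a, b], [c, d]]: sum of hypergeometric point
# probabilities over all tables with the observed margins that do not exceed
# the observed table's probability (relative tolerance 1e-7).
enum_fisher_p <- function(a, b, c, d) {
  N <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  x <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- dhyper(x, c1, N - c1, r1)
  p0 <- dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Interval Jaccard for 0-based half-open intervals.
jaccard <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1))
  union <- (a2 - a1) + (b2 - b1) - inter
  inter / union
}

# Brute-force candidate caller: exhaustive scan over all start/end pairs of
# above-threshold runs with gap tolerance (quadratic; tiny inputs only).
brute_candidates <- function(depth, min_depth, min_length, max_gap) {
  above <- which(depth >= min_depth)
  if (length(above) == 0) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  groups <- list()
  cur <- above[1]
  for (p in above[-1]) {
    if (p - cur[length(cur)] <= max_gap + 1) cur <- c(cur, p)
    else { groups[[length(groups) + 1]] <- cur; cur <- p }
  }
  groups[[length(groups) + 1]] <- cur
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(start = min(g) - 1, end = max(g))  # to 0-based half-open
  }))
  out[out$end - out$start >= min_length, , drop = FALSE]
}

# Brute-force all-positions polyA scan restricted to the 3' window.
brute_polya <- function(sequence, window) {
  len <- nchar(sequence)
  hits <- integer(0)
  for (s in seq_len(len - 5)) {
    if (substr(sequence, s, s + 5) == "AATAAA") hits <- c(hits, s - 1L)
  }
  hits[hits >= len - window]
}

# Direct covariance-formula Pearson r.
cov_formula_r <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sxy / (sqrt(sum((x - mean(x))^2) / n) * sqrt(sum((y - mean(y))^2) / n))
}

# ARPE-19 (4 months) junction observations: k skip events out of
# n = correct + skip junction events per adjacent exon pair.
arpe19_obs <- function() {
  tab <- rpe65_skip_counts("ARPE-19 (4 months)")
  data.frame(junction_id = tab$upstream_exon, k = tab$n_skip,
             n = tab$n_correct + tab$n_skip)
}
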