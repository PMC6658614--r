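# Mixture-of-binomials classification of per-junction exon-skipping rates.
# Each junction contributes an observation (k skip events out of n junction
# events); a C-class mixture Binom(n_i, q_c) with weights w_c is fitted by EM,
# and the number of classes is chosen by a parametric-bootstrap likelihood
# ratio test. Departure from a single binomial is read as evidence that some
# junctions have genuinely elevated skipping rates.

# Evaluate expr with a temporary RNG state seeded at `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

logsumexp_rows <- function(m) {
  mx <- m[, 1L]
  for (c in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, c])
  mx + log(rowSums(exp(m - mx)))
}

# log Binom(k; n, q) with q clamped away from {0,1} only where needed
log_binom <- function(k, n, q) {
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  stats::dbinom(k, n, q, log = TRUE)
}

# One EM run from given initial (w, q).
em_run <- function(k, n, w, q, tol, max_iter) {
  N <- length(k); C <- length(w)
  ll_trace <- numeric(max_iter)
  ll_old <- -Inf
  r <- NULL
  lp <- matrix(0, N, C)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (c in seq_len(C)) lp[, c] <- log(w[c]) + log_binom(k, n, q[c])
    lse <- logsumexp_rows(lp)
    ll <- sum(lse)
    ll_trace[iter] <- ll
    r <- exp(lp - lse)
    if ((is.finite(ll_old) && ll - ll_old < tol) || iter >= max_iter) break
    ll_old <- ll
    # M step
    w <- colMeans(r)
    q <- colSums(r * k) / colSums(r * n)
    q[!is.finite(q)] <- 0
  }
  list(weights = w, probs = q, responsibilities = r,
       log_likelihood = ll_trace[iter], ll_trace = ll_trace[seq_len(iter)])
}

# C initial (w, q) configurations: quantile split of k/n plus random ones.
init_params <- function(k, n, C, restarts) {
  N <- length(k)
  rate <- k / n
  inits <- list()
  grp <- cut(rank(rate, ties.method = "first"), breaks = C, labels = FALSE)
  q0 <- vapply(seq_len(C), function(c) {
    sel <- grp == c
    (sum(k[sel]) + 0.5) / (sum(n[sel]) + 1)
  }, numeric(1))
  inits[[1]] <- list(w = as.numeric(table(factor(grp, levels = seq_len(C)))) / N,
                     q = q0)
  for (s in seq_len(max(0L, restarts - 1L))) {
    grp_r <- sample(seq_len(C), N, replace = TRUE)
    q_r <- vapply(seq_len(C), function(c) {
      sel <- grp_r == c
      (sum(k[sel]) + stats::runif(1, 0.1, 1)) / (sum(n[sel]) + 1)
    }, numeric(1))
    w_r <- stats::runif(C); w_r <- w_r / sum(w_r)
    inits[[s + 1L]] <- list(w = w_r, q = q_r)
  }
  inits
}

#' Fit a mixture of binomial distributions by EM
#'
#' Fits `Binom(k_i; n_i, q_c)` mixture components with weights `w_c` by
#' expectation-maximization: E-step `r_ic` proportional to
#' `w_c * Binom(k_i; n_i, q_c)`, M-step `w_c = mean_i r_ic`,
#' `q_c = sum_i r_ic k_i / sum_i r_ic n_i`, iterated until the log-likelihood
#' gain falls below `tol`. The best of `restarts` seeded initializations
#' (deterministic quantile split plus random perturbations) is returned, with
#' classes ordered by increasing `q_c`. A class whose weight collapses below
#' `1/(10N)` is removed and the model refitted with one class fewer.
#'
#' @param obs Data frame with columns `junction_id`, `k` (skip events), `n`
#'   (total junction events), `0 <= k <= n`, `n >= 1`.
#' @param C Number of classes (>= 1).
#' @param seed Integer seed controlling the random restarts.
#' @param restarts Number of EM initializations (default 10).
#' @param tol Log-likelihood convergence threshold (default 1e-8).
#' @param max_iter Iteration cap per run.
#' @return An object of class `binom_mixture`: `n_classes`, `weights`,
#'   `probs`, `responsibilities` (N x C), `log_likelihood`, `ll_trace` of the
#'   winning run, `degenerate` flag, and the input `obs`.
#' @export
fit_mixture <- function(obs, C, seed = 1L, restarts = 10L, tol = 1e-8,
                        max_iter = 2000L) {
  stopifnot(is.data.frame(obs), all(c("junction_id", "k", "n") %in% names(obs)))
  k <- as.numeric(obs$k); n <- as.numeric(obs$n)
  stopifnot(all(k >= 0), all(k <= n), all(n >= 1), C >= 1)
  N <- length(k)
  if (C > N) stop("C = ", C, " exceeds the number of observations (", N, ")")

  if (C == 1L) {
    q <- sum(k) / sum(n)  # closed-form MLE
    ll <- sum(log_binom(k, n, q))
    return(structure(list(
      n_classes = 1L, weights = 1, probs = q,
      responsibilities = matrix(1, N, 1),
      log_likelihood = ll, ll_trace = ll,
      degenerate = FALSE, obs = obs
    ), class = "binom_mixture"))
  }

  degenerate_input <- all(k == 0)
  fit <- with_seed(seed, {
    inits <- init_params(k, n, C, restarts)
    runs <- lapply(inits, function(ini) em_run(k, n, ini$w, ini$q, tol, max_iter))
    runs[[which.max(vapply(runs, `[[`, numeric(1), "log_likelihood"))]]
  })

  # degenerate class collapse: drop and refit with C-1
  if (any(fit$weights < 1 / (10 * N)) && C > 1L) {
    out <- fit_mixture(obs, C - 1L, seed = seed, restarts = restarts,
                       tol = tol, max_iter = max_iter)
    out$degenerate <- TRUE
    return(out)
  }

  ord <- order(fit$probs)
  structure(list(
    n_classes = C,
    weights = fit$weights[ord],
    probs = fit$probs[ord],
    responsibilities = fit$responsibilities[, ord, drop = FALSE],
    log_likelihood = fit$log_likelihood,
    ll_trace = fit$ll_trace,
    degenerate = degenerate_input,
    obs = obs
  ), class = "binom_mixture")
}

#' @export
print.binom_mixture <- function(x, ...) {
  cat(sprintf("binomial mixture: %d class(es), logLik %.4f%s\n",
              x$n_classes, x$log_likelihood,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  cat("  q:", signif(x$probs, 4), "\n  w:", signif(x$weights, 4), "\n")
  invisible(x)
}

# Draw one dataset from a fitted mixture (same n_i), for the bootstrap.
sim_binmix <- function(n, weights, probs) {
  z <- sample.int(length(weights), length(n), replace = TRUE, prob = weights)
  stats::rbinom(length(n), n, probs[z])
}

# Bootstrap LRT of C vs C+1 classes; returns the p-value. Bootstrap fits use
# a relaxed tolerance and iteration cap: the LRT reference distribution needs
# far less precision than the reported model.
bootstrap_lrt <- function(obs, C, seed, B, restarts) {
  fit0 <- fit_mixture(obs, C, seed = seed, restarts = restarts)
  fit1 <- fit_mixture(obs, C + 1L, seed = seed, restarts = restarts)
  lrt_obs <- max(0, 2 * (fit1$log_likelihood - fit0$log_likelihood))
  lrt_b <- with_seed(seed + 1L, {
    vapply(seq_len(B), function(b) {
      kb <- sim_binmix(obs$n, fit0$weights, fit0$probs)
      ob <- data.frame(junction_id = obs$junction_id, k = kb, n = obs$n)
      f0 <- fit_mixture(ob, C, seed = seed + b, restarts = restarts,
                        tol = 1e-6, max_iter = 300L)
      f1 <- fit_mixture(ob, C + 1L, seed = seed + b, restarts = restarts,
                        tol = 1e-6, max_iter = 300L)
      max(0, 2 * (f1$log_likelihood - f0$log_likelihood))
    }, numeric(1))
  })
  (1 + sum(lrt_b >= lrt_obs - 1e-9)) / (B + 1)
}

# Chi-square dispersion test of the fitted C-class model (alternative switch):
# Pearson statistic of k against the per-observation mixture mean/variance.
chisq_gof <- function(obs, fit) {
  mu <- as.numeric(fit$responsibilities %*% fit$probs)  # posterior mean rate
  m <- obs$n * mu
  v <- obs$n * mu * (1 - mu)
  v[v <= 0] <- 1
  x2 <- sum((obs$k - m)^2 / v)
  df <- max(1L, nrow(obs) - (2L * fit$n_classes - 1L))
  stats::pchisq(x2, df, lower.tail = FALSE)
}

#' Select the number of binomial mixture classes
#'
#' Starts at C = 1 and, while the goodness-of-fit test rejects at level
#' `alpha` and `C < C_max`, increments C; the smallest adequate model is
#' returned. The default test is a parametric-bootstrap likelihood-ratio test
#' of C vs C+1 (B seeded bootstrap replicates; the naive chi-square reference
#' for mixture LRTs is invalid). A chi-square dispersion test is available as
#' an alternative.
#'
#' @inheritParams fit_mixture
#' @param C_max Largest class count considered (default 5).
#' @param alpha Test level (default 0.05).
#' @param B Bootstrap replicates (default 199).
#' @param method `"bootstrap"` (default) or `"chisq"`.
#' @param restarts EM restarts per fit (default 4 inside selection, for
#'   speed; the returned model is refitted at 10).
#' @return A `binom_mixture` with extra fields `selection_trace` (data frame
#'   of C, p-value) and `adequate` (FALSE when C_max was reached with the
#'   test still rejecting).
#' @export
select_classes <- function(obs, C_max = 5L, alpha = 0.05, seed = 1L, B = 199L,
                           method = c("bootstrap", "chisq"), restarts = 4L) {
  method <- match.arg(method)
  stopifnot(C_max >= 1L)
  C <- 1L
  trace <- data.frame(C = integer(), p_value = numeric())
  adequate <- TRUE
  repeat {
    if (C >= C_max || C + 1L > nrow(obs)) break
    p <- if (method == "bootstrap") {
      bootstrap_lrt(obs, C, seed = seed, B = B, restarts = restarts)
    } else {
      chisq_gof(obs, fit_mixture(obs, C, seed = seed, restarts = restarts))
    }
    trace <- rbind(trace, data.frame(C = C, p_value = p))
    if (p < alpha) C <- C + 1L else break
  }
  if (nrow(trace) && trace$p_value[nrow(trace)] < alpha) adequate <- FALSE
  fit <- fit_mixture(obs, C, seed = seed, restarts = 10L)
  fit$selection_trace <- trace
  fit$adequate <- adequate
  fit
}

#' Assign observations to mixture classes
#'
#' Each observation goes to the class with the largest responsibility; classes
#' are indexed in increasing `q_c` order, and ties break toward the lower-q
#' class.
#'
#' @param model A fitted `binom_mixture`.
#' @return A data frame with `junction_id`, `k`, `n`, `class` (1-based) and
#'   `tie` flag.
#' @export
assign_classes <- function(model) {
  r <- model$responsibilities
  cls <- apply(r, 1L, which.max)  # which.max takes the first (lowest-q) on ties
  tie <- apply(r, 1L, function(x) sum(abs(x - max(x)) < 1e-12) > 1L)
  data.frame(junction_id = model$obs$junction_id,
             k = model$obs$k, n = model$obs$n,
             class = as.integer(cls), tie = tie)
}
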