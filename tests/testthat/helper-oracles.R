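# Independent brute-force oracles used across the suite. These deliberately
# re-derive each statistic from first principles (direct enumeration, grid
# search, literal formulas) and share no code with the implementation.

# Efron partial log-likelihood for a single covariate, evaluated at each
# value of `beta_grid` (vectorized over the grid so a 1e-4-step search is
# feasible). Events tied at the same time are handled by the Efron
# average-risk-set correction.
oracle_efron_loglik <- function(beta_grid, time, event, x) {
  ll <- numeric(length(beta_grid))
  dtimes <- sort(unique(time[event == 1]))
  for (t in dtimes) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sumR <- rowSums(exp(outer(beta_grid, x[R])))
    sumD <- rowSums(exp(outer(beta_grid, x[D])))
    ll <- ll + beta_grid * sum(x[D])
    for (l in 0:(d - 1)) {
      ll <- ll - log(sumR - (l / d) * sumD)
    }
  }
  ll
}

# Literal BH step-up formula: adj_(i) = min_{j >= i} ( p_(j) * m / j ),
# capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Direct enumeration of the ssGSEA weighted-ECDF running sum for one
# sample: walk the ranking position by position and accumulate the
# difference of the two ECDFs.
oracle_ssgsea_one <- function(x, symbols, set_genes, alpha) {
  n <- length(x)
  ord <- order(-x, symbols)
  rk <- rank(x, ties.method = "average")
  w <- rk^alpha
  inset <- symbols %in% set_genes
  k <- sum(inset)
  tot_w <- sum(w[inset])
  cum_in <- 0
  cum_out <- 0
  s <- 0
  for (i in seq_len(n)) {
    g <- ord[i]
    if (inset[g]) cum_in <- cum_in + w[g] else cum_out <- cum_out + 1
    s <- s + cum_in / tot_w - cum_out / (n - k)
  }
  s
}

# Brute-force GSEA enrichment score: materialize the full running sum and
# take the extremum of maximal absolute deviation (positive wins ties).
oracle_es <- function(values, hits, p = 1) {
  n <- length(values)
  k <- sum(hits)
  w <- abs(values)^p
  sw <- sum(w[hits])
  steps <- ifelse(hits, w / sw, -1 / (n - k))
  running <- cumsum(steps)
  mx <- max(running)
  mn <- min(running)
  if (mx >= -mn) mx else mn
}

# Brute-force agglomerative clustering that recomputes the inter-cluster
# distance from the original distance matrix at every merge (average,
# complete or single linkage). Returns the sequence of merge heights.
oracle_agglomerate_heights <- function(d, linkage = "average") {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  linkfun <- switch(linkage, average = mean, complete = max, single = min)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- linkfun(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) {
          best_d <- dij
          best <- c(i, j)
        }
      }
    }
    heights[step] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Two-sided Fisher exact p-value by exhaustive summation of the
# hypergeometric tail: sum the probabilities of all tables (given fixed
# margins) no more probable than the observed one.
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_       # category size
  n <- b + d        # out-of-category size
  k <- a + b        # selected size
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small survival fixture with ties and censoring used by several tests.
make_surv_fixture <- function() {
  data.frame(
    time = c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8),
    event = c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0),
    x = c(0, 1, 0, 1, 1, 0, 1, 0, 1, 0)
  )
}

# Exponential proportional-hazards survival draw used in simulation tests.
draw_exp_surv <- function(n, beta, x, lambda = 0.1, cens_rate = 0.03) {
  rates <- lambda * exp(beta * x)
  t_ev <- stats::rexp(n, rates)
  t_cn <- stats::rexp(n, cens_rate)
  list(time = pmin(t_ev, t_cn), event = as.numeric(t_ev <= t_cn))
}

expect_no_failures <- function(tab) {
  expect_equal(nrow(attr(tab, "failures")), 0)
}
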