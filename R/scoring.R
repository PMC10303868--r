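#' Single-sample pathway activity scores
#'
#' Summarizes the expression of each gene set into one activity value per
#' sample, using one of three single-sample statistics:
#'
#' * `ssgsea` (default): for each sample, genes are ranked by decreasing
#'   expression and the score is the sum, along the ranking, of the
#'   difference between the weighted in-set rank ECDF and the unweighted
#'   out-of-set ECDF. In-set steps at rank position `i` are weighted by
#'   `|rank|^alpha`, where the top gene carries rank `N`. Each sample's
#'   score depends only on that sample's expression ranks.
#' * `zscore`: genes are standardized across samples; the set score per
#'   sample is the sum of member z-scores divided by `sqrt(set size)`.
#' * `plage`: the set score vector is the right singular vector of the
#'   standardized member-gene submatrix associated with the largest
#'   singular value, with the sign fixed so it correlates positively with
#'   the mean member z-score.
#'
#' Sets with fewer than `min_set_size` member genes present in the
#' expression matrix are dropped and listed in the `dropped_sets` attribute.
#' Expression values are used as supplied (linear or log scale); `ssgsea`
#' is rank-based and therefore invariant to monotone transforms, the other
#' two methods are not.
#'
#' @param expr Numeric matrix, genes (rows, named) x samples (columns, named).
#' @param sets A `gene_set_collection`.
#' @param method One of `"ssgsea"`, `"zscore"`, `"plage"`. `"gsva"` is
#'   recognized but not implemented and rejected with an informative error.
#' @param alpha ssGSEA rank-weighting exponent, >= 0 (default 0.25).
#' @param min_set_size Minimum number of member genes present in `expr`
#'   for a set to be scored (default 2).
#' @param normalize For ssGSEA only: divide all scores by the global
#'   (max - min) over the whole score matrix (default TRUE).
#' @return A `score_matrix`: numeric matrix, sets x samples, with
#'   attributes `method`, `alpha`, `effective_set_sizes` (named integer)
#'   and `dropped_sets` (character).
#' @examples
#' expr <- matrix(rnorm(30), 6, 5,
#'                dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
#' gsc <- gene_set_collection(list(A = c("g1", "g2"), B = c("g3", "g4", "g5")))
#' pathway_scores(expr, gsc, method = "zscore")
#' @export
pathway_scores <- function(expr, sets, method = c("ssgsea", "zscore", "plage", "gsva"),
                           alpha = 0.25, min_set_size = 2, normalize = TRUE) {
  method <- match.arg(method)
  if (method == "gsva") {
    stop_ps("method 'gsva' (kernel-ECDF scoring) is not implemented; ",
            "use 'ssgsea', 'zscore' or 'plage'")
  }
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop_ps("expression matrix must have gene row names and sample column names")
  }
  if (alpha < 0) stop_ps("alpha must be >= 0")
  if (min_set_size < 2) stop_ps("min_set_size must be >= 2")
  stopifnot(inherits(sets, "gene_set_collection"))

  members <- lapply(sets$sets, function(g) intersect(g, rownames(expr)))
  eff <- lengths(members)
  n_genes <- nrow(expr)
  keep <- eff >= min_set_size & eff < n_genes
  dropped <- names(members)[!keep]
  if (!any(keep)) {
    stop_ps("no gene set has >= min_set_size member genes in the expression matrix")
  }
  members <- members[keep]

  scores <- switch(method,
    ssgsea = ssgsea_scores(expr, members, alpha = alpha, normalize = normalize),
    zscore = zscore_scores(expr, members),
    plage  = plage_scores(expr, members))

  structure(scores,
            method = method,
            alpha = if (method == "ssgsea") alpha else NA_real_,
            effective_set_sizes = lengths(members)[rownames(scores)],
            dropped_sets = dropped,
            class = c("score_matrix", class(scores)))
}

# ssGSEA running-sum statistic. For one sample with N genes ranked in
# decreasing expression order (positions 1..N), a set S of size k and
# per-gene weights w = rank^alpha (top gene has rank N):
#   score = sum_{i=1..N} [ sum_{j<=i, j in S} w_j / sum_{j in S} w_j
#                          - #(j<=i, j not in S) / (N - k) ]
# The double sum collapses to a weighted sum over member positions because
# sum_i cumsum_i(x) = sum_k x_k * (N - k + 1).
ssgsea_scores <- function(expr, members, alpha, normalize) {
  n_genes <- nrow(expr)
  n_samp <- ncol(expr)
  symbols <- rownames(expr)
  coef_total <- n_genes * (n_genes + 1) / 2
  scores <- matrix(NA_real_, length(members), n_samp,
                   dimnames = list(names(members), colnames(expr)))
  midx <- lapply(members, function(g) match(g, symbols))
  coef <- n_genes:1
  for (j in seq_len(n_samp)) {
    x <- expr[, j]
    if (length(unique(x)) == 1L) {
      warn_ps(sprintf("sample %s has constant expression; ranks tie-broken by gene symbol",
                      dQuote(colnames(expr)[j])))
    }
    # traversal order: decreasing expression, ties broken by gene symbol
    ord <- order(-x, symbols)
    pos_of <- integer(n_genes)
    pos_of[ord] <- seq_len(n_genes)
    w <- rank(x, ties.method = "average")^alpha
    for (s in seq_along(midx)) {
      gi <- midx[[s]]
      k <- length(gi)
      pos <- pos_of[gi]
      cin <- sum(w[gi] * coef[pos]) / sum(w[gi])
      cout <- (coef_total - sum(coef[pos])) / (n_genes - k)
      scores[s, j] <- cin - cout
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

# Standardize genes across samples; NULL rows (zero variance) become NA.
standardize_genes <- function(expr) {
  mu <- rowMeans(expr)
  sd <- apply(expr, 1, stats::sd)
  z <- (expr - mu) / sd
  z[sd == 0, ] <- NA_real_
  z
}

zscore_scores <- function(expr, members) {
  z <- standardize_genes(expr)
  usable <- rownames(expr)[!is.na(z[, 1])]
  scores <- matrix(NA_real_, length(members), ncol(expr),
                   dimnames = list(names(members), colnames(expr)))
  keep <- rep(TRUE, length(members))
  for (s in seq_along(members)) {
    g <- members[[s]]
    g_ok <- intersect(g, usable)
    if (length(g_ok) < length(g)) {
      warn_ps(sprintf("set %s: excluded %d zero-variance gene(s)",
                      dQuote(names(members)[s]), length(g) - length(g_ok)))
    }
    if (length(g_ok) == 0) {
      keep[s] <- FALSE
      next
    }
    scores[s, ] <- colSums(z[g_ok, , drop = FALSE]) / sqrt(length(g_ok))
  }
  if (!all(keep)) {
    warn_ps(sprintf("dropped %d set(s) with no non-constant member genes",
                    sum(!keep)))
  }
  scores[keep, , drop = FALSE]
}

plage_scores <- function(expr, members) {
  z <- standardize_genes(expr)
  usable <- rownames(expr)[!is.na(z[, 1])]
  scores <- matrix(NA_real_, length(members), ncol(expr),
                   dimnames = list(names(members), colnames(expr)))
  keep <- rep(TRUE, length(members))
  for (s in seq_along(members)) {
    g <- intersect(members[[s]], usable)
    if (length(g) == 0) {
      keep[s] <- FALSE
      next
    }
    sub <- z[g, , drop = FALSE]
    if (length(g) == 1L) {
      # degenerate single-gene set: the standardized gene itself
      scores[s, ] <- sub[1, ]
      next
    }
    sv <- svd(sub, nu = 0, nv = 1)
    v <- sv$v[, 1]
    # fix sign: positive correlation with the mean member z-score
    ref <- colMeans(sub)
    if (sum(v * ref) < 0) v <- -v
    scores[s, ] <- v
  }
  if (!all(keep)) {
    warn_ps(sprintf("dropped %d set(s) with no non-constant member genes",
                    sum(!keep)))
  }
  scores[keep, , drop = FALSE]
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d sets x %d samples (method: %s)\n",
              nrow(x), ncol(x), attr(x, "method")))
  invisible(x)
}
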