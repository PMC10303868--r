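#' Weighted Kolmogorov-Smirnov-like enrichment score
#'
#' Walks the ranked gene list from top to bottom, incrementing the running
#' sum by `|r_i|^p / sum_in-set |r_j|^p` at in-set genes and decrementing
#' by `1 / (N - k)` at out-of-set genes. The enrichment score (ES) is the
#' running-sum value of maximal absolute deviation from zero; when the
#' maximal positive and negative deviations tie exactly, the positive one
#' is returned. The leading edge contains the in-set genes at or before
#' the maximum (for ES > 0) or at or after the minimum (for ES < 0).
#'
#' @param ranked A `ranked_gene_list` (columns `gene`, `value`), already
#'   sorted by decreasing value.
#' @param genes Character vector of gene symbols forming the set.
#' @param weight Weighting exponent `p` on the ranking values (default 1).
#' @return List with `es`, `running_sum` (length N), `hit_positions`,
#'   `leading_edge` and `size_effective` (set genes present in the
#'   ranking).
#' @export
enrichment_score <- function(ranked, genes, weight = 1) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  hits <- ranked$gene %in% genes
  k <- sum(hits)
  n <- nrow(ranked)
  if (k == 0) stop_ps("no set gene present in the ranked list")
  if (k >= n) stop_ps("set covers the whole ranked list; decrement undefined")
  w <- abs(ranked$value)^weight
  step_hit <- w * hits
  sum_w <- sum(step_hit)
  if (sum_w == 0) {
    # all in-set ranking values are 0: fall back to unweighted hits
    step_hit <- as.numeric(hits)
    sum_w <- k
  }
  running <- cumsum(step_hit / sum_w - (!hits) / (n - k))
  i_max <- which.max(running)
  i_min <- which.min(running)
  es <- if (running[i_max] >= -running[i_min]) running[i_max] else running[i_min]
  hit_pos <- which(hits)
  leading <- if (es >= 0) {
    ranked$gene[hit_pos[hit_pos <= i_max]]
  } else {
    ranked$gene[hit_pos[hit_pos >= i_min]]
  }
  list(es = es, running_sum = running, hit_positions = hit_pos,
       leading_edge = leading, size_effective = k)
}

# ES for a permuted set given only the hit positions (sorted) and the
# weight vector along the fixed ranking; same statistic as
# enrichment_score() but O(k) per evaluation. The running sum attains its
# extrema immediately after a hit (local max candidates) or immediately
# before a hit (local min candidates), so only 2k points are inspected.
es_from_positions <- function(pos, w, n) {
  k <- length(pos)
  wp <- w[pos]
  sw <- sum(wp)
  if (sw == 0) {
    wp <- rep(1, k)
    sw <- k
  }
  cin <- cumsum(wp) / sw
  miss <- (pos - seq_len(k)) / (n - k)     # misses strictly before each hit
  after <- cin - miss                      # running sum just after hit j
  before <- c(0, cin[-k]) - miss           # just before hit j
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Preranked gene set enrichment analysis on a hazard-ratio ranking
#'
#' Computes the enrichment score of every gene set against the supplied
#' ranking and assesses significance by gene-label permutation: for each
#' set, `n_perm` random gene subsets of the same effective size are drawn
#' from the ranking and their ES forms the null. The nominal p-value is
#' the add-one-smoothed fraction of same-sign permutation scores at least
#' as extreme in absolute value, so no reported p is ever 0 and the
#' resolution is `1 / (n_perm + 1)`. The normalized enrichment score (NES)
#' divides ES by the mean absolute same-sign permutation ES (classical
#' convention); `nes = "scale"` instead divides by the mean absolute ES
#' over all permutations.
#'
#' @param ranked A `ranked_gene_list` (e.g. from [hr_ranking()] or
#'   [read_ranked_list()]). Hazard ratios are used as supplied; pass
#'   `log_transform = TRUE` to rank by `log(HR)` (centered at 0), which
#'   treats protective and hazardous effects symmetrically in the weights.
#' @param collection A `gene_set_collection`.
#' @param weight Weighting exponent on ranking values (default 1).
#' @param n_perm Number of gene-label permutations (default 1000; a
#'   warning is raised below 100).
#' @param min_size,max_size Effective set-size bounds after intersection
#'   with the ranking (defaults 5 and 500).
#' @param seed Integer seed for the permutations.
#' @param nes NES normalization, `"same_sign_mean"` (default) or
#'   `"scale"`.
#' @param log_transform Rank by log hazard ratio instead of raw values.
#' @return A `gsea_result` data frame, one row per reported set, sorted by
#'   nominal p then decreasing |NES|: `set`, `size_effective`, `es`,
#'   `nes`, `nominal_p`, `bh_q`, `leading_edge` (comma-separated);
#'   attribute `skipped` lists sets outside the size bounds or with no
#'   overlap.
#' @export
gsea_preranked <- function(ranked, collection, weight = 1, n_perm = 1000,
                           min_size = 5, max_size = 500, seed = 1,
                           nes = c("same_sign_mean", "scale"),
                           log_transform = FALSE) {
  stopifnot(inherits(ranked, "ranked_gene_list"),
            inherits(collection, "gene_set_collection"))
  nes <- match.arg(nes)
  if (n_perm < 100) warn_ps("n_perm < 100 gives very coarse p-values")
  if (log_transform) {
    if (any(ranked$value <= 0)) stop_ps("log_transform requires positive ranking values")
    ranked <- ranked_gene_list(ranked$gene, log(ranked$value))
  }
  n <- nrow(ranked)
  eff <- vapply(collection$sets, function(g) sum(g %in% ranked$gene), integer(1))
  keep <- eff >= min_size & eff <= max_size & eff < n
  skipped <- data.frame(set = names(eff)[!keep], size_effective = eff[!keep],
                        stringsAsFactors = FALSE)
  if (!any(keep)) stop_ps("no gene set within size bounds after intersection")
  sets <- collection$sets[keep]
  eff <- eff[keep]

  w <- abs(ranked$value)^weight
  obs <- lapply(sets, function(g) enrichment_score(ranked, g, weight = weight))
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  # one shared null per distinct effective set size
  sizes <- sort(unique(eff))
  null_by_size <- with_seed(seed, {
    out <- vector("list", length(sizes))
    names(out) <- as.character(sizes)
    for (s in seq_along(sizes)) {
      k <- sizes[s]
      out[[s]] <- vapply(seq_len(n_perm), function(i) {
        es_from_positions(sort(sample.int(n, k)), w, n)
      }, numeric(1))
    }
    out
  })

  rows <- lapply(seq_along(sets), function(s) {
    es <- es_obs[s]
    null <- null_by_size[[as.character(eff[s])]]
    same_sign <- if (es >= 0) null[null >= 0] else null[null < 0]
    n_extreme <- sum(abs(same_sign) >= abs(es))
    p <- (1 + n_extreme) / (1 + length(same_sign))
    denom <- if (nes == "same_sign_mean") mean(abs(same_sign)) else mean(abs(null))
    nes_val <- if (length(same_sign) == 0 || denom == 0) NA_real_ else es / denom
    data.frame(set = names(sets)[s], size_effective = eff[s], es = es,
               nes = nes_val, nominal_p = p,
               leading_edge = paste(obs[[s]]$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_q <- stats::p.adjust(out$nominal_p, method = "BH")
  out <- out[order(out$nominal_p, -abs(out$nes), out$set),
             c("set", "size_effective", "es", "nes", "nominal_p", "bh_q",
               "leading_edge")]
  rownames(out) <- NULL
  structure(out, skipped = skipped, n_perm = n_perm, seed = seed,
            class = c("gsea_result", "data.frame"))
}
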