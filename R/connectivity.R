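#' Pairwise Jaccard similarity between gene sets
#'
#' `J(A, B) = |A intersect B| / |A union B|` for every pair of sets in the
#' collection. The result is symmetric with a unit diagonal.
#'
#' @param collection A `gene_set_collection` with >= 2 non-empty sets.
#' @return A `jaccard_matrix`: symmetric numeric matrix in \[0, 1\] with
#'   set names on both dimensions.
#' @export
jaccard_matrix <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sets <- collection$sets
  if (length(sets) < 2) stop_ps("need >= 2 sets for a Jaccard matrix")
  if (any(lengths(sets) == 0)) stop_ps("empty gene set; Jaccard undefined")
  universe <- unique(unlist(sets, use.names = FALSE))
  m <- vapply(sets, function(g) universe %in% g, logical(length(universe)))
  m <- t(m) * 1  # sets x genes incidence
  inter <- m %*% t(m)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  j <- inter / uni
  dimnames(j) <- list(names(sets), names(sets))
  structure(j, class = c("jaccard_matrix", "matrix", "array"))
}

#' Cluster pathways on Jaccard distance
#'
#' Agglomerative hierarchical clustering on the Jaccard distance
#' `d = 1 - J`, cut into `k` groups. Sets are reordered lexicographically
#' by name before clustering so the result does not depend on input order;
#' remaining merge ties are resolved by that fixed ordering.
#'
#' @param jm A `jaccard_matrix` from [jaccard_matrix()].
#' @param k Number of clusters, `1 <= k <=` number of sets.
#' @param linkage Agglomeration method passed to [stats::hclust()]:
#'   `"average"` (default), `"complete"` or `"single"`.
#' @return A `cluster_result`: list with `assignments` (named integer,
#'   cluster ids 1..k), `k`, `linkage` and the `hclust` tree in `$tree`.
#' @export
cluster_pathways <- function(jm, k, linkage = c("average", "complete", "single")) {
  stopifnot(inherits(jm, "jaccard_matrix"))
  linkage <- match.arg(linkage)
  n <- nrow(jm)
  if (k < 1 || k > n) stop_ps("k must be between 1 and the number of sets (", n, ")")
  ord <- order(rownames(jm))
  jm <- jm[ord, ord]
  d <- stats::as.dist(1 - jm)
  tree <- stats::hclust(d, method = linkage)
  assignments <- stats::cutree(tree, k = k)
  structure(list(assignments = assignments, k = k, linkage = linkage,
                 tree = tree),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d sets in %d clusters (%s linkage)\n",
              length(x$assignments), x$k, x$linkage))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Long-format cluster/set/gene table with optional screen annotation
#'
#' One row per (set, gene) pair, labelled with the set's cluster. When a
#' gene-level `screen_table` is supplied, that gene's hazard ratio and
#' p-values are joined by symbol (left blank where absent). Rows are
#' sorted by (cluster, set, gene) so the output is stable across runs.
#'
#' @param clusters A `cluster_result` from [cluster_pathways()].
#' @param collection The `gene_set_collection` that was clustered.
#' @param screen Optional `screen_table` with gene-kind rows.
#' @return Data frame with columns `cluster`, `set`, `gene` and, when
#'   `screen` is given, `hazard_ratio`, `lr_p`, `bh_adjusted_p`.
#' @export
cluster_gene_table <- function(clusters, collection, screen = NULL) {
  stopifnot(inherits(clusters, "cluster_result"),
            inherits(collection, "gene_set_collection"))
  set_names <- names(clusters$assignments)
  if (!all(set_names %in% names(collection$sets))) {
    stop_ps("cluster assignments name sets absent from the collection")
  }
  rows <- lapply(set_names, function(nm) {
    data.frame(cluster = unname(clusters$assignments[nm]), set = nm,
               gene = collection$sets[[nm]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(screen)) {
    genes <- screen[screen$kind == "gene",
                    c("feature", "hazard_ratio", "lr_p", "bh_adjusted_p"),
                    drop = FALSE]
    idx <- match(out$gene, genes$feature)
    out$hazard_ratio <- genes$hazard_ratio[idx]
    out$lr_p <- genes$lr_p[idx]
    out$bh_adjusted_p <- genes$bh_adjusted_p[idx]
  }
  out <- out[order(out$cluster, out$set, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
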