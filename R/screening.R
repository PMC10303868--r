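#' Systematic per-feature survival screen (pipeline mode)
#'
#' For every feature (a gene's expression row or a pathway's score row) the
#' samples are dichotomized at the feature's median, a Cox
#' proportional-hazards model of the high-vs-low indicator is fitted
#' (optionally adjusted for clinical covariates, additively or with
#' group-by-covariate product terms), and the hazard ratio with its Wald
#' and likelihood-ratio p-values is collected. Benjamini-Hochberg
#' correction is applied across all features whose fit succeeded; failed
#' fits are recorded with a reason code and excluded from the family.
#'
#' The reported `hazard_ratio` is for the high-score group relative to the
#' low-score group. Under a multiplicative interaction model this is the
#' group effect at the covariate reference level; interaction coefficients
#' stay available through the per-feature fits. The likelihood-ratio test
#' compares the full fitted model against the null (empty) model.
#'
#' @param cohort A `cohort` from [build_cohort()].
#' @param features Numeric matrix, features x samples, columns aligned to
#'   (a superset of) the cohort samples: an expression matrix for
#'   gene-level screening or a `score_matrix` for pathway-level screening.
#' @param feature_kind `"gene"` or `"pathway"` (recorded per row).
#' @param covariates Optional character vector of clinical column names to
#'   adjust for. Samples missing a covariate are dropped per fit.
#' @param interaction `"none"`, `"additive"` (main effects only) or
#'   `"multiplicative"` (adds group-by-covariate product terms). Both
#'   `"additive"` and `"multiplicative"` require `covariates`.
#' @param ties Cox tie handling, `"efron"` or `"breslow"`.
#' @param bh_on Which p-value the BH correction is computed on:
#'   `"lr"` (default, the ranking statistic) or `"wald"`.
#' @return A `screen_table` data frame, one row per successfully fitted
#'   feature, sorted by ascending `lr_p`, with columns `feature`, `kind`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `wald_p`, `lr_statistic`,
#'   `lr_p`, `bh_adjusted_p`, `n`, `n_events`; attributes `metadata`
#'   (cutoff rule, covariates, interaction, ties) and `failures`
#'   (data frame of feature + reason for skipped fits).
#' @export
screen_features <- function(cohort, features, feature_kind = c("pathway", "gene"),
                            covariates = NULL,
                            interaction = c("none", "additive", "multiplicative"),
                            ties = c("efron", "breslow"),
                            bh_on = c("lr", "wald")) {
  feature_kind <- match.arg(feature_kind)
  interaction <- match.arg(interaction)
  ties <- match.arg(ties)
  bh_on <- match.arg(bh_on)
  stopifnot(inherits(cohort, "cohort"), is.matrix(features))
  if (interaction != "none" && is.null(covariates)) {
    stop_ps("interaction = '", interaction, "' requires covariates")
  }
  clin <- cohort$clinical
  if (!is.null(covariates)) {
    missing <- setdiff(covariates, colnames(clin))
    if (length(missing) > 0) {
      stop_ps("covariate(s) not in clinical table: ",
              paste(missing, collapse = ", "))
    }
  }
  samp <- intersect(clin$sample_id, colnames(features))
  if (length(samp) < 2) stop_ps("features share < 2 samples with the cohort")
  features <- features[, samp, drop = FALSE]
  clin <- clin[match(samp, clin$sample_id), , drop = FALSE]
  if (is.null(rownames(features))) stop_ps("features matrix must have row names")

  ia <- if (interaction == "multiplicative") paste0("group:", covariates) else NULL
  rows <- vector("list", nrow(features))
  failures <- list()
  for (i in seq_len(nrow(features))) {
    feat <- rownames(features)[i]
    res <- tryCatch({
      grp <- dichotomize(features[i, ], rule = "median")
      design <- data.frame(group = factor(grp, levels = c("low", "high")))
      if (!is.null(covariates)) design <- cbind(design, clin[covariates])
      fit <- suppressMessages(
        cox_fit(clin$time, clin$event, design, ties = ties, interactions = ia))
      data.frame(feature = feat, kind = feature_kind,
                 hazard_ratio = unname(fit$hazard_ratios["grouphigh"]),
                 ci_low = unname(fit$ci_low["grouphigh"]),
                 ci_high = unname(fit$ci_high["grouphigh"]),
                 wald_p = unname(fit$wald_p["grouphigh"]),
                 lr_statistic = fit$lr_statistic, lr_p = fit$lr_p,
                 n = fit$n, n_events = fit$n_events,
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures[[length(failures) + 1]] <- data.frame(feature = feat, reason = res,
                                                     stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- res
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  failures <- if (length(failures) > 0) do.call(rbind, failures) else
    data.frame(feature = character(), reason = character())
  if (length(rows) == 0) {
    stop_ps("all feature fits failed; reasons: ",
            paste(unique(failures$reason), collapse = " | "))
  }
  tab <- do.call(rbind, rows)
  p_family <- if (bh_on == "lr") tab$lr_p else tab$wald_p
  tab$bh_adjusted_p <- stats::p.adjust(p_family, method = "BH")
  tab <- tab[order(tab$lr_p, tab$feature), , drop = FALSE]
  tab <- tab[, screen_table_columns, drop = FALSE]
  rownames(tab) <- NULL
  structure(tab,
            metadata = list(cutoff = "median",
                            covariates = covariates %||% character(),
                            interaction = interaction, ties = ties,
                            bh_on = bh_on),
            failures = failures,
            class = c("screen_table", "data.frame"))
}

#' Filter a screen table to significant high-risk features
#'
#' Keeps rows with `hazard_ratio > hr_threshold` (strict) and the chosen
#' p-value `< p_threshold` (strict), preserving order.
#'
#' @param table A `screen_table`.
#' @param hr_threshold Hazard-ratio threshold (default 1).
#' @param p_threshold P-value threshold (default 0.05).
#' @param use_adjusted Use `bh_adjusted_p` instead of `lr_p` (default FALSE).
#' @return The filtered `screen_table` (possibly zero rows).
#' @export
filter_high_risk <- function(table, hr_threshold = 1, p_threshold = 0.05,
                             use_adjusted = FALSE) {
  stopifnot(inherits(table, "screen_table"))
  if (nrow(table) == 0) stop_ps("screen table is empty")
  p <- if (use_adjusted) table$bh_adjusted_p else table$lr_p
  keep <- table$hazard_ratio > hr_threshold & p < p_threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes_keep(out, table)
}

attributes_keep <- function(out, table) {
  attr(out, "metadata") <- attr(table, "metadata")
  attr(out, "failures") <- attr(table, "failures")
  class(out) <- class(table)
  out
}

#' Hazard-ratio ranking of a gene-level screen
#'
#' Orders gene features by decreasing hazard ratio (ties broken by
#' ascending likelihood-ratio p, then symbol) for use as preranked GSEA
#' input.
#'
#' @param table A `screen_table` containing gene-kind rows.
#' @return A `ranked_gene_list` (columns `gene`, `value` = hazard ratio).
#' @export
hr_ranking <- function(table) {
  stopifnot(inherits(table, "screen_table"))
  genes <- table[table$kind == "gene", , drop = FALSE]
  if (nrow(genes) == 0) stop_ps("no gene-kind rows in screen table")
  ord <- order(-genes$hazard_ratio, genes$lr_p, genes$feature)
  genes <- genes[ord, , drop = FALSE]
  structure(data.frame(gene = genes$feature, value = genes$hazard_ratio,
                       stringsAsFactors = FALSE),
            class = c("ranked_gene_list", "data.frame"))
}

#' Annotation (category) enrichment of selected gene sets
#'
#' For each annotation category (e.g. a connectivity-map perturbation name
#' or mechanism-of-action class), builds the 2x2 table of selected vs
#' non-selected sets by in-category vs out-of-category membership over the
#' screened universe and computes the conditional odds ratio with a
#' two-sided Fisher exact p-value; Benjamini-Hochberg correction is
#' applied across categories. Degenerate tables can yield an infinite
#' odds ratio, which is reported as `Inf`.
#'
#' @param selected Character vector of selected set names (e.g. from
#'   [filter_high_risk()]).
#' @param universe Character vector of all tested set names; `selected`
#'   must be a subset.
#' @param annotation Data frame with columns `set` and `category` (a set
#'   may map to several categories).
#' @return Data frame with one row per category: `category`, `n_selected`,
#'   `n_category`, `odds_ratio`, `p`, `bh_q`, sorted by `p`.
#' @export
annotation_enrichment <- function(selected, universe, annotation) {
  if (length(selected) == 0 || length(universe) == 0) {
    stop_ps("selected and universe must be non-empty")
  }
  if (!all(selected %in% universe)) stop_ps("selected must be a subset of universe")
  if (!all(c("set", "category") %in% colnames(annotation))) {
    stop_ps("annotation needs columns 'set' and 'category'")
  }
  annotation <- annotation[annotation$set %in% universe, , drop = FALSE]
  cats <- unique(annotation$category)
  if (length(cats) == 0) stop_ps("no annotation categories overlap the universe")
  sel <- unique(selected)
  uni <- unique(universe)
  rows <- lapply(cats, function(cat) {
    in_cat <- unique(annotation$set[annotation$category == cat])
    a <- sum(sel %in% in_cat)
    b <- length(sel) - a
    c_ <- sum(uni %in% in_cat) - a
    d <- length(uni) - length(sel) - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    data.frame(category = cat, n_selected = a, n_category = a + c_,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resampling validation of a survival screen
#'
#' Repeats the median-cutoff screen on random subsamples (without
#' replacement) of the cohort and reports, per feature, the fraction of
#' completed repeats in which it passes the high-risk filter
#' (`hazard_ratio > 1`, `lr_p < 0.05` by default). Repeats whose subsample
#' retains fewer than 2 events are skipped and counted.
#'
#' @inheritParams screen_features
#' @param fraction Fraction of samples drawn per repeat, in (0, 1]
#'   (default 0.75).
#' @param n_repeats Number of resampling repeats.
#' @param seed Integer seed; results are reproducible given the seed.
#' @param hr_threshold,p_threshold,use_adjusted Passed to
#'   [filter_high_risk()].
#' @return Data frame with `feature`, `selection_frequency`, `n_selected`,
#'   `n_repeats_completed`; attribute `n_skipped` counts degenerate
#'   repeats.
#' @export
resample_validation <- function(cohort, features, feature_kind = "pathway",
                                fraction = 0.75, n_repeats = 20, seed = 1,
                                covariates = NULL, hr_threshold = 1,
                                p_threshold = 0.05, use_adjusted = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  if (fraction <= 0 || fraction > 1) stop_ps("fraction must be in (0, 1]")
  n <- nrow(cohort$clinical)
  m <- max(2L, floor(fraction * n))
  feat_names <- rownames(features)
  counts <- stats::setNames(rep(0L, length(feat_names)), feat_names)
  n_done <- 0L
  n_skipped <- 0L
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
      sub <- cohort
      sub$clinical <- cohort$clinical[idx, , drop = FALSE]
      sub$expression <- cohort$expression[, sub$clinical$sample_id, drop = FALSE]
      if (sum(sub$clinical$event) < 2) {
        n_skipped <- n_skipped + 1L
        next
      }
      tab <- tryCatch(
        suppressWarnings(screen_features(sub, features,
                                         feature_kind = feature_kind,
                                         covariates = covariates)),
        error = function(e) NULL)
      if (is.null(tab)) {
        n_skipped <- n_skipped + 1L
        next
      }
      hits <- filter_high_risk(tab, hr_threshold, p_threshold, use_adjusted)
      counts[hits$feature] <- counts[hits$feature] + 1L
      n_done <- n_done + 1L
    }
  })
  if (n_done == 0) stop_ps("all resampling repeats were degenerate")
  out <- data.frame(feature = feat_names,
                    selection_frequency = unname(counts) / n_done,
                    n_selected = unname(counts),
                    n_repeats_completed = n_done,
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}
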