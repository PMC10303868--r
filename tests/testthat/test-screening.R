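# Pipeline-mode screening, BH correction, filtering, ranking, enrichment

make_screen_cohort <- function(n = 60, n_feat = 8, seed = 3, beta = 0,
                               planted = 1) {
  set.seed(seed)
  feats <- matrix(rnorm(n_feat * n), n_feat, n,
                  dimnames = list(sprintf("F%02d", seq_len(n_feat)),
                                  sprintf("s%03d", seq_len(n))))
  eta <- if (beta != 0) beta * scale(feats[planted, ])[, 1] else rep(0, n)
  rates <- 0.1 * exp(eta)
  t_ev <- rexp(n, rates)
  t_cn <- rexp(n, 0.04)
  clin <- data.frame(sample_id = colnames(feats),
                     time = pmin(t_ev, t_cn),
                     event = as.numeric(t_ev <= t_cn),
                     age = rnorm(n, 60, 8))
  cohort <- build_cohort(feats, clin)
  list(cohort = cohort, features = feats)
}

test_that("BH correction in the screen equals the step-up oracle and handles m = 1", {
  sc <- make_screen_cohort()
  tab <- screen_features(sc$cohort, sc$features, feature_kind = "pathway")
  expect_no_failures(tab)
  expect_equal(tab$bh_adjusted_p, oracle_bh(tab$lr_p))
  expect_true(all(tab$bh_adjusted_p >= tab$lr_p))
  expect_false(is.unsorted(tab$lr_p))

  one <- screen_features(sc$cohort, sc$features[1, , drop = FALSE],
                         feature_kind = "pathway")
  expect_equal(one$bh_adjusted_p, one$lr_p)
})

test_that("BH step-up formula is honored on random p-vectors", {
  # p-vector [0.01, 0.02, 0.03, 0.04]: every adjusted value is 0.04
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:100, 1))
    adj <- p.adjust(p, method = "BH")  # the route the screen uses
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    expect_equal(order(adj[order(p)]), seq_along(p))  # monotone in raw p
  }
})

test_that("screen output is invariant to feature order and records failed fits", {
  sc <- make_screen_cohort()
  tab1 <- screen_features(sc$cohort, sc$features, feature_kind = "pathway")
  perm <- sample(nrow(sc$features))
  tab2 <- screen_features(sc$cohort, sc$features[perm, ], feature_kind = "pathway")
  expect_equal(as.data.frame(tab1), as.data.frame(tab2))

  feats <- sc$features
  feats[2, ] <- 1  # constant feature cannot be dichotomized
  tab3 <- screen_features(sc$cohort, feats, feature_kind = "pathway")
  fails <- attr(tab3, "failures")
  expect_equal(fails$feature, "F02")
  expect_match(fails$reason, "constant")
  expect_equal(nrow(tab3), nrow(feats) - 1)
  # BH family excludes the failed fit
  expect_equal(tab3$bh_adjusted_p, oracle_bh(tab3$lr_p))
})

test_that("covariate-adjusted and interaction screens wire the group term through", {
  sc <- make_screen_cohort(beta = 0.9)
  plain <- screen_features(sc$cohort, sc$features, feature_kind = "pathway")
  add <- screen_features(sc$cohort, sc$features, feature_kind = "pathway",
                         covariates = "age", interaction = "additive")
  mult <- screen_features(sc$cohort, sc$features, feature_kind = "pathway",
                          covariates = "age", interaction = "multiplicative")
  expect_setequal(plain$feature, add$feature)
  expect_setequal(plain$feature, mult$feature)
  expect_equal(plain$feature[1], "F01")  # planted feature leads the table
  expect_error(screen_features(sc$cohort, sc$features, feature_kind = "pathway",
                               interaction = "multiplicative"),
               "requires covariates")
  expect_error(screen_features(sc$cohort, sc$features, feature_kind = "pathway",
                               covariates = "bmi"), "not in clinical")
})

test_that("a planted hazard feature attains the smallest lr_p", {
  wins <- 0
  for (seed in 1:10) {
    sc <- make_screen_cohort(n = 120, n_feat = 12, seed = seed, beta = 1)
    tab <- screen_features(sc$cohort, sc$features, feature_kind = "pathway")
    if (tab$feature[1] == "F01") wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("high-risk filtering uses strict thresholds and preserves order", {
  tab <- structure(
    data.frame(feature = sprintf("f%02d", 1:10), kind = "pathway",
               hazard_ratio = c(2, 1.5, 1.0, 0.8, 3, 1.2, 0.5, 1.8, 1.1, 2.5),
               ci_low = 0.5, ci_high = 5,
               wald_p = 0.5,
               lr_statistic = 1,
               lr_p = c(0.01, 0.2, 0.01, 0.01, 0.04, 0.06, 0.01, 0.03, 0.9, 0.049),
               bh_adjusted_p = 0.5, n = 10, n_events = 8),
    class = c("screen_table", "data.frame"))
  out <- filter_high_risk(tab)
  # qualifying: HR > 1 strictly AND lr_p < 0.05 strictly
  expect_equal(out$feature, c("f01", "f05", "f08", "f10"))
  # HR exactly 1 is excluded even with small p
  expect_false("f03" %in% out$feature)
  # thresholds (0, 1.0) keep everything with p < 1
  expect_equal(nrow(filter_high_risk(tab, hr_threshold = 0, p_threshold = 1.0)),
               nrow(tab))
})

test_that("hazard-ratio ranking sorts by HR with documented tie-breaks and round-trips", {
  tab <- structure(
    data.frame(feature = c("g1", "g2", "g3", "g4", "pw"),
               kind = c("gene", "gene", "gene", "gene", "pathway"),
               hazard_ratio = c(0.5, 2.0, 1.2, 2.0, 9),
               ci_low = 0.1, ci_high = 9, wald_p = 0.1, lr_statistic = 1,
               lr_p = c(0.5, 0.2, 0.3, 0.1, 0.01), bh_adjusted_p = 0.5,
               n = 10, n_events = 9),
    class = c("screen_table", "data.frame"))
  rl <- hr_ranking(tab)
  # g4 beats g2 on equal HR by smaller lr_p; pathway row ignored
  expect_equal(rl$gene, c("g4", "g2", "g3", "g1"))
  f <- withr::local_tempfile(fileext = ".rnk")
  write_ranked_list(rl, f)
  expect_equal(read_ranked_list(f)$gene, rl$gene)

  none <- tab[tab$kind == "pathway", ]
  class(none) <- c("screen_table", "data.frame")
  expect_error(hr_ranking(none), "no gene-kind rows")
})

test_that("annotation enrichment matches the exhaustive hypergeometric oracle", {
  # 2x2 table (8,2; 10,80)
  ann <- data.frame(set = c(sprintf("sel%02d", 1:8), sprintf("bg%02d", 1:10)),
                    category = "moa_A")
  selected <- c(sprintf("sel%02d", 1:8), sprintf("selx%01d", 1:2))
  universe <- c(selected, sprintf("bg%02d", 1:10), sprintf("null%02d", 1:80))
  res <- annotation_enrichment(selected, universe, ann)
  expect_equal(res$p, oracle_fisher_p(8, 2, 10, 80), tolerance = 1e-10)
  ft <- fisher.test(matrix(c(8, 2, 10, 80), 2, byrow = TRUE))
  expect_equal(res$odds_ratio, unname(ft$estimate))
  expect_gt(res$odds_ratio, 1)

  # category covering all selected sets and none of the rest
  ann2 <- data.frame(set = selected, category = "perfect")
  res2 <- annotation_enrichment(selected, universe, ann2)
  expect_equal(res2$odds_ratio, Inf)
  expect_equal(res2$p, oracle_fisher_p(10, 0, 0, 90), tolerance = 1e-10)

  expect_error(annotation_enrichment(character(), universe, ann), "non-empty")
  expect_error(annotation_enrichment(c(selected, "ghost"), universe, ann),
               "subset")
})

test_that("null annotation categories give approximately uniform p-values", {
  set.seed(21)
  universe <- sprintf("S%03d", 1:60)
  pvals <- replicate(300, {
    selected <- sample(universe, 20)
    ann <- data.frame(set = sample(universe, 15), category = "rand")
    annotation_enrichment(selected, universe, ann)$p
  })
  # Fisher p-values are discrete and conservative; require that they are
  # not concentrated at small values and keep a uniform-like mean
  expect_lt(mean(pvals < 0.05), 0.07)
  expect_gt(mean(pvals), 0.4)
})

test_that("resampling validation is seeded, reproducible and identity at fraction 1", {
  sc <- make_screen_cohort(n = 80, n_feat = 6, seed = 9, beta = 1.2)
  full <- screen_features(sc$cohort, sc$features, feature_kind = "pathway")
  full_hits <- filter_high_risk(full)$feature

  rv1 <- resample_validation(sc$cohort, sc$features, fraction = 1.0,
                             n_repeats = 3, seed = 4)
  expect_true(all(rv1$selection_frequency[rv1$feature %in% full_hits] == 1))
  expect_true(all(rv1$selection_frequency[!rv1$feature %in% full_hits] == 0))

  rv2 <- resample_validation(sc$cohort, sc$features, fraction = 0.75,
                             n_repeats = 8, seed = 4)
  rv3 <- resample_validation(sc$cohort, sc$features, fraction = 0.75,
                             n_repeats = 8, seed = 4)
  expect_equal(rv2, rv3)

  # strongly planted feature is selected in most subsamples
  expect_gte(rv2$selection_frequency[rv2$feature == "F01"], 0.8)
})
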