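# pathsurv

Pathway-level survival analysis for transcriptomic cohorts: single-sample
pathway activity scoring, systematic Cox proportional-hazards screening of
gene-set databases, hazard-ratio-ranked gene set enrichment analysis
(GSEA), and Jaccard-based pathway connectivity clustering.

## The problem

Single-gene survival associations in expression cohorts are noisy and hard
to interpret. A more robust strategy summarizes each gene set (a pathway,
an immune signature, a drug-perturbation signature) into one activity value
per patient, relates that value to time-to-event outcome, and then asks
which pathways — and which clusters of overlapping pathways — stratify
patient risk. `pathsurv` implements that workflow as a scriptable R
package for biostatisticians and computational biologists working with
expression matrices, clinical follow-up tables and GMT gene-set
collections, with a synthetic-cohort generator so the whole pipeline can be
validated against planted ground truth.

## The statistics at the core

**Single-sample scoring.** The default ssGSEA statistic ranks the genes of
each sample by decreasing expression and accumulates, along the ranking,
the difference between the weighted in-set rank ECDF and the out-of-set
ECDF; in-set steps at a gene with rank `r` are weighted `|r|^alpha`
(default `alpha = 0.25`). Each sample's score depends only on its own
expression ranks. Combined z-scores (`sum(z) / sqrt(k)`) and PLAGE (the
leading right singular vector of the standardized member-gene submatrix)
are available as alternatives.

**Screening.** Each feature (pathway score or gene) is dichotomized at its
median; a Cox proportional-hazards model (Efron ties) of high vs low is
fitted, optionally adjusted for clinical covariates additively or with
group-by-covariate interactions. Features are ranked by the
likelihood-ratio p-value, Benjamini–Hochberg-corrected across the tested
family, and filtered to significant high-risk features
(`HR > 1`, `p < 0.05`).

**Hazard-ratio GSEA.** Genes ranked by their screen hazard ratio feed a
preranked GSEA: the enrichment score is the extremum of the weighted
Kolmogorov–Smirnov-like running sum, with significance from gene-label
permutations and NES normalization by the mean same-sign permutation
score.

**Connectivity.** Pairwise pathway similarity `J(A,B) = |A∩B| / |A∪B|`,
hierarchical clustering on the Jaccard distance `1 − J`, cut into a
user-chosen number of modules.

## Worked example

Simulate a 120-patient cohort in which pathway `SET0003` drives hazard
(log-HR 0.9 per unit latent activity), score all 30 pathways with ssGSEA,
and screen them against overall survival:

```r
library(pathsurv)

cf  <- sim_config(n_samples = 120, n_genes = 500, n_sets = 30,
                  planted_sets = c("3" = 0.9), seed = 42)
sim <- simulate_cohort(cf)
sim$cohort
#> cohort: 500 genes x 120 samples, 84 events / 120 samples

scores <- pathway_scores(sim$cohort$expression, sim$sets)  # ssGSEA default
tab    <- screen_features(sim$cohort, unclass(scores), feature_kind = "pathway")
head(as.data.frame(tab)[, c("feature", "hazard_ratio", "ci_low", "ci_high",
                            "lr_p", "bh_adjusted_p")], 3)
#>   feature hazard_ratio ci_low ci_high     lr_p bh_adjusted_p
#> 1 SET0003        2.991  1.888   4.740 1.98e-06      5.95e-05
#> 2 SET0021        1.905  1.216   2.986 4.55e-03      6.60e-02
#> 3 SET0014        0.543  0.349   0.845 6.60e-03      6.60e-02

filter_high_risk(tab)$feature
#> [1] "SET0003" "SET0021" "SET0001" "SET0026"
```

The planted pathway tops the table: patients whose ssGSEA score for
`SET0003` is above the cohort median die at about 3.0 times the rate of
below-median patients (95% CI 1.9–4.7), and it is the only pathway
surviving BH correction at 5% FDR. A Kaplan–Meier comparison of the two
groups agrees:

```r
grp <- dichotomize(unclass(scores)["SET0003", ], "median")
logrank_test(sim$cohort$clinical$time, sim$cohort$clinical$event, grp)
#> log-rank chi-square 23.7, p = 1.1e-06
```

From here, `hr_ranking()` of a gene-level screen feeds `gsea_preranked()`,
and `jaccard_matrix()` + `cluster_pathways()` group the prioritized
pathways into modules. The same workflow is available from a shell through
the CLI wrapper (`system.file("cli", "pathsurv.R", package = "pathsurv")`)
with subcommands `simulate`, `score`, `km`, `screen`, `enrich`, `gsea` and
`connect`.

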