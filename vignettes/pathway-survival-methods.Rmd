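---
title: "Methods: pathway-level survival screening with pathsurv"
author: "pathsurv maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-level survival screening with pathsurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pathsurv` turns gene-set databases and expression-plus-outcome cohorts
into pathway-level risk statements. This vignette is the package's account
of the statistical machinery: the models and their assumptions, the
tunable parameters and why their defaults are what they are, what the
synthetic-cohort generator does and does not emulate, the numerical
conventions, and the design decisions taken where the methodology was
genuinely open.

## 1. Single-sample pathway scoring

### ssGSEA (default)

For sample $j$ with $N$ genes, rank genes by decreasing expression. For a
set $S$ with $k$ members present in the matrix, the score is

$$\mathrm{score}(S, j) \;=\; \sum_{i=1}^{N}\left[
\frac{\sum_{\ell \le i,\, \ell \in S} w_\ell}{\sum_{\ell \in S} w_\ell}
\;-\;
\frac{\#\{\ell \le i : \ell \notin S\}}{N - k}
\right],
\qquad w_\ell = |r_\ell|^{\alpha},$$

where $r_\ell$ is the expression rank of gene $\ell$ within the sample
(top gene has rank $N$) and $\alpha \ge 0$ weights high-ranking genes.
The statistic is the summed difference between the weighted in-set rank
ECDF and the unweighted out-of-set ECDF. Three consequences matter in
practice:

* **Per-sample independence.** A sample's unnormalized score depends only
  on that sample's ranks; adding or removing other patients changes
  nothing. This is why ssGSEA is the default for survival work, where
  cohorts are assembled incrementally.
* **Rank invariance.** Any strictly monotone transform of a sample's
  expression (log, quantile shift) leaves its score unchanged, so linear
  vs log input scale is immaterial for ssGSEA. The z-score and PLAGE
  methods are *not* scale-invariant; inputs are used as supplied and this
  is deliberately not hidden behind an automatic transformation.
* **Compositionality.** Ranks are relative: if the members of one pathway
  move up, every other gene moves down slightly. Planting a single strong
  hazard pathway therefore induces *negative* score correlations — and
  protective (HR < 1) survival associations — in unrelated sets. The
  high-risk filter (`HR > 1`) in the screening stage removes these mirror
  associations; this is visible in the package's end-to-end validation.

Defaults: $\alpha = 0.25$ and division of the final matrix by its global
$\max - \min$, matching the conventional implementation of the statistic;
both are exposed because neither affects rank-based dichotomization (the
median and quartile group labels are invariant to the normalization).
`min_set_size = 2`: a one-gene "pathway" is a gene, not a set; sets
falling below the threshold after intersection with the matrix are
dropped and listed in the `dropped_sets` attribute. Rank ties are averaged
for the weights, and the traversal order breaks expression ties by gene
symbol so results are identical across platforms and runs. A sample with
completely constant expression is scored under that tie-break with a
warning rather than an error.

### Combined z-score and PLAGE

`zscore`: standardize each gene across samples, then
$\mathrm{score}(S,j) = \sum_{g \in S} z_{gj} / \sqrt{k}$. Zero-variance
genes cannot be standardized and are excluded from the set with a
warning. `plage`: the score vector over samples is the right singular
vector of the standardized member submatrix belonging to the largest
singular value. The singular vector's sign is arbitrary, so it is fixed
by positive correlation with the mean member z-score; a single-gene set
degenerates to the standardized gene itself. The GSVA kernel-ECDF variant
is recognized as a method name but deliberately rejected as not
implemented.

## 2. Dichotomization and cutpoints

Patient groups are formed from scores by:

* **median** (default): `low` if score ≤ median, else `high`. Boundary
  ties go to the low group — a deterministic convention that keeps
  "above-median" literally true for the high group.
* **quartile**: four ordered groups Q1–Q4 at the 25/50/75% boundaries,
  boundary ties assigned downward; downstream Cox encoding uses Q1 as the
  reference level.
* **value**: a user threshold, same ≤ convention.
* **optimal cutpoint**: `optimal_cutpoint()` evaluates the log-rank
  chi-square at every midpoint between consecutive distinct scores whose
  split leaves at least `ceil(minprop * n)` patients on each side
  (`minprop = 0.1`, the conventional band for maximally selected rank
  statistics) and returns the maximizing midpoint. The naive p-value of a
  maximally selected statistic is strongly anti-conservative — the test
  suite demonstrates a multiple of the nominal type-I rate under the null
  — so the result carries `selection_biased = TRUE` and the uncorrected p
  is labelled `p_naive`; no selection-bias correction is applied, and
  published cutpoint p-values should come from an independent cohort.
  Worth knowing: with a censored tail, the maximizing split is not
  necessarily the visually "separating" gap, because the variance term in
  the standardized statistic rewards balanced splits; the tests verify
  the argmax against a brute-force scan rather than intuition. Ties in
  the statistic resolve to the smallest threshold.

The median and quartile rules depend on scores only through ranks, so the
choice of ssGSEA normalization cannot change group labels.

## 3. Survival models

Kaplan–Meier estimation, the Mantel–Haenszel log-rank test, Cox partial
likelihood maximization and the scaled-Schoenfeld proportional-hazards
test are delegated to the `survival` package (`survfit`, `survdiff`,
`coxph`, `cox.zph`), the reference implementation of this machinery in R;
`pathsurv` wraps them behind typed results (`km_estimate`, `cox_result`,
`ph_diagnostics`) and validates inputs. Conventions:

* Ties: Efron by default (Breslow available); on tie-free data the two
  coincide, which the tests check to 1e-10.
* `cox_fit()` refuses constant and collinear designs up front, drops
  incomplete covariate rows per fit with a message, and converts
  monotone-likelihood warnings (perfect separation) into errors rather
  than returning a divergent estimate; anything with |beta| > 15 is
  treated as non-estimable.
* The likelihood-ratio statistic is `2 * (loglik_full - loglik_null)`
  against the empty model; per-term Wald z and p accompany it. The Newton
  fit is validated against a 1e-4-step grid search of an independently
  coded Efron partial likelihood.
* `ph_diagnostics()` correlates scaled Schoenfeld residuals with the
  Kaplan–Meier time transform (identity available), reports per-term and
  global chi-squares, and summarizes martingale-residual linearity for
  continuous covariates by the correlation of residuals with the
  covariate and its square. Simulation tests verify ~5% global rejection
  under proportional hazards and high power against a sign-reversing
  (crossing-hazard) effect.

## 4. Screening (pipeline mode)

`screen_features()` median-dichotomizes every feature, fits the Cox model
(plus covariates; `additive` adds main effects, `multiplicative` adds
group-by-covariate products, in which case the reported hazard ratio is
the group effect at the covariate reference level), and assembles one row
per feature sorted by the likelihood-ratio p. Benjamini–Hochberg runs on
the LR p-values by default (a flag switches to Wald) across *tests
actually performed*: features whose fit fails — constant after
dichotomization, non-convergence, separation — are excluded from the BH
family and reported with their reason string in the `failures` attribute,
so the family is never padded with tests that produced no p-value.
`filter_high_risk()` applies the strict `HR > 1` and `p < 0.05`
conventions (an HR of exactly 1 is not "high risk"). Both raw and
adjusted p columns are always emitted, so either significance convention
can be applied downstream.

`annotation_enrichment()` tests category membership (e.g. drug
mechanism-of-action classes) among selected vs non-selected sets with a
two-sided Fisher exact test over the *screened universe* — all sets that
were actually tested — rather than the whole database, which would
smuggle the database-to-cohort intersection filter into the null.
`resample_validation()` repeats the screen on seeded 75% subsamples
(without replacement) and reports per-feature selection frequencies;
repeats whose subsample retains fewer than two events are skipped and
counted.

## 5. Hazard-ratio-ranked GSEA

`gsea_preranked()` takes a two-column ranking (gene, hazard ratio) and a
collection. The enrichment score walks the ranking, adding
$|r_i|^p / \sum_{S}|r_j|^p$ at members and subtracting $1/(N-k)$
elsewhere; ES is the extremum of maximal absolute deviation (exact ties
between the positive and negative extremum resolve positive). Nulls come
from gene-label permutation — the only null available for preranked
input. Because that null depends on the set only through its effective
size, permutations are shared across equal-sized sets, which is
statistically identical to per-set permutation and proportionally
cheaper. The nominal p is add-one smoothed over same-sign permutation
scores, so the resolution is $1/(n_\mathrm{perm}+1)$ and no p is ever 0;
NES divides ES by the mean absolute same-sign permutation score (a
simple-scaling alternative is exposed).

One arithmetic consequence deserves emphasis: with $m$ sets tested, a
lone significant set's BH q-value cannot go below
$m/(n_\mathrm{perm}+1)$. FDR control at 5% over 100 sets therefore
requires more than 2000 permutations; the package's own end-to-end
validation uses 4000. The default weight is $p = 1$ on the hazard ratios
as supplied; a `log_transform` flag ranks by log(HR) instead, which
treats protective and hazardous effects symmetrically — raw HR remains
the default to match the two-column exchange format.

## 6. Connectivity

`jaccard_matrix()` computes $J(A,B) = |A \cap B| / |A \cup B|$;
`cluster_pathways()` clusters on the Jaccard distance $1 - J$ (a proper
metric, spot-verified on random triples) with `hclust`. Average linkage
is the default — it is robust for similarity-derived distances and the
merge heights are verified against a brute-force agglomeration that
recomputes inter-cluster distances from scratch at every step; complete
and single linkage are flags. Sets are sorted lexicographically by name
before clustering so the dendrogram and the k-cut are invariant to input
order. `cluster_gene_table()` expands clusters to (cluster, set, gene)
rows, joins per-gene screen statistics by symbol, and sorts stably so
exports are byte-identical across runs.

## 7. The synthetic-cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture: it is the
package's ground-truth instrument. Per planted set $s$, a latent activity
$a_s \sim N(0, \sigma_a)$ per patient; member-gene expression is
`baseline + loading * a_s + N(0, noise_sd)` with log-normal gene
baselines (meanlog 3, sdlog 1) so the matrix has the right-skewed look of
linear-scale RNA abundance; all other genes are noise around their
baselines. Event times follow a Weibull proportional-hazards model
(default shape 1 = exponential, rate 0.1) with linear predictor
$\sum_s \beta_s a_s$ plus any configured covariate effect, drawn by
inverse-CDF so the model is exact. Censoring is independent exponential
with its rate solved numerically from
$E[\text{censored fraction}] = \sum_i c/(c + r_i) / n$ — exact for the
exponential model; for Weibull shapes the event-time distribution is
approximated by an exponential with matched mean, so calibration there is
approximate. Everything derives from the config seed; a fixed config
reproduces the cohort bit-identically.

What the generator does *not* emulate: negative-binomial count noise and
library-size effects, batch structure, correlated censoring, informative
dropout, and realistic pathway overlap topology (sets are drawn
independently, so overlaps are small and random). Passing tests therefore
demonstrate the statistical machinery is correct and calibrated under a
clean proportional-hazards world — they do not certify performance on
real RNA-seq, where normalization and confounding dominate.

Default study conditions used across the validation suite: end-to-end
recovery uses 20 replicates of n = 200 patients, 1000 genes, 100 sets of
15–25 genes, one planted pathway at log-HR 0.8, 30% censoring; null
calibration uses 50 replicates of 20 sets at n = 100 (1000 pooled
p-values); PH-diagnostic calibration uses 200 replicates at n = 150.
These sizes give the binomial bands quoted in the tests while keeping the
default suite under a minute of compute.

## 8. Numerical conventions and edge cases

* All seeded operations (`simulate_cohort`, `gsea_preranked`,
  `resample_validation`) restore the caller's RNG state, so library calls
  do not perturb user scripts.
* Duplicate expression symbols collapse to the highest-mean row;
  duplicate ranked-list symbols keep the first occurrence; both log the
  event. GMT genes deduplicate preserving first occurrence.
* Ranked lists sort by descending value with a *stable* sort: tied
  hazard ratios keep their incoming order, which is what makes the
  `hr_ranking()` tie convention (ascending LR p, then symbol) survive a
  write/read round-trip through the two-column format.
* Cohort assembly orders samples lexicographically in both components, so
  downstream results never depend on input file order.
* Screen tables are written with 15 significant digits plus `#` metadata
  headers; `read_screen_table()` ignores the headers, and round-trips
  preserve all statistics well past 6 significant digits.
* Empty gene sets are rejected before Jaccard computation rather than
  adopting a 0/0 convention.

## 9. Known limitations

* No selection-bias correction for optimal cutpoints (flagged, not
  corrected); no time-varying covariates, stratified Cox or frailty
  models; no phenotype-permutation GSEA; no automatic choice of the
  cluster count k.
* The multiplicative interaction screen reports the group main effect at
  the covariate reference level; interaction coefficients are available
  from per-feature fits but not summarized in the screen table.
* z-score and PLAGE scores are sensitive to the expression scale supplied;
  users mixing cohorts should harmonize scales upstream.
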