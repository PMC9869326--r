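---
title: "Methods and design of dexatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of dexatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dexatlas)
```

`dexatlas` turns raw count matrices and heterogeneous sample metadata into
a compendium of uniformly computed pairwise differential-expression (DE)
comparisons, and then serves queries against that compendium. This
vignette explains the statistical machinery, the parameters that matter,
the choices made where the design was genuinely open, and what the
synthetic-data tests do and do not establish.

## Covariates from mixed metadata

Every comparison potentially carries different nuisance metadata — some
continuous (age, time to freezing), some categorical (sex, sequencing
strategy) — so the design cannot be fixed in advance. The pipeline is:

1. **Imputation** (`impute_metadata`). Continuous gaps get the mean within
   a stratum (by default sex, the convention for population cohorts);
   categorical gaps get the literal level `"unknown"`. If the stratum
   column is absent, non-categorical, or itself incomplete, the global
   mean is used instead — arbitrary inputs cannot be assumed to carry sex.
2. **Coding**. Continuous columns are doubled (Escoffier coding): x is
   min–max rescaled to z ∈ [−1, 1] and stored as ((1+z)/2, (1−z)/2). The
   scaling range is not canonical; min–max doubling was chosen because it
   gives every variable — doubled or indicator-coded — a constant row sum
   of 1, hence equal mass in the correspondence analysis. Categorical
   columns are one-hot coded. Constant or single-level columns are
   dropped with a warning rather than erroring, since real metadata
   frequently contains them.
3. **Correspondence analysis** (`correspondence_analysis`). Classical CA
   of the concatenated nonnegative table: eigenvalues are squared singular
   values of the standardized residual matrix and sum to χ²/n (verified
   against a direct χ² computation in the tests). CA rather than PCA
   because the coded table mixes variable types on a common
   profile/mass geometry.
4. **Elbow selection** (`select_components`). A scree elbow "picked by
   eye" is not reproducible, so it is operationalized: the elbow point is
   the scree position with maximum perpendicular distance to the chord
   joining the first and last eigenvalues (ties toward the smaller
   index), and the components *before* that point are retained, with a
   minimum of one. A linear scree keeps one component. The count can be
   overridden (`k =` in `build_covariates`) when the automatic choice is
   unsatisfying.

The comparison's own condition variable (and anything identical to it)
never enters the covariates; if nothing else is usable, the design is
intercept-only.

## Differential expression

Counts are normalized with median-of-ratios size factors (geometric-mean
reference over genes positive in all samples; factors rescaled to
geometric mean 1). Genes with at least one nonzero count are tested; there
is no independent filtering or outlier handling — a deliberate
simplification, documented rather than hidden.

Each gene is fitted with a log-link negative-binomial GLM (variance
μ + αμ²) under the full design (intercept + covariates + condition) and
the reduced design (without condition), and tested with the likelihood
ratio against χ²(1). The reference level is the alphabetically first
condition label, so log₂ fold-changes are non-reference over reference,
and the reported effect is the maximum-likelihood coefficient (no
shrinkage).

**Dispersion.** α is estimated per gene by maximizing the Cox–Reid
adjusted profile likelihood (the −½ log det(XᵀWX) correction for the
fitted means), floored at 1e−8 and capped at 10, starting from a
method-of-moments value. Two choices deserve emphasis:

- No moderation across genes (no trend, no shrinkage toward a prior).
  The acceptance properties are therefore calibration-based (type-I
  error, power) rather than value-parity with moderated pipelines.
- The estimate is computed **under the reduced design**. Estimating α
  under the full design couples the estimate to the tested contrast:
  genes whose groups differ by chance get a smaller α and an inflated
  LRT, which measurably breaks calibration at small n (observed type-I
  ≈ 0.08 at n = 10 per group). Excluding the tested term restores nominal
  behavior (≈ 0.05) and is conservative for genuinely DE genes, whose α
  absorbs some signal; at the planted-effect sizes used in the tests
  (|log₂FC| = 2, n = 10 per group) power remains essentially 1.

Genes whose fits fail are flagged and excluded from the FDR; a comparison
fails only if more than half its genes are unfittable. DEGs are genes with
BH FDR < 0.05 (re-thresholdable later with `apply_cutoffs`, which also
takes a linear fold-change cutoff — the validation analyses use 1.5).

## Compendium assembly

Candidate comparisons pass interpretability screening
(`check_inclusion`): at least three replicates per condition; no generic
condition identifiers (a caller-set flag — this cannot be detected
automatically); no cross-tissue contrasts; no controlled-for categorical
variable perfectly stratifying the groups; no `NA`/`unknown` condition;
time-series pairs must involve the reference level or be adjacent steps;
and in studies with more than three candidate comparisons only
treatment-vs-control contrasts are kept. After DE, comparisons with fewer
than 5 or more than 10000 DEGs are dropped. Every exclusion carries a
machine-readable reason, and the build report accounts for every input.

Survivors are named `STUDY: Tissue.cond1 vs cond2` (conditions
alphabetical; the single token `vs` is used throughout for
machine-parsability), annotated by ranked-hypergeometric enrichment of
their DEG list — ranked by ascending FDR, ties broken by descending
|log₂FC| then gene id, a tie-break that had to be fixed somewhere —
against the pathway database (sets of 15–2000 genes) and the TF-target
database (15–5000), with the comparison's detected genes as background.
All terms are stored regardless of significance. Each record gets a
summary card: top 15 up- and downregulated genes, top 5 pathways and TFs,
DEG and sample counts.

## Enrichment engine

`ranked_hypergeometric` scans every prefix of the ranked query and
returns the minimum upper-tail hypergeometric p over depths (smallest
depth on ties) with the overlapping genes at that depth. The minimum is
used raw — inherited behavior from the ordered-enrichment tools this
mirrors — with multiplicity handled across terms by BH, not across
depths; this makes absolute p-values optimistic but leaves rankings and
FDR-based decisions in the regime the tests calibrate.

`empirical_brown_fuse` combines dependent p-value channels: each channel
is transformed by w = −2 ln ECDF(p) (right-continuous, so the smallest
value maps to 1/n and log(0) cannot occur), the per-item sums are referred
to a scaled χ² with moments matched to E = 2m and the empirically
estimated covariance. With one channel the input is returned unchanged;
with independent channels the result tracks Fisher's method (KS distance
< 0.05 at 2000 items in the tests). The ECDF transform quantizes p-values
to multiples of 1/n, so perfectly duplicated channels collapse to the
input only up to that granularity (≈ 6% median relative error at
n = 1000) — the data-driven (empirical) variant was chosen over the
polynomial covariance approximation because joint samples of the fused
channels are always available here; the approximation error is the price.

## Queries

`prepare_user_input` normalizes the three accepted input shapes. A full
query (genes + p-values + coefficients) enables all four channels. An
ordered list receives evenly spaced surrogate p-values with the least
significant fixed at 0.049 — just under the 0.05 significance default —
and loses the Pearson channel; an unordered list receives 0.049
everywhere and loses both correlation channels. Duplicate symbols
collapse to the minimum-p occurrence by default (first occurrence
available via flag); symbols can be upper-cased for human-gene matching,
and should not be for Ensembl ids.

`query_compendium` computes: (1) user pathway/TF enrichment against the
term databases; (2) the DEG-overlap channel — ranked enrichment of the
query against every comparison's DEG set, background = user background or
the compendium universe (query genes missing from it are appended with a
warning); (3) pathway- and TF-overlap channels — hypergeometric overlap
of the user's significant terms with each comparison's significant terms
over the universe of all term ids in the respective filtered database
(the term universe had to be fixed; all filtered term ids is the
least-assuming choice); (4) Spearman/Pearson correlations between user
coefficients and DEG log₂ fold-changes, computed only for comparisons
significant in the DEG-overlap channel, on ≥ 3 overlapping DEGs with
non-constant vectors. In ordered mode the rank order stands in for the
coefficient, so only Spearman is meaningful and only it is reported.
Every channel is BH-corrected at α = 0.05 (overridable).

`input_as_reference` flips the roles: the user's genes become a
single-set database and each comparison's FDR-ranked DEG list is the
query — useful when the user list is unranked but the compendium's
weights should drive the enrichment. `enrich_genes_only` skips the term
channels entirely (the right mode for identifier namespaces without term
annotation).

## Compendium analytics

- `pairwise_comparison_correlation`: for each pair, genes DE in at least
  one and detected in both; Pearson correlation of the FDR vectors; r²
  stored, missing below 3 co-usable genes.
- `cluster_comparisons`: Ward.D2 on Euclidean distances between rows of
  |r| (the absolute correlation). The source convention is ambiguous
  between |r| and r²; |r| = √r² preserves more dynamic range and is the
  default, with r² available via flag. Missing similarities are imputed
  as 0 (most conservative). The default height cut of 30 is
  data-scale-dependent and kept for parity; `n_clusters` provides a
  scale-free alternative used throughout the tests.
- `median_cluster_overlap`: median over ordered within-cluster pairs of
  |DEG_i ∩ DEG_j|/|DEG_i| — "a member typically shares this fraction of
  its DEGs with another member".
- `annotate_clusters`: member FDR vectors are the channels (genes missing
  in a member contribute p = 1), fused per gene with empirical Brown,
  and the fused ranking is enriched against a gene-set database.
- `de_prior`: per-gene frequency of being DE among comparisons where the
  gene is detected, densely ranked (ties lexicographic). This is the
  frequency-based prior; externally published priors computed with other
  algorithms enter only as user-supplied tables for
  `prior_overlap_curve`, which tests top-q overlap at 1% increments and
  leaves the q = 1 odds ratio missing (the sets equal the universe).
- `build_fc_matrix` / `elastic_net_extract` / `predictor_importance`:
  genes detected in ≥ 70% of comparisons (inclusive; adjustable) enter a
  genes × comparisons log₂FC matrix, non-detected cells zero-filled with
  the mask retained — sparse genes otherwise over-predict whatever they
  co-occur with, and the filter plus zero-fill is the concrete
  resolution adopted. The elastic net uses mixing α = 0.5 with the
  penalty chosen by 10-fold CV at the 1-SE rule under a caller-supplied
  seed (neither is canonical; both are exposed). Gene-by-gene importance
  is O(genes²) elastic-net fits, so `predictor_importance` caps the gene
  count (default 2000, keeping the highest-variance genes) — at desk
  scale the tests use tens of genes.

## Synthetic data: what it does and does not show

`simulate_counts` draws log-normal baseline means (log-mean log 100,
log-sd 1.2 — a realistic bulk RNA-seq dynamic range), plants
normal-distributed log₂ fold-changes on a random gene subset, and
generates NB counts at a single dispersion (default 0.1, a typical bulk
value), with an optional balanced or confounded batch shift.
`simulate_compendium` builds comparison records directly: per-block
shared DEG cores plus private DEGs, FDR values Beta(1, 50) truncated
below 0.05 for DEGs and Uniform(0.05, 1] otherwise (so thresholding
behaves like real output), and block-correlated fold-changes. The first
comparison's full ranked DEG list doubles as a ready-made query whose
source comparison strictly dominates its block-mates.

Calibration and recovery tests run at n = 10 per group, 2000 genes for
null calibration, and 12-comparison compendia — sizes chosen to mirror
the small-cohort end of real data while keeping the full suite fast.
Passing them shows the machinery is correct and calibrated under the
generative model: single shared dispersion, no outliers, no library
composition bias, clean block structure, exchangeable genes. It does not
show robustness to dispersion trends, count outliers, or correlated genes
— the situations where moderated pipelines earn their complexity — and no
claim is made that gene-wise dispersion matches a moderated analysis
value-for-value on real data.

## Numerical conventions

Hypergeometric odds ratios use the Haldane 0.5 correction when any 2×2
cell is zero. p-values entering Brown fusion are clamped to
(double.xmin, 1]. BH is used wherever "FDR-adjusted" appears. Degenerate
inputs prefer explicit missing values over silent defaults: correlations
on < 3 points are NA, singleton clusters have NA median overlap, the
q = 1 overlap odds ratio is NA. All generators and CV fits are
deterministic given their seed; identical builds are byte-identical.
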