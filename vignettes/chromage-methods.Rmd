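---
title: "Euchromatin scores and epigenetic age acceleration from histone-mark count matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Euchromatin scores and epigenetic age acceleration from histone-mark count matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromage)
```

## Scope and model

`chromage` analyzes cell-type-specific histone-modification profiling
(ChIP-seq or CUT&Tag of marks such as H3K27ac, H3K27me3, H3K4me3 and
H2AK119ub) *downstream* of alignment and peak calling: its inputs are
region-by-sample matrices of read counts, a sample sheet describing
genotype, age and replicate structure, and standard annotation files (BED,
bedGraph, GMT). The motivating design is a two-genotype (wild-type vs
Huntington's-disease knock-in), three-age (2, 6, 10 months) study of
striatal neurons, where the question is whether the disease genotype
*accelerates* the chromatin changes that normally accompany aging —
de-repression of polycomb-silenced bivalent developmental genes.

The analysis chain is:

1. **Normalization.** Median-of-ratios size factors
   (`size_factors_median_of_ratios()`): the reference for each region is
   the geometric mean of its counts across samples (regions with any zero
   excluded); a sample's factor is the median of its count-to-reference
   ratios. This estimator assumes that most regions are unchanged between
   samples; see *Limitations* for what happens when that assumption is
   strained.
2. **Per-gene z-scores** (`gene_zscores()`), computed per mark across *all*
   samples — both genotypes and all ages jointly — with the population SD.
   Joint scaling is what makes scores comparable across genotypes; a
   per-genotype z would erase exactly the cross-genotype differences the
   design asks about. Regions with zero SD are set to all-zero z-scores, so
   constant genes stay neutral downstream.
3. **Euchromatin score** (`euchromatin_score()`): per gene and per paired
   sample, `z(H3K27ac) − z(H3K27me3)`. Higher means more open, active
   chromatin. The two marks are profiled from splits of the same extract,
   so samples are paired at the replicate level on (genotype, age,
   replicate) (`pair_samples()`).
4. **Chromatin-state clustering** (`kmeans_cluster()` over
   `mark_profile_features()`), selection of the bivalent
   (H3K4me3-high + H3K27me3-high) cluster (`select_bivalent_cluster()`) and
   of its H2AK119ub-high/low subclusters (`split_high_low()`).
5. **The clock** (`fit_clock()`, `predict_epigenetic_age()`): ordinary
   least squares of the mean euchromatin score over the bivalent
   developmental-TF cluster against chronological age, fitted on wild-type
   samples only. Epigenetic age of any sample is read off by inverting the
   calibration line, and acceleration is predicted minus chronological age.
6. **Differential enrichment** (`nb_wald_differential()`): a moment-based
   negative-binomial Wald test on normalized counts with
   Benjamini–Hochberg control at 0.1, plus the rank tests
   (Mann–Whitney, Kruskal–Wallis with Bonferroni post-hocs) used for
   group comparisons of scores and signal changes.
7. **Dynamics**: trajectory-shape calls (`classify_trajectory()`),
   euchromatin-score modules (`detect_score_modules()`), the
   PRC1-CBX paralog-switch statistic (`paralog_switch_score()`) and
   gene-set overlap/enrichment tests.

## The synthetic study generator

Because the motivating datasets are full sequencing studies, the package
ships a generator (`study_config()`, `generate_study()`) that emulates
their *post-alignment shape*: per-gene counts for WT/HD × ages 2/6/10
months × replicates × marks, negative-binomially distributed
(`var = mu + alpha * mu^2`, `alpha = 0.05` shared across genes), with
library-size factors drawn uniformly from [0.6, 1.6] and one RNG stream per
mark split from the master seed (adding a mark never perturbs the others).

Five planted gene classes drive the means (log2 scale, as functions of the
*effective* age `e`):

* **background** — flat; the majority class (~78% of genes by default),
  because the normalization model requires that most regions be unchanged.
* **bivalent_c1** — bivalent developmental TFs: H3K4me3 high and flat,
  H3K27me3 high but declining (−0.06/month), H3K27ac rising
  (+0.06/month), H2AK119ub high and declining (−0.05/month). These genes
  euchromatinize with age; they are the clock's dial.
* **bivalent_c2** — same H3K27ac/H3K27me3 dynamics but H2AK119ub low and
  flat; distinguishes the PRC1-mark subclusters.
* **identity** — neuronal-identity genes: strongly active at baseline, with
  an HD-only H3K27ac decline and H3K27me3 gain (±0.08/month). This class
  is genotype-gated by construction, not age-gated, so it persists even at
  `kappa = 1`.
* **stress** — stress-response genes whose euchromatin-determining marks
  follow an inverted-U in effective age, peaking at 6 months
  (−0.02·(e−6)² for H3K27ac, mirrored for H3K27me3). On the WT clock this
  *peaks at 6 months*; HD reads the same curve at accelerated effective
  ages (3, 9, 15 months for `kappa = 1.5`) and therefore declines — one
  mechanism reproduces both genotypes' shapes.

Aging acceleration is multiplicative by default: HD effective age is
`kappa × age`, so `kappa = 1.5` makes a 6-month HD animal epigenetically
9 months old — a planted 3-month distortion the clock must recover. An
additive mode (`age + kappa` months) is available.

Baselines are drawn per gene (uniform log2 range [4, 7]) and shared across
marks up to a per-mark jitter (SD 0.25 log2), modelling the correlated
accessibility of a locus; the per-mark effect sizes above are calibration
choices (the motivating study reports significance, not effect sizes) made
once to give moderate, realistic dynamic ranges (≈2-fold across the
lifespan).

### What the generator does *not* emulate

Read-level artifacts (GC bias, duplication), peak-boundary uncertainty,
cell-type mixtures, gene–gene correlation beyond the shared baseline, and
per-gene dispersion variation. Passing tests therefore demonstrate that the
estimators recover their targets under the stated statistical model, not
that they are robust to every artifact of real sequencing data.

## Numerical and design choices

* **Size factors** use the arithmetic median on the ratio scale, exactly as
  defined; DESeq2 interpolates even-count medians in log space, so the two
  agree exactly at odd reference-row counts and to ~0.1% otherwise.
* **The Wald test** is moment-based: group means of normalized counts, a
  pseudocount of 1 bounding fold changes at zeros, and the delta-method
  standard error `(1/ln2)·sqrt(Σ_g (1/n_g)(1/(μ_g+pc)+α))`. It is
  deliberately simpler than a full NB GLM — no design matrices, no
  dispersion shrinkage toward a trend, no LFC shrinkage — because the
  downstream conclusions consume only normalized counts and a significance
  threshold. Under the generator's null (5,000 regions, 3 vs 3,
  `alpha = 0.05`) its empirical type-I error at nominal 0.05 is ≈0.047.
* **Dispersion** is estimated by pooled within-group method of moments with
  a floor (`alpha_min`) and optional 30% shrinkage toward the across-region
  median — enough structure for calibrated tests at desk scale.
* **kmeans** uses kmeans++ initialization and Lloyd iterations, best of
  `n_restarts` by inertia, fully seeded. Background-dominated designs have
  a tempting local optimum (splitting the big flat class while merging two
  small ones); 25 restarts found the global optimum in every seed we
  examined, so the pipeline call sites use 25.
* **Clustering features** are `log2(mean normalized count + 1)` per mark
  and per (genotype, age) group, *row-centered*: centering removes each
  gene's baseline level so clustering sees mark contrasts. We deliberately
  do not scale rows to unit variance — scaling inflates contrast-free
  background genes into unit-norm noise and destroys the partition
  (adjusted Rand index drops from ≈0.97 to ≈0.07 on the synthetic design).
* **Bivalent-cluster selection** maximizes `min(z̄_H3K4me3, z̄_H3K27me3)`
  over cluster means standardized across clusters, with ties broken by the
  larger sum then the smaller label. "Cluster 1 (high)" / "cluster 2 (low)"
  labels from `split_high_low()` are always derived from mean-signal
  ordering, never from raw kmeans label numbers.
* **The clock** is fitted on per-pair (replicate-level) scores, not group
  means, so residual SD is estimable; prediction refuses slopes below
  `1e-6` score-units/month, where the line carries no age information.
* **Score modules** replace a full co-expression-module workflow with a
  deterministic simplification: keep the top 20% of genes by across-pair
  score variance, build per-gene trajectories of group means ordered by
  (genotype, age), standardize, and cluster with seeded kmeans, choosing
  `k` in 2..8 by maximum mean silhouette width.
* **Trajectory shapes** use an explicit rule table (peaked / dipped / up /
  down / flat, evaluated in that order) with a data-driven tolerance: the
  pooled between-replicate SD of the group means (`trajectory_epsilon()`).
  The rules partition every input triple.
* **The paralog-switch score** formalizes a qualitative observation
  (PRC1 chromobox usage shifting from Cbx6/7 toward Cbx2/4/8) as
  `mean LFC(up set) − mean LFC(down set)` with a resampling null: same-sized
  random gene sets drawn from the background without replacement,
  `p = (1 + #{null ≥ observed})/(B + 1)`. Thresholds on this score are our
  convention, not an established standard.
* **Overlap tests** default to the binomial tail (matching the motivating
  analysis), with the exact hypergeometric as the alternative and as the
  basis of `gmt_enrichment()`.

## Problem sizes

The packaged study conditions are 1,600 genes (1,240 background / 60
identity / 120 bivalent-c1 / 80 bivalent-c2 / 100 stress), 2 genotypes × 3
ages × 3 replicates × 4 marks. Property checks use 100 seeded replicate
studies for clock recovery and cluster selection, 5,000 regions for test
calibration, and 200 resampling runs for permutation-null uniformity; at
these sizes the full verification suite and the acceptance script each run
in about a minute on a single core.

## Known limitations

* **Normalization contamination.** Median-of-ratios is only as good as its
  unchanged majority. With ~22% of genes dynamic, residual size-factor
  errors of a few percent correlate with effective age and inflate
  estimated acceleration by ≈+0.3 months at `kappa = 1.5`. This is a real
  property of normalization-based chromatin clocks, not a simulation
  artifact; designs where most of the genome changes would need reference
  regions or spike-ins.
* **Calibration range.** Epigenetic age is a calibration-curve inversion.
  The mean score is mildly convex in effective age (z-scores of counts,
  not log counts), so predictions *extrapolating beyond the fitted WT age
  range* (2–10 months) are biased upward — at `kappa = 2` a 6-month HD
  sample has effective age 12 and is over-estimated by roughly +0.7
  months. Within the calibrated range, recovery is accurate to ≈0.3
  months.
* **Replicate-limited precision.** With 3 replicates per cell, the per-run
  SD of mean HD acceleration at 6 months is ≈0.35–0.5 months; single-run
  accelerations below ~1 month should not be over-interpreted.
* The z-scoring convention (joint across genotypes) and replicate-level
  pairing are documented choices; the motivating analysis does not state
  them, and a per-genotype z option is available in `gene_zscores()` via
  the sample subset argument.

## A compact run

```{r example, eval = FALSE}
study <- generate_study(study_config(seed = 1))
pairing <- pair_samples(study$samples)
z <- lapply(study$counts[c("H3K27ac", "H3K27me3")], function(cm)
  gene_zscores(normalize_counts(cm, size_factors_median_of_ratios(cm))))
score <- euchromatin_score(z$H3K27ac, z$H3K27me3, pairing)

feat <- mark_profile_features(study$counts, sheet = study$samples,
                              group_by = c("genotype", "age_months"))
states <- kmeans_cluster(feat, k = 5, seed = 7, n_restarts = 25)
biv <- select_bivalent_cluster(
  states,
  cluster_mark_means(states, rowMeans(feat[, grep("H3K4me3", colnames(feat))])),
  cluster_mark_means(states, rowMeans(feat[, grep("H3K27me3", colnames(feat))])))
biv_genes <- names(states$cluster)[states$cluster == biv]

pm <- gene_set_mean_score(score, biv_genes)
clock <- fit_clock(pm, pairing$age_months, pairing$genotype, "WT")
ages <- predict_epigenetic_age(clock, pm, pairing$age_months,
                               pairing$genotype)
aggregate(acceleration ~ genotype + age_months, ages, mean)
```
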