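---
title: "Methods: quantifying fate heterogeneity in isochronic neuron cohorts"
author: "isochron authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying fate heterogeneity in isochronic neuron cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(isochron)
```

This vignette is the package's account of its models and numerical
choices: what each statistic assumes, which parameters matter, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## 1. The biological question

Apical progenitors (APs) of the embryonic cortical ventricular zone
generate deep-layer neurons early (~E11.5–E13.5 in mouse) and
superficial-layer neurons later (~E14.5–E16.5). A FlashTag pulse labels
M-phase APs and their immediate daughters, so a cohort labelled at one
injection time is *isochronic* — born simultaneously. Combining the pulse
with chronic BrdU delivery separates directly AP-born neurons
(FT⁺BrdU⁻: bright FlashTag because the dye was not diluted by further
divisions, BrdU-negative because they never re-entered S phase) from
indirectly born ones. The package quantifies, for such cohorts, (i) how
dispersed their final laminar positions are and (ii) how heterogeneous
their single-cell transcriptomes are — both as a function of birthdate
and differentiation stage.

## 2. Direct-born gating

Per imaging section, a cell passes the gate when its FlashTag intensity
is *strictly above* the section median and its BrdU intensity *strictly
below* the section's 20th percentile. Two conventions had to be fixed:

* **Percentiles** use linear interpolation between order statistics
  (R's default type-7 quantile) everywhere in the package. The kept set
  is insensitive to the interpolation flavor in all boundary cases we
  enumerate in the tests.
* **Ties at the median** are excluded (the comparison is strict). A
  section in which every FlashTag intensity is identical keeps no cells
  and raises a warning rather than silently passing half the section.

`gate_top_ft()` implements the fallback gate (top 10% FlashTag per
section) used when no BrdU channel exists; ties at the boundary quantile
are all kept so the gate never depends on storage order.

## 3. Radial position and dispersion

`radial_position()` defines normalized depth as
$r = d_{sub} / (d_{sub} + d_{pia})$, with $d_\cdot$ the Euclidean
distance to the nearest point of the manually traced subplate-lower-border
and pial-surface polylines (exact point-to-segment projection, not vertex
snapping). This is well defined for curved landmarks, needs no assumption
of columnar geometry, and is invariant under rigid motions of the section
— a property the tests verify to 1e-9. Cortical-plate mode rescales $r$
linearly so the CP lower/upper landmark depths map to 0/1; cells falling
outside $[0,1]$ are excluded and counted, not clamped.

Dispersion summaries use the sample SD ($n-1$ denominator), the
interpolated IQR, and the mean-normalized IQR (IQR divided by the mean
position, a dimensionless spread comparable across cohorts at different
depths). Epoch contrasts are a two-sample Welch test on per-cohort SDs;
distribution contrasts are the two-sample Kolmogorov–Smirnov test; trends
of SD over collection day are ordinary least squares with the analytic
95% confidence band — "linear interpolation over time" is read as a
linear fit, since a confidence band is only defined for a model.

For the unsupervised early/late bipartition (`cluster_cohorts()`), each
cohort is featurized as the binned density of its *mean-centered*
positions — centering removes laminar location so the clustering responds
to spread/shape only. Defaults: 20 bins over $[-0.5, 0.5]$, Euclidean
distance, average linkage, flat cut at $k=2$. Linkage and bin scheme are
exposed as arguments because no convention is canonical; average linkage
was chosen as the least shape-assuming of the common options.

## 4. Single-cell QC and normalization

Cells are dropped when they have fewer than 2000 detected genes
(count > 0) *or* more than 12% mitochondrial counts. The filtering
sentence is stated as a conjunction of defect conditions; we drop on
either, since each alone marks a damaged cell or failed library — with
the strictness convention that exactly 2000 genes / exactly 12% is kept.
Genes are kept when they reach 100 counts in at least 2 cells.
Normalization is reads-per-million with a log2(x+1) layer; the
pseudocount is exposed (`rpm_log2(pseudocount=)`) because only
"log2 transformed" is conventional, and +1 is the toolchain default.
Mitochondrial genes are identified by a flag column, populated from the
"mt-" name prefix by the readers.

## 5. The heterogeneity statistic

The core quantity asks: does PC1 of a condition's expression capture more
covariance than chance? Per cross-validation:

1. subsample 80 cells without replacement;
2. rank genes by vst-style standardized variance *on that subsample* and
   keep the top 80;
3. compute the fraction of variance explained by PC1 of the
   log2(RPM+1) values (genes centered and unit-scaled);
4. independently permute every gene across the 80 cells — this preserves
   each gene's marginal exactly while destroying gene–gene covariance —
   and recompute the PC1 fraction;
5. record the ratio actual/permuted.

100 cross-validations give the ratio distribution; 1 means "no structure
beyond chance". Design choices that were genuinely open:

* **Genes per subsample.** The procedure's order (cells selected, then
  variable genes identified) implies re-selection within each subsample;
  a `genes_per_rep = FALSE` switch selects once globally instead.
* **Scaling.** Genes are unit-scaled before PCA (the toolchain default);
  `scale = FALSE` is available and tested. With scaling, the ratio is a
  statement about correlation structure rather than variance
  concentration.
* **One permutation per repetition**, matching one actual/permuted pair
  per cross-validation; the permutation seed is drawn inside the
  repetition so the whole run is reproducible from one master seed via a
  counter-based seed fan-out (`fan_out_seeds()`), and any single
  repetition can be replayed in isolation.
* **vst details.** The mean–variance trend is a loess fit of
  log10(variance) on log10(mean) (span 0.3, degree 2) over genes with
  positive mean and variance; standardized values are clipped at
  $\sqrt{n_{cells}}$. The ranking is tie-broken by gene id. The tests
  cross-check the ranking against the independent reference
  implementation of the same method and require near-perfect rank
  agreement.

The epoch contrast (early E12/E13 vs late E14/E15, per stage) is a
two-way repeated-measures ANOVA over conditions with cross-validations as
repetitions, delegated to `stats::aov`; the deep- vs superficial-layer
contrast is a two-sided Mann–Whitney test on pooled per-repetition
ratios. These wrappers are thin contracts over standard routines — the
package's contribution is the ratio statistic, not the ANOVA.

## 6. Clustering and marker analyses

`cluster_neurons()` follows the standard community-detection pipeline:
top 2000 variable genes, PCA to 15 dimensions of the scaled log2(RPM+1)
matrix, kNN graph (k = 20) reweighted by shared-nearest-neighbor Jaccard
similarity (pruned below 1/15), Louvain modularity at resolution 1.
Clusters are relabelled by decreasing size so ids are stable. Determinism
is enforced by seeding the community search. One limiting-behavior caveat:
as resolution → 0 modularity merges all *connected* communities, but
strongly separated subtypes can disconnect the SNN graph entirely, in
which case the component count is the floor on K.

The early-variable-gene set is the deduplicated union of the two top-50
rankings (E12-born and E13-born): genes found in both lists appear once,
so the size is $2k - \text{overlap}$ — with an overlap of 11 this yields
89 genes, the arithmetic the set construction must reproduce. The
alternative reading (discarding shared genes from both lists) is
inconsistent with that arithmetic and was rejected.

Late-born-marker thresholds are the mean RPM over cells of designated
late-born reference clusters (a parameter; `pick_late_clusters()`
defaults to the clusters with the largest E14+E15 fraction). The
positive fraction is computed *among cells with marker RPM > 0 only* —
the dropout guard — and both numerator and denominator are reported. The
fraction is monotonically non-increasing in the threshold, which the
tests verify.

## 7. The synthetic-data generator

The generator exists so that every downstream claim is checkable against
known truth; its defaults are the package's canonical study conditions.

**Imaging** (`simulate_cohort()`): true depths are Normal(center,
spread) *clamped* to [0,1] — clamping rather than resampling is simpler
and the boundary mass is negligible for the shipped designs
(center ± 2·spread inside the unit interval), but extreme specs will pile
mass at 0/1; this is a documented caveat, not a bug. Depths are placed
between two jittered landmark polylines at uniform lateral positions;
intensities are log-normal (non-negative, right-skewed, like real imaging
intensities) with high/low location parameters conditional on the
direct-born flag; 15% of cells are direct-born by default — a minority,
as in real sections, which is also what makes a median/percentile gate
informative. The canonical design is 3 pups × 2 injection ages with an
early cohort (center 0.35, spread 0.15 — broad, deep) and a late cohort
(center 0.75, spread 0.05 — compact, superficial).

**Expression** (`simulate_counts()`): one set of baseline per-gene means
(gamma, mean ≈ 5 counts) shared by all conditions; subtype *s* of a
condition multiplies its own disjoint 40-gene program block by
2^effect_logfc; counts are negative-binomial (dispersion 0.5) with 10%
independent Bernoulli dropout; the first 2% of genes are flagged
mitochondrial. Sampling is inverse-CDF on per-entry uniforms, so two
specs sharing a seed but differing in effect size are *coupled* (common
random numbers): effect-size ladders compare like with like. The
canonical design mirrors the birthdated single-cell resource: E12–E15 ×
{AP, N1d, N4d} plus adult DL/SL, 150 cells per condition (~2100 cells ×
1000 genes): APs and late-born N1d/N4d homogeneous (k = 1); early-born
N1d with three strong programs (log2FC 2 — the early surge of partially
executed late-born programs); early-born N4d with two weaker ones
(log2FC 1 — reduced heterogeneity 4 days after birth); adult DL three
programs, adult SL one.

What the generator does **not** emulate: batch effects, doublets,
ambient RNA, library-size confounding with biology, mean-dependent
dropout, spatial intensity gradients, or segmentation errors. Passing
tests therefore demonstrate the statistics' correctness and calibration,
not robustness to these real-data artifacts.

## 8. Problem sizes and numerical choices

The shipped experiments use ~300-cell conditions with 1000 genes, 100
cross-validations of 80 cells × 80 genes (each a few milliseconds of
loess + PCA; a full condition takes a few seconds), and 100-seed
parameter-recovery sweeps — sizes at which every distributional claim has
comfortable Monte-Carlo resolution while the whole suite runs in minutes
on one CPU.

One detection-limit finding is worth recording: at the procedure's fixed
80-cell/80-gene subsample, a 0.5-log2FC program spanning 40 of 1000 genes
is statistically invisible — the paired difference in mean ratio against
the null is ≈ +0.002 with Monte-Carlo error of similar size. The
monotonicity experiment over effect_logfc ∈ {0, 0.5, 1, 2} therefore
plants programs of 80 genes (the scale of the 89-gene early-variable
program) and relies on coupled simulation; with the 40-gene default the
0 → 0.5 step is a coin flip, which we note rather than hide.

Other numerical conventions: quantiles are interpolated (type 7)
everywhere; PCA uses `prcomp` (LAPACK SVD) and agrees with a direct SVD
oracle to 1e-9; constant genes are dropped before unit-scaling and
flagged wherever a min–max normalization would divide by zero; degenerate
Welch inputs (both groups constant and equal) return p = 1 with a
`degenerate` flag instead of NaN.

## 9. Known limitations

* The radial-position model assumes cells lie between the two landmark
  polylines; cells outside the band get extrapolated ratios rather than
  being flagged geometrically (cohort construction should pre-filter).
* The RM-ANOVA contrast assumes a balanced design (equal repetitions per
  condition); unbalanced designs fall back to a Welch contrast with a
  warning.
* `cluster_neurons()` materializes a dense distance matrix — fine for
  10³–10⁴ cells, not for atlas-scale data.
* Heterogeneity ratios from conditions barely above 80 cells reuse most
  cells across cross-validations, so the 100 repetitions are not
  independent; the ratio distribution is then tighter than its nominal
  Monte-Carlo spread.
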