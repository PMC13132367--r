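---
title: "Models, parameters and numerical choices in cdc1niche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and numerical choices in cdc1niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cdc1niche` quantifies conventional type-1 dendritic cells (cDC1) and their
spatial coupling to T cells in tumor tissue across three modalities: bulk
RNA-seq signatures, multiplex immunofluorescence (mIF) point patterns, and
imaging spatial transcriptomics niches. This vignette documents the models
the package implements, the tunable parameters that matter, what the
synthetic generators do and do not emulate, and where the design was
genuinely open and a choice had to be made. It states no empirical result
that the test suite does not itself compute.

## 1. Bulk signature arm

### Normalization

Counts are normalized to log2-CPM with *effective* library sizes: TMM
normalization factors (trimmed mean of M-values, 30% trim on log-ratios, 5%
on average log-expression, inverse-asymptotic-variance weights, reference
sample chosen by the upper-quartile rule) multiply the raw library size, and
values are `log2(count / effective_size * 1e6 + 1)`. The +1 pseudocount is
used for every log transform in the package, so zero counts map to exactly
zero and single-gene displays stay non-negative. Cohorts available only as
normalized values (log2-TPM) bypass TMM via `as_normalized_matrix()` and are
used as provided; nothing is imputed for undetected genes. The in-package
TMM implementation is verified against edgeR's to 1e-6 in the test suite.

### Signature derivation

Candidate pools (in practice, unions of published cell-type gene sets) are
reduced per cohort by:

1. **Detectability**: keep genes with ≥ 5 raw counts in ≥ 50% of samples
   (≥ 1 TPM in TPM mode); both comparisons inclusive.
2. **Meta-signal**: the per-sample mean of gene-wise z-scored normalized
   values over the retained candidates. The source method leaves the
   meta-signal formula open; the mean of z-scores was chosen because it is
   scale-free, symmetric in the candidates, and reduces to the single gene's
   z-score when only one candidate exists.
3. **Importance**: Spearman correlation of each candidate with the
   meta-signal; keep ρ > 0.4 (strict, one-sided in sign — anti-correlated
   genes are not markers of the cell type) with two-sided p < 0.05. p-values
   come from the t transform of ρ with average ranks on ties. The
   significance rule is read as *unadjusted* p < 0.05; with candidate pools
   of tens of genes and the ρ > 0.4 hurdle dominating, multiplicity
   correction would change little, but this is a documented choice, not a
   derivation.
4. **Intersection** across cohorts, ordered by mean ρ.

On synthetic cohorts (three cohorts of n = 200) the chain recovers ≥ 80% of
planted signature genes in ≥ 9/10 seeds (acceptance criterion 7).

### Scoring and tests

`enrichment_score()` is a direct implementation of the kernel-CDF rank
enrichment method for continuous log-scale input: per gene, a Gaussian
kernel CDF across samples with bandwidth sd/4; per sample, genes ordered by
that statistic with symmetric rank weights |i − p/2| (τ = 1); score = max
positive + min negative deviation of the weighted KS walk. Numerical
choices: genes absent from a cohort are silently ignored (cross-platform
feature spaces differ); zero-variance genes are held at their CDF midpoint
0.5 — the h → 0 limit — with a warning, which keeps fully degenerate inputs
(identical samples) well-defined and exchangeable rather than erroring.
A second, independently coded step-by-step implementation in the test suite
must agree to 1e-8.

Scores are min–max rescaled to [1, 10] *within cohort and signature* for
display; every statistical test runs on raw scores (rescaling is monotone,
so rank tests are unaffected — asserted as a regression test). Constant
score vectors rescale to the midpoint 5.5 with a warning. Group tests are
two-sided Mann–Whitney U over CR/PR vs SD, CR/PR vs PD, SD vs PD (CR merged
into PR because complete responses are rare), exact for combined n ≤ 20
without ties, otherwise the tie-corrected normal approximation.

## 2. mIF spatial arm

### Thresholding and phenotyping

Marker positivity uses iterative triclass Otsu: one Otsu pass on a 256-bin
histogram; values above the upper class mean become foreground, below the
lower class mean background, and the between-means region is re-thresholded
until it stabilizes or drops under 1% of the data. This suits skewed
immunofluorescence intensity distributions where one Otsu pass over-calls
the bright tail. Otsu ties (e.g. two separated point masses) resolve at the
middle candidate bin, keeping the threshold centered and deterministic.
Phenotypes follow a strict priority: BATF3+ → cDC1; else CD8+ → CD8 T;
else CD3+ → CD4 T; else "other".

### Geometry

Cells within 20 µm of the field border are removed (the margin is a
parameter; "close to the border" is not quantified in the source). Tissue
area is an occupancy grid: 50-µm bins over the coordinate bounding box,
area = occupied bins × bin area, the whole tissue (tumor + stroma) counted.
At typical cell densities (≥ ~10³ cells/mm²) the occupancy probability per
bin is ≈ 1 and the estimator is within ~10% of truth; the bin size is
exposed because sparser samples need coarser bins.

Distances are Euclidean in the plane, in microns. `mean_min_distance()` is
*directional*: the mean over cDC1 cells of the distance to the nearest
target T cell, matching the "from every BATF3+ cell" reading; it is not
symmetrized. The triad radius is `max` of the two nearest-neighbour
distances per cDC1 — the smallest circle containing both a CD4 and a CD8
partner (necessarily distinct cells, since phenotypes are exclusive).
Samples lacking any required phenotype are *excluded* via a sentinel object,
not errored, so cohort loops continue. Both statistics equal brute-force
O(n·m) oracles exactly and are rigid-motion invariant to 1e-9 (tested).

### Survival

The median split sends ties to the low arm (deterministic, conservative);
the log-rank test and Kaplan–Meier curves come from the survival package.
The decile Cox model converts the covariate to rank-based deciles
(`ceiling(10·rank/n)`, maximum tie ranks, so ties collapse and any
order-preserving transform gives identical deciles) entered as a numeric
covariate with Efron tie handling; the hazard ratio is per decile increase.

## 3. Spatial transcriptomics niche arm

Cells with < 50 total molecules are dropped. Candidate cDC1/CD8 cells are
called by two routes and intersected:

- **Threshold route**: per type, the log1p sum of canonical counts
  (BATF3/CLEC9A/XCR1; CD8A/CD8B) is assumed bimodal; positives lie above the
  valley (density minimum) between the two highest modes of a Gaussian KDE.
  *Numerical choice*: the Silverman bandwidth is floored at 0.5 on the
  log1p-count scale. Raw Silverman bandwidths track the discreteness of
  small counts and place a mode on every integer, which makes "the two
  highest modes" adjacent background peaks; the floor (half the unit
  spacing) removes discreteness artifacts while leaving genuine bimodality
  (separation ≳ 2 log-units) intact. With a unimodal distribution the
  method falls back to an Otsu threshold with a warning.
- **Cluster route**: Leiden communities (modularity objective, resolution
  2.0, seeded) on a k = 15 nearest-neighbour graph over depth-normalized
  log1p counts; a cluster is positive for a type when its mean canonical
  sum exceeds the global mean by one SD; clusters positive for both types
  are "mixture". The one-SD cut and the resolution are exposed parameters;
  the source does not operationalize its cluster merging.

**Consensus** (also not operationalized in the source, so made concrete
here): a cell is a candidate of type t iff the threshold route calls t
(cells called "both" resolve to the type with the larger canonical sum,
ties to cDC1) *and* its cluster is labelled t or "mixture".

**Hubs**: one per candidate; members are all cells (any type) within 10 µm
of the candidate centroid (20-µm diameter, ≈ 314 µm²), counts summed; hubs
may overlap. A hub is cDC1-rich iff its aggregated BATF3+XCR1+CLEC9A count
is ≥ 1 molecule — so a hub centered on a threshold-positive cDC1 is rich by
construction, which the tests assert.

**Differential expression** between rich and devoid hubs defaults to a
per-gene two-sided rank-sum test on log1p aggregated counts with BH
correction; log2 fold changes are computed on class means with a +1
pseudocount. The zero-inflated NB estimator used by the motivating study is
deliberately out of scope; the backend is a function argument so such an
estimator can be slotted in without touching the interface. **Preranked
GSEA** implements the weighted KS statistic (weight |stat|, exponent 1)
with same-sign gene-label permutations for NES and p.

The probe-based (GeoMX-style) stage drops samples under 50,000 raw counts,
normalizes by median-ratio size factors (a documented stand-in for the
platform's size-factor normalization), and reports Spearman correlations of
each partner transcript with the BATF3 anchor.

## 4. The synthetic world

The generators are the package's stated world: their defaults are fixed
here, chosen once for realism and testability, and the tests measure the
package against them. The motivating study reports no effect sizes for its
restricted cohorts, so defaults are *not* calibrated to any trial.

- **Bulk** (`gen_bulk_cohort`): per-sample latent abundances for cDC1, CD8
  and NK (standard normal; cDC1–CD8 correlation 0.6 by default, realized by
  a symmetric eigen square root so the singular |r| = 1 case works);
  signature-gene means multiply by `exp(latent)`; NB counts with variance
  μ + αμ² (α = 0.3, a typical bulk RNA-seq dispersion); gene baselines
  log-normal around 50 counts. Response is Bernoulli through a logistic
  link on the cDC1 latent (1 SD of latent shifts the log-odds by
  `response_effect` = 1); CR vs PR and SD vs PD splits are 20/80 and 50/50.
  Optional survival is exponential with log-hazard −0.5 per cDC1 latent SD,
  administratively censored at 36 months. Not emulated: batch effects
  across cohorts (the motivating analysis applies no cross-cohort batch
  correction), gene–gene co-expression beyond the latent factors, library
  size heterogeneity beyond count stochasticity.
- **Tissue** (`gen_tissue`): uniform points on a rectangular field; a
  fraction of T cells is displaced from a random cDC1 by an isotropic
  Gaussian (default SD 10 µm, a cell-contact length scale); displaced
  points falling outside the field are rejected and resampled, preserving
  the displacement distribution (clipping would pile mass on the border).
  Marker intensities are bimodal log-normals consistent with the phenotype
  so thresholding/phenotyping can run end-to-end. Not emulated: staining
  artifacts, segmentation errors, intensity spatial autocorrelation,
  tissue-shaped (non-rectangular) domains — so a green test establishes
  correctness of the statistics, not robustness to imaging pathology.
- **Spatial transcriptome** (`gen_spatial_transcriptome`): 3,000 cells on
  500 × 500 µm by default (≈ 0.012 cells/µm², giving ~4 cells per 10-µm
  niche, a realistic niche occupancy); types cDC1/CD8/other at 2/10/88%
  (cDC1 rare, as in tissue); depth 230 molecules/cell (a realistic imaging
  panel median); a 200-gene desk-scale panel (5 canonical + 5 activation +
  190 background). Canonical lineage markers carry base weight 0.05
  relative to background genes — marker transcripts are near-absent outside
  their type, which is what makes them markers — and are multiplied by
  `marker_fold` = 100 in the owning type, so the owning/background mean
  ratio is exactly `marker_fold`. Activation genes are broadly expressed
  (base weight 1, they are inducible rather than lineage-restricted) and
  multiply by `activation_fold` = 3 within 10 µm of a true cDC1. Counts are
  Poisson by default (NB optional). Not emulated: segmentation spillover,
  cell-shape effects, panel-wide co-expression programs, spatial expression
  gradients other than the cDC1 activation neighbourhood.

All generators are pure functions of their parameters: one global seed fans
out to named substreams (`substream_seed`), so stages are individually
reproducible and repeated calls are byte-identical.

## 5. Degenerate inputs and tie-breaks (summary)

| Situation | Behavior |
|---|---|
| All-zero sample in TMM | error naming the sample |
| Zero-variance gene in meta-signal | excluded, warning |
| Zero-variance gene in enrichment ranking | held at CDF midpoint, warning |
| Constant score vector in rescaling | midpoint 5.5, warning |
| Empty group in group tests | pair skipped with note |
| Missing phenotype in distance stats | excluded-sample sentinel |
| Otsu between-class-variance ties | middle candidate bin |
| Median-split ties | low arm |
| Cox decile ties | collapse into the same decile |
| Threshold call "both" in consensus | larger canonical sum, ties → cDC1 |
| No second KDE mode | Otsu fallback, warning |

## 6. Known limitations

- Raw image processing (unmixing, segmentation) and read alignment are out
  of scope; inputs begin at cell tables and count matrices.
- The hub DE default is a rank-sum test, not a zero-inflated NB model; with
  strong class imbalance in hub sizes, fold changes on aggregated counts
  partially reflect hub cell-count composition. The backend hook exists for
  heavier models.
- The threshold detector assumes an (approximately) bimodal canonical-sum
  distribution; panels where a marker is broadly expressed will trip the
  Otsu fallback.
- Permutation NES/p in `preranked_gsea` uses gene-label permutations, which
  ignore inter-gene correlation; p-values are calibrated under the tested
  null but can be anticonservative on strongly correlated real data.
- The distance statistics ignore edge effects; near field borders,
  nearest-neighbour distances are biased upward. Border trimming mitigates
  but does not remove this.
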