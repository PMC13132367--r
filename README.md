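# cdc1niche

Conventional type-1 dendritic cells (cDC1) cross-present tumor antigens to
CD8+ T cells and are a strong correlate of response to PD-(L)1 checkpoint
inhibitors. Quantifying them — and their spatial interplay with T cells — is
awkward because the evidence lives in three very different data modalities.
`cdc1niche` packages the computational machinery for all three:

1. **Bulk RNA-seq signatures** — TMM/log2-CPM normalization, cross-cohort
   derivation of immune gene signatures (detectability filter → per-sample
   meta-signal → Spearman importance filter → cross-cohort intersection), a
   direct implementation of the kernel-CDF rank enrichment score for
   per-sample signature scoring, 1–10 min–max rescaling for display, and
   Mann–Whitney response-group tests plus Pearson/Spearman correlation
   panels.
2. **Multiplex immunofluorescence (mIF) spatial statistics** — iterative
   triclass-Otsu marker thresholding, priority-rule phenotyping
   (BATF3+ → cDC1; else CD8+ → CD8 T; else CD3+ → CD4 T; else other), border
   trimming, occupancy-grid tissue area, densities, directional
   nearest-neighbour distances (mean over cDC1 cells of the distance to the
   nearest CD8/CD4 T cell), triad radii (per cDC1, the smallest radius
   containing both a CD4 and a CD8 partner), rank-sum group contrasts, and
   survival association via median-split log-rank and a per-decile Cox model.
3. **Imaging spatial transcriptomics niches** — per-cell QC, two-method
   consensus detection of candidate cDC1/CD8 cells (bimodal canonical-sum
   thresholding × Leiden cluster annotation), construction of 20-µm-diameter
   niches ("hubs", all cells with centroids within 10 µm of a candidate),
   cDC1-rich classification (≥ 1 BATF3/XCR1/CLEC9A molecule), rank-sum hub
   differential expression with a pluggable backend, preranked GSEA, and an
   anchor-gene Spearman correlation stage for probe-based profiling.

Because the motivating clinical datasets are access-restricted, the package
ships first-class **synthetic data generators** that emulate the statistical
structure of each input (NB bulk counts driven by correlated latent
cell-type abundances; planar point patterns with tunable cDC1–T cell
attraction; cell×gene counts with marker-specific and
activation-neighbourhood structure). Every analysis stage is tested against
independent oracles on these generators.

## The statistics at the core

- **Enrichment score.** For gene *i* and sample *j*, the Gaussian-kernel CDF
  estimate is computed with bandwidth `h_i = s_i/4`. Within each sample,
  genes are ordered by this statistic, assigned symmetric rank scores
  `|i − p/2|`, and a weighted Kolmogorov–Smirnov random walk (τ = 1)
  contrasts signature genes with the rest; the score is the maximum positive
  plus minimum negative walk deviation, in [−1, 1]. Scores are min–max
  rescaled to [1, 10] per cohort *for display only*; all tests run on raw
  scores:  `g̃ = 1 + 9 (g − min g)/(max g − min g)`.
- **Triad radius.** For each cDC1 cell, `max(d_NN(cDC1→CD8), d_NN(cDC1→CD4))`
  — the smallest circle around the cDC1 containing both partners.
- **Hub.** One per candidate immune cell: all cells with centroids within
  10 µm (area ≈ 314 µm²), transcripts summed; cDC1-rich iff the aggregated
  BATF3+XCR1+CLEC9A count is ≥ 1.

## Worked example

```r
library(cdc1niche)

# --- bulk arm: a synthetic 100-patient trial cohort --------------------
sim  <- gen_bulk_cohort(bulk_sim_params(n_samples = 100, n_genes = 1000,
                                        seed = 42))
norm <- log2_cpm(sim$counts, compute_tmm_factors(sim$counts))
sc   <- enrichment_score(norm, cdc1_signature())   # BATF3/XCR1/CLEC9A
group_compare(sc, sim$clinical)
#>          pair n1 n2    U       p           note
#> 1 CR/PR vs SD 49 31 1017 0.01115 normal approx.
#> 2 CR/PR vs PD 49 20  734 0.00128 normal approx.
#> 3    SD vs PD 31 20  388 0.13487 normal approx.

# --- mIF arm: a tissue with strong cDC1-T attraction -------------------
tis <- gen_tissue(tissue_sim_params(attraction_fraction = 0.8,
                                    displacement_sd = 5, seed = 42))
thr <- marker_thresholds(tis)                       # triclass Otsu per marker
ph  <- assign_phenotypes(tis[, 1:6], thr)
mean_min_distance(ph)                               # mean cDC1->CD8, um
#> [1] 5.40
triad_radius(ph)$mean
#> [1] 7.72
densities(ph, estimate_tissue_area(ph))
#>   phenotype   n density_mm2
#> 1      cDC1  32        34.6
#> 2      CD8T 200       216.2
#> 3      CD4T 200       216.2
#> 4     other 998      1078.9
```

The response-group p-values show the planted cDC1–response association
(CR/PR vs PD most significant); the 5.4 µm mean cDC1→CD8 distance reflects
the 80% attracted fraction (a fully random pattern at this CD8 density
would sit near 41 µm = 1/(2√λ)).

For the spatial-transcriptomics arm, see `?gen_spatial_transcriptome`,
`?build_hubs` and `?hub_de`, or run the self-contained demo pipeline:

```sh
Rscript inst/cli/cdc1niche.R run --out demo_out --seed 1
```

## Layout

- `R/` — implementation (simulators, signatures, mIF spatial, hubs, IO,
  pipeline orchestrator)
- `tests/testthat/` — unit, property and acceptance tests, with independent
  brute-force/clean-room oracles in `helper-oracles.R`
- `vignettes/methods.Rmd` — the modeling and numerical choices, assumptions,
  and limitations
- `inst/cli/cdc1niche.R` — command-line entry point
- `scripts/acceptance.R` — acceptance report
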