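---
title: "Methods: single-cell spatial analysis of IMC tissue sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell spatial analysis of IMC tissue sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidyimc)
```

## What the package does

Imaging mass cytometry (IMC) ablates tissue sections with a ~1 µm laser
and quantifies dozens of metal-tagged antibodies per pixel, yielding — after
segmentation — a table of cells with centroid coordinates and mean marker
intensities. `tidyimc` implements the downstream single-cell analysis for
cohort studies that compare a disease group against controls across
annotated tissue regions, as in studies of peri-lesional mucosa in
medication-related osteonecrosis of the jaw (ONJ): intensity preprocessing,
region assignment, hierarchical marker gating, cross-type spatial
statistics, and region-stratified differential statistics. A synthetic
tissue generator with planted ground truth makes every stage testable
without patient data.

All user-facing functions take a tibble-like `cell_table` first and return
tibbles, so stages chain with the pipe; `run_pipeline()` strings them
together under a single seed.

## Intensity model and preprocessing

Raw per-cell intensities are winsorized per marker and then
arcsinh-transformed with cofactor 5 (`asinh(x / 5)`), the standard
variance-stabilizing transform for cytometry. Winsorization uses the 0.1th
and 99.5th empirical percentiles; the bounds are the type-7 interpolated
quantiles snapped to the nearest attained order statistics inside the
retained range. Snapping is a deliberate numerical choice: clipping at an
interpolated bound changes the order statistics that bound interpolates, so
a second application would clip further — gross at small n. Snapped bounds
make the operation exactly idempotent while remaining within rounding of
the interpolated percentile for realistic n.

Quantiles are pooled over all cells in the run rather than computed per
ROI; single ROIs can be small enough (hundreds of cells) that per-ROI
0.1%/99.5% quantiles are dominated by a handful of observations. Per-ROI
pooling remains available via `preprocess_table(pool = "roi")`.

## Region geometry

Tissue regions (epithelium, stroma, vessel) come in as an integer label
raster with a physical pixel size. Cells are points (centroids); a cell's
region is the label of the pixel containing it — polygonal cell outlines
are out of scope. Signed distances to a region use a Euclidean distance
transform (EBImage) against the region's boundary pixels, where a boundary
pixel is a region pixel 4-adjacent to a non-region pixel and the raster
edge counts as non-region. The sign is negative inside the region
(configurable). Distances are read at the cell's pixel, so they agree with
the exact minimum over boundary-pixel centers to within half a pixel
diagonal; the test suite verifies agreement with a brute-force oracle to
one pixel diagonal.

## Hierarchical gating

Cells are classified in four levels from marker positivity:

1. **Level 1** — five basic types (immune, endothelial, epithelial,
   fibroblast, functional) plus `unclassified`. Rules are declarative
   (YAML; `require_positive` / `require_negative` marker sets with integer
   priorities); "positive for any of a set" is written as one rule per
   marker sharing a label. The default priority order is immune >
   endothelial > epithelial > fibroblast > functional, so lineage
   co-expression resolves toward the rarer, more specific identity. The
   panel deliberately contains no CD3/CD45; immune cells are gated from
   subtype lineage markers directly.
2. **Level 2** — immune subtypes (B, CD4 T, CD8 T, BnT, Treg, macrophage,
   M2, NK, exhausted T, DC), compound gates ranked most-specific-first:
   Treg (CD4⁺FoxP3⁺) outranks exhausted T (PD1⁺CD4/CD8⁺), which outranks
   BnT (CD20⁺ with CD4/CD8), M2 (CD68⁺CD163⁺) outranks macrophage, and so
   on. Unmatched immune cells become `immune-other`.
3. **Level 3** — infiltration phenotypes: an immune cell co-expressing a
   compartment lineage marker is `immune-in-epithelial` /
   `-endothelial` / `-fibroblast`, precedence epithelial > endothelial >
   fibroblast.
4. **Level 4** — non-exclusive functional flags: proliferation (Ki67 or
   pERK), apoptosis (BNIP3), autophagy (Caveolin), pro-inflammatory
   (pNFκB), migration (IntegrinB1), transcriptional activity (pSTAT3). A
   dominant-state reduction (fixed precedence in that order) is provided
   for visualization and composition summaries. The marker for
   "transcriptional activity" is genuinely ambiguous in the field
   (YAP1 is also plausible); pSTAT3 is the default and the mapping is
   configurable. The level-1 "functional" type is realized as cells
   positive only for functional markers with no lineage signal.

Positivity is strict (`intensity > threshold`; a value exactly at the
threshold is negative) — a deterministic, documented tie-break. YAP1 is
scored on the nuclear channel (`nuc_YAP1`), falling back to whole-cell
with a warning if the nuclear channel is absent.

**Thresholds.** Per marker, a two-component Gaussian mixture with unequal
variances is fitted to the arcsinh intensities (mclust), and the threshold
is the equal-posterior crossing between the component means. Two numerical
choices matter here:

- *Initialization.* mclust's default hierarchical initialization can miss
  a minority positive mode (a 1–3% cell type) hidden behind the skewed
  background. EM restarts initialized from 90th- and 98th-percentile cuts
  compete with the default fit and the best log-likelihood wins.
- *Degeneracy.* A fit is degenerate when its component means are closer
  than `max(0.1, 2 * sqrt(s1 * s2))` — the mixture has split a unimodal
  distribution down the middle — or when the upper component carries less
  than 80% of the mass above the crossing — the "positive mode" is just
  the tail of an unimodal distribution. Such markers fall back to the
  midpoint of the 10th/90th percentiles and are flagged. A small
  component *weight* is deliberately **not** treated as degeneracy: rare
  types legitimately give sparse but well-separated positive modes, and
  overriding a correct sparse fit with a percentile midpoint would call
  half the background positive.

Fits use a deterministic subsample (default 5 000 cells per marker) and a
fixed seed, so thresholds are reproducible run to run.

## Spatial statistics

Co-localization between cell types is measured with the cross-type Ripley
K function on each ROI's rectangular window,

$$\hat K_{ab}(r) = \frac{|W|}{n_a n_b} \sum_i \sum_j e_{ij}\,
  \mathbf 1[d_{ij} \le r],$$

with translation edge correction
$e_{ij} = |W| / ((w - |\Delta x|)(h - |\Delta y|))$ — the closed-form
correction for rectangles, symmetric in the two types, and exactly
checkable against a brute-force pair loop (the test suite requires
agreement to 1e−9 relative). For a type against itself, self-pairs are
excluded and the denominator is $n(n-1)$. The interaction score is the
centred L-function

$$u = \sqrt{\hat K_{ab}(r) / \pi} - r,$$

zero in expectation under complete spatial randomness, positive for
attraction, negative for avoidance. Radii of 50 and 100 µm capture
immediate and intermediate neighbourhoods. Scores with fewer than
`min_count = 10` cells of either type in the ROI are recorded as invalid
rather than dropped silently (rare types — DCs, control B cells — routinely
fall below this).

ROI scores aggregate to one score per biological replicate (individual) by
a weighted mean with weights $n_a n_b$, so sparse ROIs do not swamp
well-populated ones. Group contrasts use the two-sided Wilcoxon rank-sum
test on per-sample scores (exact when tie-free and $n+m \le 14$),
with Benjamini–Hochberg adjustment across all pairs *within* each radius —
radii are presented separately, so they form separate families. This
ROI-weighted aggregation + rank-sum design replaces mixed-model inference
over nested ROIs; it matches the primary test used for every other
comparison in the pipeline and keeps the replicate structure explicit
(individuals are biological replicates, ROIs technical). Mixed-effects
modelling of ROI nesting is a documented non-goal.

## Differential composition and functional statistics

Single-cell labels aggregate to per-sample proportions (ROIs pooled
first); the denominator is every cell in the stratum, including
unclassified cells. Tests always run on per-sample values, never
per-cell — per-cell testing would treat thousands of correlated cells as
independent replicates (pseudoreplication). Each comparison reports group
medians and IQRs (matching box-plot conventions), the Wilcoxon rank-sum p
(primary), a Welch t-test p (confirmation), and BH-adjusted Wilcoxon p
with significance stars (*** < 0.001, ** < 0.01, * < 0.05, `ns.`). The BH
family is all labels of one classification level within one stratum per
table. Comparisons with fewer than 3 samples per group report `NA`.
Whether proportions should use region-restricted or whole-section
denominators is ambiguous in practice; both are available
(`stratum = "region"` vs `"all"`).

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, so
planted parameters can be recovered:

- **Cohort shape:** 8 Control and 6 ONJ individuals, 2–5 ROIs each,
  1000×1000 µm windows at 1 µm/pixel, ~2 500 cells per ROI
  (0.0025 cells/µm²).
- **Anatomy:** an epithelial band (200 µm mean depth, undulating
  junction) over stroma, with circular vessels inside the stroma.
- **Composition:** 16 true cell types with fixed marker signatures;
  unclassified filler (all markers negative) at 4%. Per-individual
  proportions are jittered on the log scale (sd 0.3) and renormalized —
  biological replicate variation; ROIs share their individual's
  parameters.
- **Intensities:** two lognormal populations per marker (positive
  meanlog = log 20, sdlog 0.35; background meanlog = 0, sdlog 0.35),
  chosen to give the clear bimodality on the arcsinh scale that real
  panels are designed for. Every lineage marker is positive in at least
  one planted type (a marker that stains nothing would never be included
  in a real panel, and gives a mixture nothing to fit).
- **Planted disease effects (ONJ arm):** Treg 2% → 6%, exhausted T
  1.5% → 3%, B 0.8% → 2%, epithelial 30% → 24%; Treg and exhausted T
  switch from CSR to Thomas-cluster placement (µ = 20 offspring,
  σ = 15 µm), modelling the shift from dispersed to self-clustered
  immune organization; functional positivity rises in the epithelium
  (Ki67 0.12 → 0.25, BNIP3 0.03 → 0.12, …) and pNFκB rises in
  fibroblasts and endothelium.
- **Spatial modes:** counts are drawn Poisson(density × area) first, then
  placed uniformly (CSR), as Thomas offspring thinned to the drawn count
  (uniform thinning preserves the cluster structure), or by sequential
  hard-core rejection (`r_min`).

The generator does **not** simulate raw pixel images, segmentation
errors, spillover, batch effects, or marker correlations beyond the type
signatures. Passing tests therefore demonstrate that the pipeline's
statistics behave correctly on data with the assumed structure — not that
real IMC sections satisfy those assumptions. One structural feature is
worth knowing when reading results: immune densities differ between
regions (e.g. perivascular enrichment), so even CSR-placed types show
mildly positive self-interaction scores in both groups; group contrasts
difference this out.

The planted epithelial shift (30% → 24%) is small relative to the
between-individual jitter and is usually *not* significant at n = 8 vs 6 —
a realistic reminder that composition tests at this sample size only
resolve large effects; the three-fold Treg shift is detected reliably.

## Problem sizes and determinism

Every stochastic stage flows from one integer seed; two runs with the same
configuration and seed produce byte-identical result CSVs (verified in the
suite). The test suite exercises: the estimator oracle on 100 random
configurations (up to 500 points); CSR calibration over 200 simulations;
null operating characteristics over 400 scaled replicates (14 single-ROI
samples each); spatial detection power over 50 reduced cohorts (8 + 6
individuals, 2 ROIs, 800 µm windows); and gating recovery over 50 cohorts
of 7 individuals at 800 µm. These sizes are the package's own validation
choices, balancing statistical resolution against a laptop-scale run.

## Known limitations

- Isotropic and inhomogeneous edge corrections are not implemented; the
  translation correction assumes rectangular windows.
- The gating defaults mirror main-text marker definitions of the target
  application; real panels will want their own rule file
  (`read_gating_rules()`).
- Signed distances are raster-resolution limited (half-pixel quantization).
- The UMAP embedding (`embed_cells()`, n_neighbors = 30, min_dist = 0.3)
  is a visualization aid calling uwot; its internals are out of scope.
- `cell_table` restricts groups to Control/ONJ/Tonsil and fails fast on
  anything else; relabel upstream if your cohort differs.
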