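# tidyimc

Tidy single-cell spatial analysis for imaging mass cytometry (IMC)
tissue sections.

IMC profiles 38+ metal-tagged antibodies on a tissue section at ~1 µm
resolution; after segmentation, each section becomes a table of cells with
centroid coordinates and per-marker intensities. Cohort studies — for
example comparing peri-lesional oral mucosa from jaw-osteonecrosis (ONJ)
patients against healthy controls — then ask three questions per tissue
region: *what* cells are there (composition), *what state* are they in
(functional marker positivity), and *how are they arranged* (spatial
attraction/avoidance between cell types). `tidyimc` implements that whole
downstream analysis as a pipeline of tibble-in/tibble-out functions:

- **Preprocessing** — per-marker winsorization (0.1th/99.5th percentiles)
  and arcsinh transform with cofactor 5: `preprocess_table()`.
- **Regions** — assignment of cells to epithelium/stroma/vessel label
  rasters and signed Euclidean distances to region boundaries
  (negative inside): `assign_region()`, `signed_distance()`.
- **Gating** — four-level supervised classification from marker
  positivity, with per-marker thresholds from a two-component Gaussian
  mixture (equal-posterior crossing): basic types → immune subtypes →
  infiltration phenotypes → functional states: `classify_cells()`.
- **Spatial statistics** — cross-type Ripley K with translation edge
  correction, summarized as the centred L-function
  `u = sqrt(K(r)/π) − r` at r = 50 and 100 µm (`u > 0` attraction,
  `u < 0` avoidance), aggregated ROI → individual and contrasted between
  groups by Wilcoxon rank-sum with Benjamini–Hochberg correction:
  `interaction_scores()`, `contrast_groups()`.
- **Differential statistics** — per-sample composition proportions and
  functional positive fractions, region-stratified, tested with
  Wilcoxon (primary) + Welch t (confirmation) + BH:
  `per_sample_proportions()`, `differential_table()`.
- **Synthetic cohorts** — a generator that plants known cell-type
  proportions, lognormal marker intensities, and spatial modes
  (CSR / Thomas clusters / hard-core inhibition) with full ground truth:
  `generate_cohort()`.

`autoplot()` / `plot_*()` functions draw the standard figures, and
`tidy()` / `glance()` methods give broom-style summaries.

## Worked example

Simulate a study-shaped cohort (8 Control vs 6 ONJ individuals, 2 ROIs
each) in which regulatory T cells (Tregs) expand from 2% to 6% of cells
and switch from dispersed to self-clustered placement in the ONJ arm,
then recover both effects:

```r
library(tidyimc)
library(dplyr)

cohort <- generate_cohort(design = cohort_design(rois = c(2, 2)), seed = 42)
#> # imc_cohort: 54980 cells, 22 ROIs, 14 samples (seed 42)

cells <- cohort$cells |>
  preprocess_table() |>                  # winsorize + arcsinh(x/5)
  assign_region(cohort$maps) |>          # epithelium / stroma / vessel
  classify_cells()                       # 4-level gating, gmm2 thresholds

tibble::as_tibble(cells) |> count(level1) |> mutate(pct = round(100 * n / sum(n), 1))
#>   level1           n   pct
#> 1 endothelial   4221   7.7
#> 2 epithelial   14765  26.9
#> 3 fibroblast   13920  25.3
#> 4 functional    2697   4.9
#> 5 immune       17595  32
#> 6 unclassified  1782   3.2     # planted filler: 4%

scores   <- interaction_scores(cells, level = "level2", windows = cohort$maps)
contrast <- contrast_groups(aggregate_to_sample(scores))
contrast |> filter(type_a == "Treg", type_b == "Treg")
#>   type_a type_b radius n_control n_onj mean_u_control mean_u_onj  diff        p  p_adj
#> 1   Treg   Treg     50         8     6          12.62        124 111.3 0.000666 0.0183
#> 2   Treg   Treg    100         8     6           9.14        101  91.8 0.000666 0.0183
```

The Treg self-interaction score `u` sits near zero in controls
(dispersed) and around +120 µm in ONJ samples (strong self-attraction at
r = 50 µm); the group difference survives BH adjustment across all 55
subtype pairs per radius (`p_adj = 0.018` — the exact Wilcoxon p for a
fully separated 8-vs-6 split is 2/3003 ≈ 0.00067). The planted
composition shift is recovered by the differential table:

```r
per_sample_proportions(cells, level = "level2") |>
  differential_table() |>
  filter(label == "Treg")
#>   stratum label n_control n_onj median_control median_onj p_wilcoxon p_adj stars
#> 1     all  Treg         8     6          0.026      0.073    0.00067 0.002    **
```

`run_pipeline(run_config(seed = 1))` runs every stage on the default
cohort and writes result CSVs plus a JSON run manifest;
`inst/scripts/imc-pipeline.R` exposes the same as a command line
(`Rscript imc-pipeline.R run --seed 1 --out results/`).

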