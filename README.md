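# pitdeconv

Cell-type deconvolution and normal-tissue contamination detection for
bulk RNA-seq of pituitary neuroendocrine tumors (PitNETs).

PitNET surgical specimens routinely entrap non-neoplastic anterior-pituitary
cells, and stromal/immune (TME) populations add further signal, so bulk
RNA-seq profiles are mixtures. `pitdeconv` is for researchers who want to
(i) estimate the cellular composition of such samples against a
single-nucleus reference of normal pituitary, (ii) verify on pseudobulk
mixtures with known ground truth that the estimates can be trusted, and
(iii) quantify and flag residual normal tissue per sample before any
downstream transcriptomic analysis.

## What it computes

Given bulk CPM **y** (genes × 1) and a signature matrix **X** (genes ×
cell types, mean CPM of marker genes), the ν-SVR engine solves a linear
ν-support-vector regression of the z-scored **y** on the z-scored **X**
over ν ∈ {0.25, 0.5, 0.75}, keeps the fit with the lowest reconstruction
RMSE, clips negative coefficients and normalizes:

    p̂ ∝ max(0, ŵ),   Σₖ p̂ₖ = 1

with significance from a permutation null (random pseudo-mixtures resampled
from the mixture matrix). The weighted-NNLS engine instead solves

    min_{p ≥ 0} Σ_g w_g ( y_g − Σₖ p_k · S_k · m_{gk} )²,
    w_g = 1 / (ε + σ²_g),

where m·ₖ are type mean profiles from a multi-donor reference, Sₖ per-type
cell size factors (so p̂ is a *cell-count* proportion), and σ²_g the
cross-subject variance of the reconstruction, re-estimated each iteration.

Signatures come either from a marker table (GES50–GES300: significant
markers with adjusted p ≤ 0.05 and ln-fold-change > 1, top-N by within-type
mean CPM) or directly from cells (union of top-G fold-change genes, G
chosen by minimizing the signature's condition number). Estimates are
validated per cell type by Pearson correlation against ground truth
(validated ⇔ r > 0.70, p < 0.05), and per-sample proportions are
partitioned into tumor / same-lineage / residual-normal / TME fractions,
with contaminated samples also detectable by complete-linkage clustering
on the top-500 most variable genes.

A seeded synthetic module (`simulate_reference()`, 13 pituitary cell types
across 3 donors with negative-binomial counts and donor effects;
`simulate_pseudobulk()`; `simulate_bulk_cohort()`) stands in for the
controlled-access atlases, so the whole pipeline runs offline.

## Worked example

```r
library(pitdeconv)

ref <- qc_filter(simulate_reference(sim_config(seed = 1)))
#> qc_filter: 1420/1450 cells retained (removed: 19 by feature bounds,
#>   0 by count bound, 11 by mito bound)

sig <- build_signature_from_cells(ref)
#> build_signature_from_cells: excluding low-representation type(s)
#>   (<50 cells): nk_cell
sig
#> <signature_matrix SC-G100> 1200 genes x 12 types

mix <- simulate_pseudobulk(ref, n_samples = 40, cells_per_sample = 500,
                           seed = 2)
dec <- svr_deconvolve(mix, sig, cfg = svr_config(n_permutations = 0))
report <- evaluate_deconv(mix, dec)
glance(report)
#> # A tibble: 1 × 4
#>   n_types n_validated median_r min_r
#> 1      13          12    0.994 0.991
```

Every estimable cell type is validated (r ≥ 0.991 against the known
mixing proportions); `nk_cell` is reported as `absent` — it fell under the
50-cell exclusion when the signature was built, so the report says so
instead of silently dropping it.

Contamination scoring on a simulated GH-tumor cohort, where half the
samples carry 30% planted cross-lineage residue:

```r
coh <- simulate_bulk_cohort(ref, "somatotroph", rep(c(0, 0.3), each = 3),
                            reads_per_sample = 2e6, seed = 3)
contam <- contamination_score(
  svr_deconvolve(bulk_cpm(coh$counts), sig,
                 cfg = svr_config(n_permutations = 0)),
  histotype = coh$truth$histotype
)
glance(contam)
#> # A tibble: 1 × 4
#>   n_samples n_contaminated mean_contamination sd_contamination
#> 1         6              3              0.299          0.00142
```

The three contaminated samples are flagged and their residual-normal
fraction is recovered at 0.299 ± 0.001 against the planted 0.30. Results
are tibbles throughout; `tidy()`, `glance()`, `autoplot()` and
`plot_truth_scatter()` cover the usual reporting plots, and
`run_pipeline()` executes the whole chain into a directory of TSV
artifacts reproducibly from one seed.

## Package layout

* `R/` — synthetic reference and bulk-cohort generators; QC, normalization,
  marker detection, GES construction; the two deconvolution engines;
  benchmark evaluation; contamination scoring, batch adjustment and
  clustering flags; IO and the end-to-end pipeline.
* `vignettes/methods.Rmd` — the models, their assumptions, parameter
  conventions and known limitations.
* `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles (simplex grid search, upstream bimod test, edgeR CPM).
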