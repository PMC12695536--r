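---
title: "Deconvolution of pituitary tumor bulk RNA-seq: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolution of pituitary tumor bulk RNA-seq: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Surgical specimens of pituitary neuroendocrine tumors (PitNETs) frequently
entrap non-neoplastic anterior-pituitary cells, and the tumor
microenvironment (TME — stromal and immune populations) contributes its own
signal. Bulk RNA-seq of such specimens therefore mixes the tumor
transcriptome with residual normal tissue of the same or other pituitary
lineages (PIT1, TPIT, SF1), which can masquerade as tumor biology in
downstream analyses. `pitdeconv` implements a reference-based deconvolution
workflow for this setting: it builds cell-type signatures from an annotated
single-nucleus reference of normal pituitary, estimates per-sample cell-type
proportions in bulk data, validates the estimates on pseudobulk mixtures
with known composition, and converts estimated proportions into a
per-sample contamination report with clustering-based flagging.

# Models

## Marker detection and signature construction

The reference is CPM-normalized per cell (`cpm_normalize()`). Markers are
detected one-vs-rest per cell type on natural-log CPM with a bimodal
likelihood-ratio test (`find_markers()`): within each group, expression is
modelled as a point mass at zero with probability $1-\pi$ plus a normal
distribution on the nonzero values; the alternative fits $(\pi, \mu,
\sigma)$ per group and the null a pooled set, so
$2(\ell_{\text{in}} + \ell_{\text{out}} - \ell_{\text{pooled}})$ is
referred to $\chi^2_3$. This matches the "bimod" test of the standard
single-cell toolchain, including its numerical guards ($\pi$ clamped to
$[10^{-5}, 1-10^{-5}]$; $\sigma = 1$ when fewer than two nonzero values),
and the implementation is cross-checked against that toolchain in the test
suite. Genes are tested only when detected in at least `min_pct` (default
0.25) of either group; p-values are Bonferroni-adjusted over all genes in
the matrix, the adjustment method being configurable.

A GES (gene expression signature) of size $N$ keeps, per type, the
significant markers (adjusted $p \le 0.05$, natural-log fold change $> 1$,
where logFC is computed on CPM+1 means), ranks them by within-type mean CPM
— ties broken by smaller adjusted p, then gene id, for reproducibility —
and takes the top $N$ (`build_ges()`, $N \in \{50, 100, 150, 200, 300\}$ by
convention, any positive integer accepted). The union of per-type sets
forms the gene axis; genes never exceeding 1 CPM in any type are dropped.
Member sets are nested across $N$ by construction. Ranking by within-type
mean expression (rather than by fold change) follows the "most highly
expressed genes per cell type" convention; the alternative is one argument
away in the marker table.

The single-cell signature mode (`build_signature_from_cells()`) skips the
marker table: types with fewer than 50 cells are excluded (the usual
low-representation rule, configurable), genes are ranked per type by fold
change of the type mean over the maximum of the other type means, and for
each candidate per-type size $G$ the union-of-top-$G$ signature is scored
by its 2-norm condition number; the best-conditioned $G$ wins. The
condition-number heuristic is a documented approximation of how web-based
deconvolution services pick their internal signatures; their exact rules
are unpublished.

## The ν-SVR engine

`svr_deconvolve()` regresses each z-scored mixture column on the globally
z-scored signature with a linear ν-support-vector regression, for ν in
{0.25, 0.5, 0.75} (configurable), keeping the fit whose reconstruction has
the lowest RMSE. Negative coefficients are clipped to zero and the rest
normalized to sum one ("relative mode"; no absolute-score mode is
provided). Significance comes from a permutation null: random
pseudo-mixtures are assembled by drawing gene values with replacement from
the full mixture matrix, and the p-value is the fraction of null
reconstruction correlations at least as large as the observed one. The
proprietary "B-mode" batch correction of the web service this engine
emulates is *not* reproduced; `batch_adjust()` offers a documented
location/scale alignment instead (off by default), and quantile
normalization is likewise disabled by default. Constant mixture columns
cannot be z-scored and are rejected with a labelled error.

## The weighted-NNLS engine

`wnnls_deconvolve()` works from multi-subject profiles
(`subject_profiles()`): per (donor, type) mean CPM profiles, their
cross-subject variance, and a per-type cell size factor (mean library
size). The design matrix holds type mean profiles scaled by the size
factors, so the non-negative coefficients are cell-count proportions after
normalization — this is what lets the engine report cell fractions rather
than RNA-mass fractions when types differ in RNA content. Genes are
weighted by $w_g = 1/(\varepsilon + \sigma^2_g)$, where $\sigma^2_g$ is the
cross-subject variance of the *reconstructed* expression under the current
proportion estimate and $\varepsilon = 10^{-8} \times \bar{\sigma^2}$;
weighted NNLS (Lawson–Hanson, via `pracma::lsqnonneg`) and weight updates
alternate until the maximum proportion change drops below `tol` ($10^{-6}$)
or `max_iter` (100) is reached. The alternation has no convergence
guarantee: on a minority of samples it settles into a small limit cycle, in
which case the last iterate is returned and flagged in `stats$converged`
(accuracy in our benchmarks is barely affected; a summary warning is
emitted). With one donor, or zero cross-subject variance, the engine
reduces exactly to unweighted NNLS.

## Validation rule and contamination accounting

`evaluate_deconv()` computes, per cell type, the Pearson correlation
between true and estimated proportions across samples with the standard
t-distribution p-value, and calls a type *validated* when $r > 0.70$ and
$p < 0.05$. Types absent from a signature are reported (reason `"absent"`),
never silently dropped; constant vectors give reason `"degenerate"`.

`contamination_score()` partitions estimated proportions by a lineage map:
tumor type(s) of the histotype; same-lineage endocrine types;
residual normal tissue (endocrine types of *other* lineages, posterior
signal, and stem/progenitor signal where applicable); and TME (stromal +
immune). Two conventions deserve mention. First, stem/progenitor signal in
PIT1-lineage tumors is counted as same-lineage by default, because such
signal in somatotroph tumors typically reflects tumor-intrinsic
reprogramming rather than entrapped normal tissue; this is a switch on the
lineage map. Second, the TME fraction is *not* contamination — the
contamination figures concern pituitary residue only. The `contaminated`
flag defaults to residual fraction ≥ 0.20; this threshold is a tool
parameter sitting between the contamination levels reported for clearly
contaminated cohorts (around 40%) and essentially clean ones (around 10%),
not a biological constant.

`flag_discordant()` cuts the complete-linkage dendrogram (Euclidean
distances on the top-500 most variable genes, both defaults configurable)
into $k$ clusters and flags a sample when (a) its cluster's majority
lineage differs from its own, (b) its cluster has no >50% majority, or (c)
it falls outside its lineage's main cluster — the cluster holding the
plurality of that lineage's samples. Condition (c) covers the
"distinct group" pattern: contaminated samples of one histotype often
split off together, forming a cluster that is pure in annotated lineage
and hence invisible to a majority-only rule.

# The synthetic reference

Real inputs to this workflow are controlled-access or external single-cell
atlases, so the package carries a generator (`simulate_reference()`) that
emulates their structure: 13 cell types — somatotrophs, lactotrophs,
thyrotrophs, gonadotrophs, corticotrophs, stem cells and PIT1-lineage
progenitors, plus three stromal and three immune populations — across 3
donors and 2,000 genes. Each type owns a disjoint block of 120 marker genes
enriched 8-fold over a log-normal gene baseline; donors carry per-gene
multiplicative log-normal effects (SD 0.15) shared by all of a donor's
cells, which is precisely the cross-subject variance the weighted-NNLS
engine exploits; counts are negative-binomial (dispersion 0.3, a typical
UMI overdispersion) around log-normal per-cell library sizes (mean 5,000,
CV 0.2); 20 genes are mitochondrial with per-cell expected fractions
uniform on [1%, 4%]. Endocrine types get 150 cells, stromal 80, immune
60/60/40 — immune populations deliberately scarce, with one rare enough to
fall under the 50-cell exclusion so that the absent-type reporting path is
exercised end to end. Cell-type abundances of the real atlas are not
published, so these are configurable defaults, not calibrated values.

What the generator does *not* emulate: transcriptome-wide co-expression,
ambient RNA, doublets, platform noise, and the transcriptional remodelling
of actual tumors. Passing recovery benchmarks on this generator therefore
demonstrates correctness of the estimation machinery under the model's
assumptions — not field performance on real PitNET cohorts, where
signature mismatch (normal reference vs. remodelled tumor) is the dominant
error source.

`simulate_pseudobulk()` realizes "random mixing" as flat-Dirichlet
proportions over the available types with multinomial cell allocation,
cells drawn with replacement (so small populations can exceed their
census), raw counts summed without any per-cell scaling factor, then
CPM-normalized. Whether the original simulation toolchain drew proportions
uniformly or census-weighted is not stated anywhere we could find; the
uniform simplex is the documented, seeded choice. True proportions are
cell-count fractions — for types with unequal library sizes these
deliberately differ from RNA-mass fractions; that discrepancy is a
documented property of the scenario, not a bug.

`simulate_bulk_cohort()` plants contamination directly: a sample with
fraction $f$ has expected profile $(1-f)\,\text{tumor} + f\,\text{residue}$,
with the residue spread over endocrine types outside the tumor's lineage
(configurable), sampled to a fixed read depth by multinomial draw.

# Numerical choices and degenerate inputs

* CPM is exact column scaling; zero-sum columns are labelled errors naming
  the column.
* QC bounds are strict inequalities (1,000 < features < 5,000,
  counts > 200, mitochondrial fraction < 5%); metrics are recomputed from
  the matrix on every call, making `qc_filter()` idempotent.
* All randomness flows from explicit integer seeds;
  `run_pipeline()` derives stage seeds from the single config seed and two
  runs with the same config are byte-identical.
* Duplicate gene ids on input are summed with a warning.
* Ranking ties anywhere (GES ranking, HVG selection) break
  lexicographically so output never depends on hash order.
* The permutation null in the SVR engine treats a constant permuted
  pseudo-mixture as zero correlation rather than NA.

# Problem sizes used in the checks

The bundled checks run the full default scenario — 150 pseudobulk samples
of 500 cells against the 13-type reference — for the headline recovery
benchmark; 50 noiseless 2–3-type mixtures for oracle equivalence against a
0.01-step simplex grid search; 30 bulk samples at 5M reads for
contamination recovery across $f \in \{0, 0.1, \dots, 0.5\}$; and ten
independent 35-sample cohorts for the clustering flag check. These sizes
were chosen to exercise the estimators at the scale of the benchmarks they
mirror while keeping a complete run in the minutes range on a single core.

# Known limitations

* The location/scale batch adjustment is a simplification of
  empirical-Bayes batch correction; `method = "combat"` delegates to the
  `sva` implementation when it is available.
* The weighted-NNLS iteration can cycle rather than converge (flagged, see
  above).
* Signatures built from normal tissue cannot distinguish genuine residual
  normal cells from tumor-intrinsic lineage mimicry; the stem/progenitor
  convention above is a pragmatic default, not a resolution of that
  ambiguity.
* The posterior-pituitary lineage class is supported in the map but the
  default synthetic atlas contains no posterior types; posterior
  contamination can only be represented if the user's reference includes
  such a population.
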