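# pseudolign

Pseudotemporal integration of **unpaired** single-cell transcriptomic
(scRNA-Seq) and proteomic (scp-MS) data.

When a cell population moves continuously through a perturbation — the
motivating system is a FUCCI-reporter HEK293 culture sampled over the first
8 h of hypoxia — the transcriptome and the proteome respond on different
clocks: transcription reacts almost immediately, translation trails by
hours. Measuring both at single-cell resolution yields two datasets with
*different cells*, *different informative features*, and *no shared
coordinate system*. `pseudolign` builds that coordinate system:

1. **Isolate the stimulus from the cell cycle.** Per feature, a nested
   Gaussian model comparison — log expression on cell-cycle phase (reduced)
   versus phase + categorical sampling time (full) — gives a likelihood-ratio
   statistic `Λ = 2(ℓ_full − ℓ_reduced) ~ χ²(T−1)` under the null; Holm
   correction and a top-50 ranking select each modality's own hypoxia
   markers. Cell cycle itself is annotated from FUCCI reporters (protein) or
   marker-gene scores (RNA); a Leiden screen removes an aberrant
   subpopulation first.
2. **One trajectory per modality.** On the marker-restricted, z-scored data:
   adaptive-bandwidth Gaussian kernel on a k-NN graph, density correction,
   transition matrix, and diffusion pseudotime from a root cell,
   `dpt²(x, r) = Σ_{i≥2} (λ_i/(1−λ_i))² (ψ_i(x) − ψ_i(r))²`.
3. **Align the axes.** Cells get order coordinates `u = rank/(n−1)`; the
   median coordinates at the sampling times both experiments share become
   anchors of a monotone piecewise-linear warp (protein → RNA axis). Joint
   standardized profiles with 95% confidence bands, per-modality onset
   times, the transcription–translation lag, and pre-/established-response
   zone boundaries are read off the common axis.

Missing protein intensities are an explicit mask, never zeros; k-NN
imputation over mutually observed features recovers the stimulus variance
that data-dependent acquisition hides in sparsely quantified proteins.

A synthetic-data generator (`simulate_experiment()`) produces coupled
mRNA/protein datasets from shared latent cell states — cycle position,
heterogeneous response delays, first-order protein kinetics with a nominal
`ln(2)/k_deg = 2 h` lag, negative-binomial counts, abundance-biased
detection, FUCCI reporters, planted doublets/failed wells and a planted
discordant subpopulation — with full ground truth, so every stage is
testable without downloads.

## Worked example

```r
library(pseudolign)

res <- run_pipeline(pipeline_config(seed = 42))

glance(res$traj_rna$pt)
#> # A tibble: 1 × 4
#>   n_cells root    oriented spearman_time
#>     <int> <chr>   <lgl>            <dbl>
#> 1     904 RNA0144 TRUE             0.884

glance(res$traj_prot$pt)
#> # A tibble: 1 × 4
#>   n_cells root     oriented spearman_time
#>     <int> <chr>    <lgl>            <dbl>
#> 1     562 PROT0036 TRUE             0.839

res$onset
#> # A tibble: 1 × 4
#>   onset_rna_h onset_prot_h lag_h threshold
#>         <dbl>        <dbl> <dbl>     <dbl>
#> 1        1.79         3.82  2.04       0.5

res$zones
#> <zones> prehypoxia ends at u = 0.485; established response from u = 0.626
```

Reading: after QC, 904 RNA and 562 protein cells remain; each modality's
oriented pseudotime correlates strongly with real sampling time (Spearman
0.88 / 0.84). The transcriptome's aggregate response completes half of its
rise at 1.8 h, the proteome at 3.8 h — an estimated
transcription–translation lag of 2.0 h against the generator's nominal 2 h.
On the common axis, sharp markers separate the prehypoxic zone at u ≈ 0.49
and slow markers mark the established response from u ≈ 0.63.

Useful entry points: `filter_cells()`, `normalize_log1p()`, `knn_impute()`,
`assign_phase_from_fucci()`, `score_cell_cycle()`, `wilcoxon_de()`,
`lrt_rank_markers()`, `cluster_cells()`, `diffusion_map()`,
`dpt_pseudotime()`, `pseudotemporal_order()`, `align_axes()`,
`feature_profile()`, `estimate_onset_lag()`, `demarcate_zones()`. Results
are tibbles or carry `tidy()`/`glance()` methods; `autoplot()` draws
pseudotime-vs-time boxplots and joint profile ribbons. A thin CLI lives at
`inst/cli/pseudolign.R` (`simulate`, `run-all`).

## Scope

Single progressive trajectories only — no branching or discrete cluster
topologies. The methods vignette
(`vignettes/pseudotemporal-integration.Rmd`) documents the model, every
tunable parameter, the generator's assumptions, and known limitations.
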