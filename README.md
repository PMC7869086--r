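# neuroquant

Quantitative anatomy of CB1/CCK-positive GABAergic interneurons: a
tidyverse-native R toolkit for the four measurement pipelines used to
establish cell-type markers and their subcellular distribution —

1. **Single-cell marker mining** (`normalize_expression()`,
   `select_marker_high_cells()`, `rank_candidate_genes()`,
   `correlate_genes()`): per-cell copy-number normalization
   `x · T̄ / T_c`, a strict 10%-of-regional-max `Cnr1` gate with
   Grubbs outlier control (iteration = 1, α = 0.05), detection-fraction
   ranking of candidate gene lists, and Spearman correlation panels.
2. **ISH enrichment quantification** (`compute_enrichment()`,
   `classify_cells()`, `coexpression_summary()`): per-cell enrichment =
   ROI mean / background mean; strong/weak CB1 classification with
   region cutoffs (HC-CA1 2, HC-CA3 4.5, HC-DG 3, SS-CTX 3, BLA 5);
   per-gene positivity and co-expression percentages.
3. **Bouton morphology** (`compute_bdi()`, `classify_targeting()`):
   bouton distribution index `N_SP / (N_SO + N_SR)` (optionally
   area-normalized), with BDI > 1 ⇒ perisomatic and BDI < 0.5 ⇒
   dendritic targeting.
4. **STORM point patterns** (`points_in_roi()`, `roi_density()`,
   `ripley_k_l()`, `pool_rois()`, `csr_envelope()`): ROI filtering,
   localization density with per-image normalization, and Ripley's

   K̂(r) = A / (n(n−1)) · Σ_{i≠j} e_ij · 1(d_ij ≤ r),  L = √(K/π)

   with isotropic edge correction (exact for rectangles, arc-sampled for
   polygons), r_max = 1000 nm, far-apart ROI pooling and CSR envelopes.

Seeded generators (`sim_expression()`, `sim_ish_table()`,
`sim_ish_image()`, `sim_localizations()`, `sim_bouton_map()`) produce
ground-truthed inputs for every stage, so each pipeline is tested as a
recovery problem. Statistical primitives (`grubbs_test()`,
`mann_whitney_u()`, `kruskal_wallis()`, `ks_normality()`) come with exact
small-sample branches. Results carry `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures.

## Worked example

Simulate a CA1-like RNAscope quantification of 194 strong-CB1 interneurons
whose true *Necab1* positivity is 92% and *Necab2* positivity 100%, then
recover the co-expression table from the sampled enrichments:

```r
library(neuroquant)
library(dplyr)

cfg <- ish_sim_config(region = "HC-CA1", n_cells = 194, p_strong = 1,
                      p_pos = c(Necab1 = 0.92, Necab2 = 1), seed = 1)
sim_ish_table(cfg)$quant |>
  classify_cells() |>
  coexpression_summary() |>
  filter(cb1_class == "strong")
#> # A tibble: 4 × 7
#>   region cb1_class n_cells target n_positive  frac   pct
#>   <chr>  <chr>       <int> <chr>       <int> <dbl> <dbl>
#> 1 HC-CA1 strong        194 Necab1        180 0.928  92.8
#> 2 HC-CA1 strong        194 Necab2        194 1     100
#> 3 HC-CA1 strong        194 all           180 0.928  92.8
#> 4 HC-CA1 strong        194 none            0 0       0
```

92.8% of cells classify *Necab1*-positive in this draw (binomial noise
around the 92% truth at n = 194); every *Necab2* channel clears its cutoff.
A clustered STORM pattern against its CSR envelope:

```r
w <- window_rect(0, 2000, 0, 2000)   # nm
pts <- sim_localizations(point_process_config(w, "Thomas", intensity = 5,
                                              offspring_mean = 20,
                                              offspring_sigma = 30, seed = 7))
res <- ripley_k_l(pts, w, r_max = 500)
env <- csr_envelope(w, n_points = nrow(pts), n_sims = 199, r_max = 500, seed = 8)
autoplot(res, envelope = env)   # L(r) - r rises above the envelope: clustering
```

See `vignettes/quantitative-interneuron-anatomy.Rmd` for the models,
parameter defaults, and numerical choices.

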