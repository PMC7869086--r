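---
title: "Quantitative anatomy of CB1/CCK-positive interneurons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative anatomy of CB1/CCK-positive interneurons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroquant)
library(dplyr)
```

`neuroquant` packages the four quantitative procedures used to establish
NECAB1 and NECAB2 as calcium-binding markers of CB1/CCK-positive GABAergic
interneurons, together with seeded generators that produce ground-truthed
inputs for each stage. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic data do and do not
emulate.

## 1. Single-cell marker mining

**Model.** Interneuron candidate mining runs on a cells-by-genes copy-number
table. Three steps matter:

1. *Normalization.* Each cell's values are rescaled by $\bar T / T_c$, where
   $T_c$ is the cell's total copy number and $\bar T$ the dataset mean total.
   Single-cell capture chemistry multiplies every gene of a cell by an
   unknown harvesting efficiency; equalizing totals removes exactly that
   multiplicative factor. We read "normalized to the mean of the total copy
   number per cell" as this rescaling rather than a plain division by
   $\bar T$, because only the rescaling cancels the per-cell bias; the
   alternative is a one-line change and would not equalize totals.
   Note the identifiability limit: after normalization, per-gene means equal
   the true profile means times the mean capture efficiency. Recovery is
   therefore assessed compositionally — normalized per-gene means against
   profile means rescaled to the realized mean total — which is exact in
   expectation and free of the unidentifiable global scale.
2. *Marker gating.* Within each brain region, cells are retained when the
   marker (`Cnr1` by default) strictly exceeds `threshold_frac` (default
   0.1) of the region's maximum marker value — "exceeding" makes the
   inequality strict, so a cell at exactly 10% of max is excluded. A
   GABAergic class pre-filter can be applied first, matching the original
   order of operations. The retained marker values then pass
   `grubbs_iterations` (default 1) rounds of a two-sided Grubbs test at
   `grubbs_alpha` (default 0.05); a significant outlier is removed each
   round and logged in an audit table. The variable tested and the
   sidedness are not documented in the source procedure; we default to the
   marker values and two-sided testing, both configurable.
3. *Screening and correlation.* Candidate genes (e.g. the 660 GO
   "calcium-binding" annotations, supplied as a plain gene list) are ranked
   by detection fraction (normalized level ≥ 1 copy) with ties broken by
   mean level and then gene symbol. Spearman correlations between marker
   panels use average ranks for ties and t-approximate p-values, flagged
   when n < 10.

**Generator.** `sim_expression()` draws counts per gene and cell from a
negative binomial parameterized by (mean, size); `size -> Inf` or
`poisson = TRUE` gives the Poisson limit used for closed-form checks. The
per-cell efficiency is log-uniform on `efficiency_range` (default 0.5–2, a
4-fold capture spread typical of plate-based single-cell protocols) and
multiplies all gene means, so normalization has exactly the bias it claims
to remove, and the truth table carries the factor for recovery tests.
Positivity rules make a gene an all-or-none Bernoulli per cell type, which
is how the anti-correlated `Pvalb`/`Sst` versus `Necab` structure is
emulated. No distributional parameters are published for the mined dataset,
so all profile scales are stand-ins declared in configs, never hard-coded in
analysis code.

## 2. ISH enrichment scoring and classification

**Model.** A cell's enrichment is its ROI mean pixel intensity divided by
the background mean. The default background is the complement of the union
of all cell ROIs dilated by 2 px (square structuring element) — the
published procedure says only "background mean", so an explicit background
polygon is accepted as an override. Pixels belong to a ROI by the
pixel-centre test in 0-based, origin-top-left coordinates; analysis is
single-plane (z-stacks must be reduced upstream).

Cells are classified strong- versus weak-CB1 by region cutoffs (HC-CA1 2,
HC-CA3 4.5, HC-DG 3, SS-CTX 3, BLA 5) and positive per gene by gene cutoffs
(default 2 — the gene-level cutoffs are not published). The boundary is
inclusive (≥ cutoff ⇒ strong/positive) since cutoff values such as "2" are
printed without tie rules; `boundary = "exclusive"` flips this.
Classification is monotone: raising an enrichment can never turn a positive
cell negative.

**Generator.** `sim_ish_table()` draws per-cell truths and lognormal
enrichments `cutoff * exp(N(location, scale))`. The default laws put the
location 5 scale-units from the cutoff on the correct side: the per-draw
misclassification mass is `pnorm(-5) ≈ 3e-7`, beyond the 0.999
guaranteed-separation margin the generator promises, so end-to-end
classification recovers the truth for 100% of cells at the study sizes
(hundreds of cells, hundreds of seeds). `sim_ish_image()` renders the same
truths as Poisson pixel noise (nucleus disks at `background_mean *
enrichment` on a `background_mean` field), one channel per call, providing
the from-pixels round trip; Poisson error of a ~200-pixel ROI at background
200 counts is well under the 10% recovery tolerance. The images emulate
intensity statistics only — no optics (PSF, chromatic shift), no chemistry
(probe efficiency, bleed-through), so a passing round trip validates the
measurement arithmetic, not image restoration.

```{r ish-demo}
cfg <- ish_sim_config(region = "HC-CA1", n_cells = 194, p_strong = 1,
                      p_pos = c(Necab1 = 0.92, Necab2 = 1), seed = 1)
sim <- sim_ish_table(cfg)
cl <- classify_cells(sim$quant)
suppressWarnings(coexpression_summary(cl)) %>%
  filter(cb1_class == "strong")
```

## 3. Bouton distribution index

The exact BDI formula lives in earlier work and is not restated in the
source; the default here is the bouton-count ratio
$\mathrm{BDI} = N_\mathrm{SP} / (N_\mathrm{SO} + N_\mathrm{SR})$, consistent
with the gloss that BDI > 1 means an axon arbor "mainly restricted to the
stratum pyramidale". Because the three layers differ several-fold in
thickness, a `density_ratio` mode normalizes the counts by layer areas; the
mode used is recorded in every result row. Classification: BDI > 1
perisomatic, BDI < 0.5 dendritic, everything else (including the boundary
values the strict inequalities leave unassigned) "ambiguous", the class that
was omitted from downstream analysis. At n = 500 boutons, layer
probabilities of 0.7 (perisomatic) or 0.2 (dendritic) sit > 4 binomial SDs
from the decision boundaries, so class recovery exceeds 99% of seeds.

## 4. STORM point-pattern analysis

**Density.** ROI density is NLP (number of localization points, boundary
inclusive, even-odd rule) per μm² of ROI area (shoelace formula, nm² to μm²
by 1e-6). The normalized density divides by the full-field localization
density of the image, cancelling image-to-image immunostaining/imaging
variability; whether the original normalization used the full field or an
immunopositive mask is unstated, so the full field is the default and any
mask can be passed as `image_points`. z coordinates are carried but ignored:
densities are per-area and the L-function planar.

**Ripley's K/L.** The estimator is
$\hat K(r) = \frac{A}{n(n-1)} \sum_{i \ne j} e_{ij} 1(d_{ij} \le r)$ with
the isotropic correction $e_{ij}$ equal to the reciprocal of the fraction of
the circle centred at point $i$ with radius $d_{ij}$ inside the window, and
$L = \sqrt{K/\pi}$. The maximal radius defaults to 1000 (nm — the unit is
not printed with the radius, but nm is the coordinate unit). The r grid is
100 evenly spaced radii in `(0, r_max]`. For rectangles the circle fraction
is exact: each edge cuts off an arc confined to the half-circle facing it,
so only adjacent-edge arcs can overlap and pairwise inclusion–exclusion
closes the union exactly. For general simple polygons the fraction is
sampled at `n_arc = 720` circle points (error of the fraction ≤ 1/`n_arc`
per intersected arc; configurable). Extreme weights are logged, never
capped — transparency over silent truncation. Duplicate coordinates are
legal and contribute from the smallest positive radius on. Deep-interior
patterns reduce every weight to exactly 1, which is how the estimator is
pinned against a naive unweighted oracle in the tests.

**Pooling and envelopes.** ROIs analysed jointly are translated onto a
horizontal grid with bounding-box gaps exceeding `r_max`, so no cross-ROI
pair can enter any sum, and the union of translated polygons becomes a
multi-polygon window. CSR envelopes are pointwise min/max of `L - r` over
`n_sims` (default 199) binomial patterns.

**A note on the CSR consistency check.** $\hat K$ is unbiased under CSR,
but $\hat L = \sqrt{\hat K / \pi}$ is Jensen-biased downward wherever the
expected pair count is small: at radii with ~1 expected pair the bias is
several Monte-Carlo standard errors and no unbiased-$K$ estimator can avoid
it. The CSR consistency suite therefore evaluates radii from 0.025 to 0.25
of the unit-square side (hundreds of expected pairs at n = 200, where the
square-root transform is effectively linear) and uses a 3-SE band, and
additionally checks $\hat K$ against $\pi r^2$ directly.

```{r ripley-demo, fig.width = 5, fig.height = 3.2}
w <- window_rect(0, 2000, 0, 2000)
th <- sim_localizations(point_process_config(w, "Thomas", intensity = 5,
                                             offspring_mean = 20,
                                             offspring_sigma = 30, seed = 7))
res <- ripley_k_l(th, w, r_max = 500)
env <- csr_envelope(w, n_points = nrow(th), n_sims = 39, r_max = 500, seed = 8)
autoplot(res, envelope = env)
```

**Generators.** CSR draws a Poisson(`intensity` × area) count uniformly in
the window; the Thomas process draws parents in the bounding box dilated by
4σ (so clusters seeded just outside the window still contribute — standard
cluster-process practice) with Poisson(`offspring_mean`) Gaussian offspring,
clipped to the window. σ = 30 nm with ~20 offspring per parent mimics the
tight molecular clusters that make `L(r) - r` positive by r = 100 nm; the
generators simulate no blinking, drift, or multi-emitter artifacts, so
passing tests validate the spatial statistics, not localization-microscopy
artifact handling.

## 5. Statistical primitives

* `grubbs_test()`: maximum studentized deviate against
  $G_{crit} = \frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$ with $t$ the upper
  $\alpha/2n$ t-quantile on $n-2$ df; zero variance flags nothing.
* `mann_whitney_u()`: exact p by full enumeration of all labelings when
  $n_x + n_y \le 12$ (desk-scale `choose(12, 6) = 924` enumeration) and no
  ties; otherwise normal approximation with tie and continuity corrections.
  The branch taken is reported.
* `kruskal_wallis()`: H with tie correction, chi-square reference (flagged
  when any group n < 5).
* `ks_normality()`: KS distance against a normal with fitted mean/SD. The
  asymptotic p ignores parameter estimation and is anti-conservative — this
  is surfaced in the method string rather than hidden; `lilliefors = TRUE`
  calibrates by a Monte-Carlo null with re-fitted parameters.
* Sidedness is not documented in the source; all tests default to
  two-sided.

## 6. Problem sizes and calibration checks

The test suite works at the following sizes, chosen so that every
distributional claim has a comfortable Monte-Carlo margin: CSR consistency
with 200 simulations of n = 200 in the unit square; Thomas detection over
100 seeds (~400 points each); normalization recovery at 10,000 cells;
type-I calibration of Mann–Whitney (n = 20 + 20) and Kruskal–Wallis
(3 × 15) over 10,000 null replicates against the band [0.042, 0.058];
co-expression recovery at the published sample sizes (194/156/105/74 cells)
averaged over 500 seeds. Larger sizes change none of the conclusions.

## 7. Known limitations

* ROI delineation (morphological active contours) and raw-frame STORM peak
  detection are out of scope: ROIs and localization tables are inputs.
* The rectangle edge correction is exact; polygonal windows inherit the
  1/`n_arc` arc-sampling error (raise `n_arc` where ppm-level agreement is
  needed).
* The ISH generator's guaranteed separation makes classification accuracy a
  property of the configuration; it measures pipeline correctness, not the
  difficulty of classifying borderline real cells.
* The synthetic expression mixture reproduces marker co-expression
  structure, not a full transcriptome: library-size confounds beyond a
  single multiplicative efficiency (e.g. cell-cycle, ambient RNA) are not
  modelled.
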