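---
title: "periloc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{periloc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periloc)
```

This vignette is the package's account of the science it implements: the
models, the parameters that matter, the numerical conventions, and what
the synthetic data can and cannot tell you about real experiments.

## The Peripheral Distribution Index

Many mRNAs are actively localized: transported along the cytoskeleton
toward the cell periphery, or retained near the nucleus. A
population-level, segmentation-light way to quantify this from a FISH
image is a radial second-moment ratio. For one segmented cell with RNA
intensity $I_i$ on pixels $i$, cell mask $C$ and nuclear mask $N \subseteq
C$:

$$\mathrm{PDI} \;=\;
\frac{\sum_{i \in C} I_i\, d_i^2 \,/\, \sum_{i \in C} I_i}
     {\tfrac{1}{|C|}\sum_{j \in C} d_j^2},$$

where $d_i$ is the Euclidean distance from the center of pixel $i$ to the
centroid of the nuclear mask. The numerator is the second moment of the
observed signal; the denominator is the second moment the same cell would
have if the signal were spread uniformly — so the cell's own shape and
size cancel, and:

* PDI = 1: diffuse signal filling the cell;
* PDI < 1: signal concentrated near the nucleus;
* PDI > 1: signal pushed toward the periphery.

Conventions (`nucleus_centroid()`, `intensity_second_moment()`,
`uniform_second_moment()`, `compute_pdi()`):

* Pixel coordinates are 0-based `(row, col)` at pixel centers; pixels are
  assumed square and all distances are in pixel units. No physical
  calibration enters, because the uniform-moment normalization makes the
  ratio dimensionless.
* The nucleus centroid is the *unweighted* mean of nuclear-mask pixel
  coordinates (DAPI intensity is not informative here).
* Inputs are single 2-D rasters; maximum-intensity projection of z-stacks
  is upstream of the package.
* The ratio is exactly invariant under positive scaling of the raster and
  under 90° rotations of raster plus masks, and invariant to translation
  up to float rounding — the test suite asserts all three.

### Processing pipeline and its two knobs

`compute_pdi()` (1) subtracts a scalar background and clips at zero,
(2) optionally zeroes all pixels of the nuclear mask, (3) computes the
moment ratio. Two parameters deserve attention:

* **`background`** (intensity units, default 0, or `"auto"`). Microscopy
  rasters carry an additive offset; because the PDI weights pixels by
  intensity, an offset drags the index toward 1. The estimation procedure
  is deliberately configurable: `"auto"` uses the median intensity outside
  the cell mask, a robust choice when the field of view contains mostly
  non-cell area; a measured scalar can be passed instead. The value
  actually subtracted is recorded in the result row.
* **`subtract_nuclear_signal`** (default `FALSE`). For oligo-dT (polyA)
  channels the nuclear signal is dominated by unexported transcripts and
  is subtracted by convention. Subtraction removes nuclear *signal* but
  keeps nuclear *pixels* in the uniform-moment denominator, so a perfectly
  diffuse cytoplasmic signal then yields PDI > 1 — an apparent increase,
  not a biological one. The inflation grows with the nuclear area
  fraction, which is why PDI values must not be compared across cell
  populations with very different spreading areas: in poorly spread cells
  the nucleus covers a larger fraction of the cell. `compute_pdi()` flags
  (never excludes) cells whose nuclear/cell area ratio exceeds
  `nucleus_area_threshold` (default 0.5); comparisons should be anchored
  on an internal diffuse control channel within the same cells. The
  acceptance suite checks both directions of this effect on two
  geometries.

Cells that fail (zero signal after background subtraction, empty nucleus)
raise classed errors from `compute_pdi()`; `pdi_batch()` converts them to
flagged rows with `NA` PDI so a population table never silently drops
cells.

## The fractionation count statistics

The second arm of the package analyses gene × sample count matrices from
paired protrusion (Ps) / cell-body (CB) fractions, with two or more
replicates per fraction per condition.

### Normalization and filtering

`log_cpm()` computes $\log_2\!\big((c + 0.5)\,/\,(L + 1) \times 10^6\big)$
with library size $L$; the half-count offset keeps zeros finite and the
matching +1 keeps the transform monotone in $c/L$. `filter_expressed()`
keeps genes with log-CPM > 0.5 in at least one sample.

For the *testing* paths (`enrichment_test()`, `diff_fc()`) the default
library sizes are TMM-scaled effective sizes
(`effective_lib_sizes(..., "tmm")`, via `edgeR::calcNormFactors`). The
reason is compositional: a fractionation experiment plants real mass
asymmetry — if ~5% of genes carry 4-fold more counts in Ps, raw Ps
totals are inflated by ~15–20%, which shifts the log-ratio of *every*
unenriched gene by about −0.2 and inflates the null false-positive rate
well above nominal. Trimmed-mean-of-M-values scaling estimates the
scaling factor from the unchanged bulk of genes and restores both the
centering of null log-ratios and the nominal type-I rate; the acceptance
suite verifies 5% ± 1% on null simulations and ≤ 7% false positives on
simulations with planted enrichment. `normalization = "total"` switches
back to raw totals (used in the closed-form unit tests, and appropriate
when composition effects are known to be absent). The direct-ratio path
`ps_cb_ratio_direct()` — a stand-in for probe-panel normalization —
deliberately stays with plain total-count scaling, since probe panels
measure a small targeted set.

### The moderated t-test

With 4 replicates per fraction, per-gene variance estimates are noisy;
the standard remedy is empirical-Bayes moderation. Per gene $g$ the model
is a cell-means fit on log-CPM: the enrichment coefficient is
$\widehat{\beta}_g = \bar{x}_{Ps} - \bar{x}_{CB}$ (so $\widehat{\beta}_g$
*is* the log2 Ps/CB fold change, Ps in the numerator) with residual
variance $s_g^2$ on $d_g$ degrees of freedom. Variances are shrunk toward
a prior $(d_0, s_0^2)$:

$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
t_g = \frac{\widehat{\beta}_g}{u\,\tilde{s}_g},\qquad
t_g \sim t_{d_0 + d_g} \text{ under } H_0,$$

with $u$ the unscaled coefficient standard deviation
($\sqrt{1/n_1 + 1/n_2}$ for the two-group contrast). The prior is fitted
by method of moments on $\log s_g^2$: under the hierarchical model the
log variances are shifted log-chi-squared, so matching their mean and
excess spread (via the trigamma function and its Newton inverse) yields
$(d_0, s_0^2)$; a non-positive excess returns $d_0 = \infty$ (all genes
share one variance). Both parameters are overridable, which the unit
tests use for closed-form checks, and the two limits behave as expected:
$d_0 = 0$ reproduces the ordinary equal-variance t-test, $d_0 = \infty$
a z-like test on the pooled prior variance. With the same prior injected,
the statistics agree with the reference empirical-Bayes implementation in
`limma` to 1e-9, which the suite uses as an independent cross-check.

### Enrichment and dependence calls

* `classify_ps_enriched()`: Ps-enriched iff FC > 2 (natural scale) *and*
  p < 0.05. Both cutoffs are arguments.
* `diff_fc()`: the change in enrichment between conditions,
  $\log_2(\mathrm{Diff\,FC}) = \log_2 FC_{perturbed} - \log_2
  FC_{control}$, estimated as the fraction × condition interaction of the
  four-group cell-means model, moderated-t as above. Negative values mean
  the gene lost Ps enrichment in the perturbed condition. Attaching the
  p-value to the interaction contrast is a documented choice; nothing in
  the design identifies a per-condition pairing, so the interaction is
  the natural estimand.
* `classify_dependence()`: among Ps-enriched genes, *dependent* iff
  $\log_2(\mathrm{Diff\,FC}) \le -1$ and p < 0.05 (defaults). The rule is
  one-sided on purpose: dependence is defined by *loss* of enrichment
  under perturbation, so gains — however significant — are classified
  independent. The cutoffs are required configuration, not constants;
  a 2-fold drop at p < 0.05 is the default.
* `hypergeometric_overlap()` / `gene_set_overlap()`: inclusive upper-tail
  hypergeometric p for the overlap of two sets in a universe, BH-adjusted
  across a collection. The recommended universe is the intersection of
  genes passing the expression filter in the experiments being compared;
  the functions take the universe explicitly rather than guessing it.

## The synthetic-data generators

### Cell images

`simulate_cell_image()` emulates a single-cell FISH channel: an
elliptical cell with an interior elliptical nucleus (arbitrary offset and
rotation; validity — nucleus inside cell, cell inside frame — is checked
on a dense boundary parametrization), `n_spots` diffraction-limited spots
placed with one of three radial laws about the nucleus centroid, a
Gaussian PSF of `psf_sigma_px` (spots are evaluated analytically on the
pixel grid, windowed at 4σ), a constant background, and optional Gaussian
(clipped at 0) or Poisson noise applied *after* blurring, with the
blurred raster as the Poisson rate. Radial laws:

* `uniform`: uniform over cell-mask pixels — the calibration class, whose
  mean squared radius equals the mask average (tested to 3 standard
  errors at 5000 spots, against a brute-force mask summation);
* `perinuclear`: isotropic Gaussian, σ = `radial_param` × mean cell
  radius (mean distance of mask pixels from the nucleus centroid),
  truncated to the mask by rejection sampling with a hard iteration cap
  (a classed error, not an infinite loop, if the acceptance region is
  tiny);
* `peripheral`: uniform over mask pixels whose distance from the nucleus
  centroid is at least `radial_param` × the mask's maximum distance.

Each generated object consumes its own RNG stream (`withr::with_seed`
from the field spec's seed; batches derive per-cell seeds as `seed + i − 1`),
so generating more cells never changes earlier ones and identical specs
are bit-identical. `cell_image_pattern()` provides the *deterministic*
analytic counterparts (uniform / truncated-Gaussian / outer-shell
intensity fields) used for calibration: uniform gives PDI = 1 exactly up
to float error, the Gaussian with σ ≤ 0.2 × mean cell radius gives
PDI < 1, the outer 15–20% shell gives PDI > 1.

There are no canonical quantitative spot densities or noise levels for
real FISH images, so the defaults (300 spots, PSF σ 1.5 px, no noise) are
stated as plausible placeholders and every one is exposed. What the
simulation does *not* emulate: irregular (non-elliptical) cell outlines,
z-projection artefacts, probe-specific amplification noise, segmentation
errors, or spatially structured background. Passing tests therefore
demonstrate the *metric* and *pipeline* are correct and calibrated — not
that any particular biological image will be noise-free.

### Count experiments

`simulate_ps_cb_counts()` emulates the paired fractionation design: two
fractions × two conditions × `n_replicates` (default 4, matching the
replication of the motivating design). Gene baselines are log-normal
(defaults: log2 mean 6, log2 sd 2 — a realistic spread of expression
across ~3 orders of magnitude), counts are negative-binomial with
dispersion 0.05 (typical for cell-line RNA-Seq; 0 gives Poisson),
per-sample size factors are log-normal with log2 sd 0.2. Planted truth:
`n_enriched` genes get ×2^`true_log2fc` in Ps in both conditions;
`n_dependent` of them have the enrichment multiplied by
(1 − `dependence_attenuation`) in the perturbed condition (default 1:
complete loss). The defaults — 2000 genes, 100 enriched at log2FC 2, 50
dependent — are the conditions under which the recovery rates quoted in
the test suite are asserted: ≥ 90% of planted enriched genes recovered by
the FC > 2 & p < 0.05 rule, ≥ 85% of planted dependent genes classified
dependent with ≤ 10% misclassification of independents, and a null
false-positive rate within 5% ± 1% (10 seeds × 2000 genes). Not
emulated: GC/length biases, batch effects, isoform structure, or
correlated genes; recovery rates on real data will be lower.

## Numerical choices and degenerate inputs

* Empty nuclear mask, empty cell mask, zero total signal: classed errors
  (`periloc_empty_nucleus`, `periloc_empty_mask`, `periloc_low_signal`);
  `pdi_batch()` turns them into flagged rows.
* A gene with zero residual variance in all groups: the moment fit of the
  variance prior excludes non-finite log variances; with a fixed prior the
  moderated t of a zero coefficient is defined as 0 (p = 1).
* `cumulative_fraction()` is right-continuous with ties sharing a step;
  values are required finite.
* Hypergeometric p-values are inclusive upper tails, so an overlap of 0
  gives exactly 1; BH adjustment delegates to the stock step-up
  implementation after validating the inputs.
* Image rasters are written as 32-bit TIFF scaled into [0, 1] by their
  maximum (the writer returns the factor); the PDI's scale invariance
  makes this lossless for quantification, and the round trip is tested.

## Problem sizes

The test suite and the calibration script are sized for a laptop-class
single core: PDI calibration on 512 × 512 rasters (~75,000 mask pixels),
brute-force oracle comparisons on 100 random ≤ 16 × 16 images,
statistical calibration on 2000-gene × 16-sample simulations (10 seeds
for the null rate), and the full suite runs in well under a minute. All
rates quoted above are the ones the suite itself computes at those sizes.

## Known limitations

* The PDI compares distributions only *within* comparable cell
  populations; the nuclear-subtraction inflation makes cross-population
  comparisons invalid when spreading areas differ (the flag helps, the
  user decides).
* The moderated-t path assumes approximately normal log-CPM residuals and
  a common variance across the groups of a gene; it does not implement
  observation-level precision weights, so strongly heteroskedastic
  low-count genes are better served by the expression filter than by the
  model.
* TMM scaling assumes the majority of genes are unchanged between
  fractions; designs where most of the transcriptome relocalizes would
  need spike-in normalization, which is out of scope.
* The dependence call inherits both cutoffs from configuration; it is a
  screen, not a posterior probability.
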