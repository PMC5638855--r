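# periloc

Quantifying peripheral RNA localization in cells, from two directions:

* **Imaging** — many mRNAs are not distributed uniformly through the
  cytoplasm but are transported toward the cell periphery and protrusions.
  Given a single-molecule FISH image of one segmented cell (RNA intensity
  raster, binary cell mask, binary nuclear mask), `periloc` computes the
  **Peripheral Distribution Index (PDI)**: the intensity-weighted second
  moment of the RNA signal about the nucleus centroid, normalized by the
  second moment of a hypothetical uniform signal over the cell mask,

  PDI = [ Σᵢ Iᵢ·dᵢ² / Σᵢ Iᵢ ] / [ (1/N)·Σⱼ dⱼ² ]

  where *dᵢ* is the distance of pixel *i* from the nucleus centroid, the
  numerator runs over cell-mask pixels of the RNA channel and the
  denominator over the N cell-mask pixels with uniform weight. PDI = 1 is
  a diffuse signal, PDI < 1 perinuclear concentration, PDI > 1 peripheral
  concentration.

* **Fractionation counts** — cells grown on microporous filters can be
  separated into a protrusion (Ps) and a cell-body (CB) fraction, each
  profiled by RNA-Seq or probe counting. `periloc` implements the
  companion statistics: log2-CPM transformation with composition-robust
  (TMM) library scaling, the expression filter (log-CPM > 0.5 in at least
  one sample), an empirical-Bayes **moderated t-test** of per-gene Ps/CB
  enrichment, the Ps-enrichment call (FC > 2 and p < 0.05), the
  differential-enrichment contrast between a perturbed and a control
  condition, log2(Diff FC) = log2(FC_perturbed) − log2(FC_control), with
  a one-sided dependence classification, direct normalized-count ratios,
  cumulative-fraction (ECDF) summaries, and hypergeometric gene-set
  overlap tests with Benjamini–Hochberg adjustment.

Because the interesting validation cases need known truth, the package
also ships first-class **synthetic-data generators**: FISH-like cell
rasters (elliptical cell/nucleus geometry, spots with uniform /
perinuclear / peripheral radial bias, Gaussian PSF blur, background,
Gaussian or Poisson noise) and paired Ps/CB negative-binomial count
experiments with planted enriched and dependence-attenuated genes.

Intended users: cell biologists quantifying subcellular mRNA localization
and bioinformaticians analysing protrusion-fractionation experiments.

## Worked example

Simulate three populations of cells with different radial RNA biases and
quantify them:

```r
library(periloc)
library(dplyr)

geom <- cell_geometry(256, 256, c(100, 60), c(30, 20), c(5, 8))
cells <- c(
  setNames(simulate_cell_images(5, geom, spot_field(400, "uniform", seed = 1)),
           paste0("unif_", 1:5)),
  setNames(simulate_cell_images(5, geom, spot_field(400, "perinuclear", 0.25, seed = 100)),
           paste0("peri_", 1:5)),
  setNames(simulate_cell_images(5, geom, spot_field(400, "peripheral", 0.7, seed = 200)),
           paste0("shell_", 1:5)))

pdi_batch(cells) |>
  mutate(group = sub("_[0-9]+$", "", cell_id)) |>
  group_by(group) |>
  summarise(mean_pdi = mean(pdi), sd = sd(pdi))
#>   group mean_pdi      sd
#> 1 peri     0.104 0.00432
#> 2 shell    2.06  0.00473
#> 3 unif     0.980 0.0270
```

Perinuclear cells sit well below 1, uniform cells at 1, peripheral cells
well above — the three regimes the index is built to separate
(`plot_pdi()` draws the per-cell strip plot).

The count pipeline, end to end on a simulated two-condition experiment
with 100 planted Ps-enriched genes of which 50 lose their enrichment in
the perturbed condition:

```r
sim  <- simulate_ps_cb_counts(seed = 42)     # 2000 genes, 4 replicates
keep <- filter_expressed(log_cpm(sim$counts))
fit  <- enrichment_test(sim$counts[keep, ], sim$sample_info, "control")
glance(fit)
#>   n_genes prior_df prior_var df_residual condition
#> 1    2000     7.80     0.149           6 control

cls  <- classify_ps_enriched(fit)                  # FC > 2 & p < 0.05
dd   <- diff_fc(sim$counts[keep, ], sim$sample_info)
classify_dependence(cls, dd) |> count(localization, dependence)
#>   localization  dependence         n
#> 1 non_localized not_applicable  1896
#> 2 ps_enriched   dependent         52
#> 3 ps_enriched   independent       52
```

104 genes are called Ps-enriched (the 100 planted plus 4 false calls)
and 52 are classified as dependent on the perturbed factor (the 50
planted plus 2). `tidy(fit)` returns the per-gene table; `autoplot(fit)`
draws the volcano plot and `plot_cumulative_fraction()` the ECDF of
log2(Diff FC).

A command-line front end wrapping the same functions ships in
`inst/exec/periloc` (subcommands `simulate-image`, `simulate-counts`,
`pdi`, `enrich`, `diffclass`, `overlap`, `ecdf`); every run writes a
`manifest.json` with all parameters and seeds.

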