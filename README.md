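# grainspectra

Analysis of series of macroscopic multispectral autofluorescence images of
wheat grain cross-sections across development. Plant cell-wall phenolics,
chlorophyll and lignin-related structures fluoresce in characteristic
emission bands under UV, blue and green excitation; imaged at the
macroscale (whole transverse sections, a few µm per pixel), their spatial
distribution can be followed across the grain's tissue layers — pericarp,
endocarp, testa, aleurone, starchy endosperm, crease — at four
developmental stages (250, 450, 650, 850 °DAF, ten sections each). The
package is aimed at image-analysis and plant-science workflows that need
to compare such multi-image fluorescence series quantitatively.

## What it computes

* **Cube assembly** — four RGB filter acquisitions (U1, U2, Blue, Green;
  14-bit) merge into a 12-channel image ordered by emission wavelength;
  the reflection-contaminated `U1r` channel is dropped, leaving 11
  channels whose per-pixel rows are *pseudo-spectra*. Per-channel additive
  backgrounds are estimated from signal-free regions and subtracted.
* **Regions of interest** — the whole section (gray-level threshold 2 on
  the 8-bit sum-of-intensity image, square opening/closing 51/150 px at
  reference scale, largest region) and the outer tissues (two Otsu
  thresholds restricted to section pixels — total sum and the UV-weighted
  sum U1b+U1g+U2b+U2g+BLg — merged, disk opening/dilation/opening 1/8/12,
  largest region). Section areas in mm² come from the whole-section mask.
* **Large PCA** — one PCA over all section pixels of the series, fitted
  streaming: each image contributes its pixel count, pseudo-spectrum sum
  and cross-product matrix X'X; the accumulated covariance

      C = (Σᵢ XᵢᵀXᵢ − N m mᵀ) / (N − 1)

  is eigendecomposed into eigenvalues λₖ and loadings L common to the
  series. Scores (x − m)ᵀLₖ refold into score images, rendered 8-bit with
  series-wide bounds ±3√λₖ.
* **Score distributions** — per component, all outer-tissue scores pool
  into a 10,000-bin histogram; its percentiles (1 % steps) define ≤ 100
  shared variable-width bins; each image's observed distribution is its
  per-bin relative frequency. Stage averages and a PCA of the stacked
  distributions (the *similarity map*) compare developmental stages.
* **Synthetic phantoms** — ground-truthed section phantoms (tissue ring
  geometry with crease, three endmember fluorophores, stage trajectories,
  Gaussian noise, 14-bit quantization) reproduce the study design so the
  whole pipeline is testable end to end without the unreleased raw data.

## Worked example

```r
library(grainspectra)
run <- run_pipeline(default_run_config(seed = 1))  # 4 stages x 10 sections
run$area_by_stage
#>     mean_mm2    sd_mm2  n stage
#> 250 4.827112 0.2274122 10   250
#> 450 6.570216 0.3508343 10   450
#> 650 7.105053 0.2158820 10   650
#> 850 6.269722 0.2966569 10   850
round(run$pca$explained[1:5], 2)
#> [1] 63.50 29.54  6.82  0.03  0.02
```

Measured section areas grow from ~4.8 mm² at 250 °DAF to ~7.1 mm² at
650 °DAF and shrink slightly at 850 °DAF; the first three components
carry >99.8 % of the spectral variance. The mean component-1 score over
the outer tissues rises strictly with stage (−290.6, −231.7, −216.1,
−146.7 for seed 1) — the fading of red chlorophyll emission — and stage
centroids order monotonically along axis 1 of the component-1 similarity
map (−0.140, 0.022, 0.053, 0.066).

The `analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate.R` … `05_similarity.R`), each writing its tables
under `results/`.

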