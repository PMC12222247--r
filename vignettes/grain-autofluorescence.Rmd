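---
title: "Multispectral autofluorescence analysis of developing wheat grain sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral autofluorescence analysis of developing wheat grain sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainspectra)
```

## The problem

Autofluorescence of plant cell walls carries compositional information:
phenolic compounds fluoresce blue under UV excitation, chlorophyll red
under blue/green excitation, lignin-related structures green under blue
excitation. Imaged at the macroscale, an entire transverse section of a
wheat grain (several mm²) can be covered at a few µm per pixel, so the
spatial distribution of these signatures across the grain's tissue layers
— pericarp, endocarp, testa, aleurone, starchy endosperm, and the ventral
crease — can be followed along grain development without staining.

The acquisition produces, per section, four RGB images through four
excitation filter cubes (two UV, named U1 and U2, and two visible, Blue
and Green), on a 14-bit camera. A study series covers four developmental
stages (250, 450, 650 and 850 cumulative degree-days after flowering,
°DAF) with ten sections per stage: forty multispectral images, hundreds
of millions of pixels in total. The questions the pipeline answers are:
which spectral contrasts structure this series, where in the tissues do
they sit, and how do they evolve with development?

## The pipeline

### Cube assembly and background correction

Merging the blue/green/red planes of the four filter images, ordered from
high to low emission wavelength, gives 12 channels; the red plane of U1
contains reflection from the excitation Rayleigh band rather than
fluorescence and is dropped, leaving an 11-channel cube (channels U1b,
U1g, U2b, U2g, U2r, BLb, BLg, BLr, GRb, GRg, GRr). The per-pixel row over
these channels is the pixel's *pseudo-spectrum*. Because fluorescence
under visible excitation is weaker than under UV, the BL and GR planes are
multiplied by a single gain before merging; the gain is a configuration
value (`visible_gain`) and the synthetic manifests record the value the
renderer used, so assembly exactly inverts the attenuation.

Three channels (BLb, GRb, GRg) carry no autofluorescence and act as a
baseline in every pseudo-spectrum. The additive, channel-dependent
background is estimated as the mean over a set of signal-free rectangular
regions taken on a few images of the series (three regions on each of
four images by default, one image per stage) and subtracted from every
image. Subtraction clamps at zero — counts are nonnegative and the
downstream sum images and Otsu thresholds assume it.

Two views are derived per image: the *sum-of-intensity* image (sum over
the 11 channels rescaled to 256 gray levels over the image's own range —
the rescale rule is this package's choice, making the fixed gray-level
threshold below meaningful on a 0–255 scale) and the *RGB composite*
(averages of the retained red, green and blue channels, excluding the
baseline channels, clipped to a common 0–11,000 count range and
gamma-corrected with γ = 0.5 so that all sections of a series are
rendered comparably).

### Regions of interest

The whole-section ROI thresholds the sum image at gray level 2 (strictly
above; a per-section override supports the occasional image where the
common value fails), then applies a square-element opening and closing of
reference sizes 51 and 150 px and keeps the largest connected region. The
outer-tissue ROI computes two Otsu thresholds on the section's pixels —
one on the total sum image, one on the sum of the UV-weighted channels
U1b, U1g, U2b, U2g and BLg, which avoids red emission — takes the union
of the two supra-threshold sets, and post-processes with disk elements:
opening of radius 1, dilation of radius 8, opening of radius 12, keeping
the largest region.

Conventions fixed by this package:
"size" means side length for squares and radius for disks; Otsu operates
on an 8-bit requantization of the masked pixels (Otsu needs a bounded
histogram; the masked-subset variant is implemented here and cross-checked
against `EBImage::otsu` on full images); connected components use
4-connectivity (the labeling the imaging library provides — after the
morphological smoothing, candidate blobs are compact and the choice does
not affect which is largest). All reference sizes are given for a
3500-px-wide grid and scale linearly with the working grid width.

The whole-section ROI also measures the section area,
`count · pixel_size² · 10⁻⁶` mm².

### Large PCA

One PCA is fitted over *all* whole-section pixels of the series. Each
image is unfolded into its pixel × 11 table \(X_i\) and contributes three
accumulable statistics: the pixel count \(n_i\), the pseudo-spectrum sum
(its contribution to the global mean \(m\)), and the cross-product matrix
\(X_i'X_i\). After a single pass,

\[ C = \frac{1}{N-1}\Big(\sum_i X_i'X_i - N\,m m'\Big), \]

and the eigendecomposition of \(C\) gives eigenvalues \(\lambda_k\) and
loadings \(L\) common to the whole series; per-pixel scores are
\((x - m)'L_k\), refolded to the image grid. Choices made here: the
covariance uses the \(N-1\) divisor (explained-variance percentages are
divisor-invariant); channels are not standardized (covariance PCA on raw
counts, so component 1 retains its intensity interpretation); per-image
contributions are combined by pairwise summation in double precision;
eigenvector signs are canonicalized by making each column's
largest-magnitude entry negative, which renders the intensity component
all-negative in the conventional presentation — tests compare loadings up
to sign regardless.

Score images are rendered to 8 bits with bounds \(\pm s\sqrt{\lambda_k}\)
derived from the eigenvalues, identical for every image of the series on
a given component. The spread factor \(s = 3\) (≈ 99.7 % of a Gaussian
score spread) is the default and is configurable.

### Score distributions and similarity maps

For each component, all ROI scores of the series are pooled into a fine
histogram of 10,000 linear bins; percentiles 0–100 % in 1 % steps of that
global distribution (interpolated linearly within fine bins, not
re-streamed from raw scores) define ≤ 100 variable-width bins shared by
the whole series. The observed distribution of one image is the relative
frequency of its outer-tissue ROI pixels in those bins — relative rather
than raw counts, so sections of different sizes are comparable, and the
pooled distribution is uniform by construction, which the tests exploit.
Duplicate edges from massive ties are merged; a fully degenerate pool
yields a single bin.

The global percentile pass and the observed distributions use the same
pixel set (the outer-tissue ROI), so the pooled pixel-weighted observed
distribution is uniform at 1 % per bin — the property the conservation
tests check. (Fitting the PCA on whole-section pixels while quantifying
distributions on outer-tissue pixels is intentional: the components are
defined by the whole section, the quantification targets the outer
layers.)

Stage-average distributions are unweighted means over each stage's
sections (grains contributing several sections are not reweighted), and a
standard column-centered PCA of the images × bins frequency matrix gives
the *similarity map*: per-image coordinates whose clustering and ordering
express how score distributions evolve with development.

## The synthetic phantom series

The package generates ground-truthed phantoms with the statistical
structure the analysis assumes, and the tests run the full pipeline
against that ground truth.

The geometry is a dented ellipse (axis ratio 0.72, crease modeled as a
single Gaussian radial infold of fractional depth 0.28 and angular width
0.35 rad) with concentric tissue bands: outer pericarp, endocarp, a thin
testa line, aleurone (differentiating only from 450 °DAF), starchy
endosperm, plus a crease complex treated as one mixed tissue (sub-tissue
resolution is out of scope). The major semi-axis is solved numerically so
the section area matches the stage-typical means the generator is
calibrated to (4.64, 6.56, 7.11, 6.11 mm² for 250–850 °DAF — growth to
650 °DAF, slight shrinkage at maturity); per-section jitter
(±4 % scale, a few pixels of center shift, ±3 % abundance multipliers,
10 % log-normal pixel texture) provides within-stage variability while
keeping stage-level means within 10 %.

Three endmember pseudo-spectra span the contrasts of interest without
claiming chemical accuracy: a chlorophyll-like fluorophore (red emission
under BL/GR, weak red under U2), a hydroxycinnamate-like one (blue/green
emission under the UV filters), and a lignin-like one (green under BL
plus a broad UV contribution). Their stage trajectories follow the
developmental biology of the caryopsis: chlorophyll-like abundance in the endocarp and pericarp
is maximal at 250 °DAF and decays monotonically to near zero at 850;
hydroxycinnamate-like abundance rises to 650 and falls back at 850;
lignin-like signal is absent at 250, confined to dot features (small
discs seeded in the endocarp, and at 650 also the outer pericarp, at
0.5–0.65 % of eligible pixels) at 450–650, and homogeneous over the
pericarp-side outer layers at 850 — the aleurone is excluded from the
lignin-bearing set, as late-stage lignin deposition targets the
pericarp-side layers, not the aleurone.

The forward model is linear mixing plus a per-channel additive
background, additive Gaussian noise (σ = 3 counts by default — camera
read-noise scale; additive Gaussian is the minimal noise model for which
central-limit bounds can be written), rounding, and clipping to the
14-bit range. The U1r plane receives a flat reflection term over the
section instead of fluorescence, so dropping it during assembly is
meaningful. The visible-filter planes are attenuated by `1/visible_gain`
(default 2) before quantization; the attenuation is acquisition-dependent
in practice, so the inverse gain is a recorded manifest value rather than
a constant.

The default working grid is 512 × 384 px with the pixel size enlarged in
proportion (9.84 µm), so the full 40-section series — the problem size
used by the test suite and the reproduction script — runs in about two
minutes while keeping grain dimensions, areas and morphological sizes on
the real physical scale. Full-resolution grids remain reachable through
`phantom_geometry()`.

What the phantoms deliberately do not emulate: optics (point-spread
function, vignetting, spectral bleed), stitching seams, embryo/scutellum
anatomy, non-equatorial sections, or grain-level random effects. Passing
tests therefore demonstrate that the pipeline recovers the structure the
forward model encodes — sharp-edged, linearly mixed, Gaussian-noise data
— not that it is robust to every artefact of real acquisitions.

## Numerical conventions and degenerate inputs

* Background subtraction clamps at zero; zero background is the identity.
* The sum image of an all-zero cube is all zero (no division by a zero
  maximum); a blank sum image segments to an empty mask.
* Otsu on a constant masked region raises a degenerate-input error rather
  than guessing a threshold.
* A score pool with a single distinct value yields a single-bin
  histogram and single-bin distributions rather than an error.
* Percentile refinement is consistent: halving the step produces bins
  whose pairwise merge reproduces the coarser frequencies exactly.
* The streaming PCA equals a dense PCA of the concatenated pixel table to
  1e−8 relative (eigenvalues and sign-aligned loadings); eigenvalue sums
  conserve the covariance trace to 1e−10 relative.
* Cube TIFF storage is 32-bit at a 2^14 scale; the storage quantum is
  2^14/2^32 ≈ 4 × 10⁻⁶ counts, so round trips preserve channel order
  exactly and values to well below photon noise.
* Re-running a configuration with the same seed reproduces every table
  byte-for-byte; there is no incremental resume — regenerating a series
  is cheaper than stage caching at these problem sizes.

## Worked example

```{r example, eval = FALSE}
library(grainspectra)

# a reduced series: two sections per stage
cfg <- default_run_config(seed = 1,
                          design = c(`250` = 2L, `450` = 2L,
                                     `650` = 2L, `850` = 2L))
run <- run_pipeline(cfg)

run$area_by_stage              # section areas, mm^2, per stage
round(run$pca$explained[1:5], 2)  # explained variance, %
plot_loadings(run$pca)
plot_stage_distributions(run$stage_averages$comp1, run$bins$comp1)
plot_similarity_map(run$similarity$comp1)
```

The `analysis/` scripts run the same workflow at the full study design
(4 × 10 sections) and write the tables under `results/`.

## Known limitations

The phantom's sharp tissue boundaries make segmentation easier than on
real sections, where the outer pericarp may detach and stitching
artefacts cross tissue layers; the Jaccard levels reported by the
acceptance script are upper bounds on real-data performance. Component
identity (which PCA axis captures which contrast) is fixture-dependent:
on the default phantoms, component 1 is the intensity axis dominated by
the fading red emission, but on other designs the order can differ, and
interpretation must always go through the loadings. Biological or
chemical attribution of components is out of scope.
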