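---
title: "Quantifying spine-resident fluorescence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spine-resident fluorescence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinequant)
```

## The measurement model

A two-photon/confocal plane of phalloidin-stained cortex contains
thousands of spine-sized bright puncta, plus brighter and much larger
structures (somata, main dendritic branches) that must be excluded, all
over a flat detector pedestal. `spinequant` quantifies a spine-resident
green signal (EGFP-CapZ) relative to the red spine marker in fixed
5-pixel ROIs:

1. the red channel is smoothed with the 3×3 binomial Gaussian kernel
   `[1 2 1; 2 4 2; 1 2 1]/16` (reflective borders);
2. pixels above the 90th percentile of the smoothed image are segmented
   by marker-controlled watershed (each local maximum floods a basin);
3. segments with area outside [3, 200] px are discarded — this single
   area band is what rejects somata/shafts (too large) and noise specks
   (too small);
4. each retained segment yields one round ROI of 5 px diameter — the 13
   integer offsets within Euclidean distance 2 — centered on the
   segment's brightest smoothed pixel (ties: smallest row, then column;
   ROIs that would cross the border are dropped, overlapping ROIs are
   allowed);
5. per-channel ROI means are taken on the **raw** data; smoothing only
   defines geometry;
6. the background per channel is the lesser of the two modal pixel
   values of the paired hemisphere images (integer-binned histogram,
   smallest value on ties), and the corrected intensity is
   `c = (mean_green − bg_green)/(mean_red − bg_red)`. ROIs with a
   non-positive red denominator are excluded and counted. Subtracting
   the background in *both* channels before the ratio is what makes `c`
   invariant under a uniform attenuation of both channels — the property
   that makes the metric robust to focal depth;
7. per animal, `cn = 100 · c / max(c)` over all four images (two per
   hemisphere), so the maximum-bearing ROI is exactly 100 and
   distributions are comparable across animals.

Downstream statistics are per-hemisphere cn histograms (counts averaged
over images within animal, then across animals), the per-bin
`(contra − ipsi)/ipsi` difference ratio (bins with zero ipsi mean are
undefined, reported `NA`), the integrated top-N cn per image averaged
per hemisphere (N = 100 default; ties at the cutoff are included
deterministically by roi id), per-animal contra/ipsi ratios, a two-sided
paired t-test within cohorts and an unpaired Student's t-test between
group ratio sets, all at α = 0.05 — matching the field's usage for this
design.

## The synthetic data and what it does (not) emulate

`generate_field()` renders: isotropic Gaussian puncta (σ = 1 px,
truncated at 4σ) with log-normal peak amplitudes (median 1000 DN, log-sd
0.6) over a 100 DN pedestal on 256×256 px at 0.103 µm/px; a green
channel whose per-spine amplitude is the red amplitude times a CapZ
factor drawn from a two-component log-normal mixture (bright component
probability 0.25, medians 1.0 vs 0.2, log-sd 0.3 — bright-detectable
CapZ in about a quarter of spines); two full-width shaft stripes
(width 3 px, +800 DN) and one soma disc (r = 15 px, +1600 DN) present in
all channels; Poisson shot noise on the photon signal, Gaussian read
noise (sd 3 DN) on everything, quantized to 16-bit integers. The
pedestal is modeled as an electronic offset — it carries read noise but
no shot noise — which is also what makes the image mode exactly equal
the pedestal when read noise is off.

Spines are placed as a hard-core process: minimum center separation
4 px (~0.4 µm, the physical size of a spine head) and 4 px clearance
from the structure masks. Spine heads are discrete objects that cannot
interpenetrate, and the somata/branch structures stand for the regions
the ROI selection is meant to exclude, not for spine carriers.

The lateralized effect (`effect_spec`) converts, per effect-side image,
`n_extra_bright` randomly chosen dim spines to bright by multiplying
their CapZ factor by `bright_gain` (defaults 50 and 3). Conversion
rather than addition keeps the phalloidin-defined spine count balanced
between hemispheres, as observed in the tissue this emulates. An `add`
mode is available.

The optional third channel models an α-actinin immunolabel with
per-spine amplitude `0.5 · red_amp · (1 + coupling · z)`, `z` the CapZ
factor scaled to the field maximum. Scaling by the red amplitude encodes
that α-actinin, an actin crosslinker, tracks the spine's actin content;
with zero coupling the actinin c-intensity is then independent of CapZ
rank and the colocalization ratio is centered on 100%. (With a
red-independent actinin amplitude the c-intensity becomes proportional
to the reciprocal red amplitude — heavy-tailed and correlated with
rank-selection noise — and the independence null no longer holds at the
percent level; that model variant is deliberately not used.)

Not emulated: sub-pixel spine positions and shape variation (centers are
integer pixels; real puncta are anisotropic), optics-accurate PSFs,
3D stacks (single planes only, matching the analysis), spatially varying
background or vignetting, bleaching within a series, and true biological
variance between animals beyond sampling variation. Passing tests
therefore show the *procedure* is correct and calibrated under this
generative model, not that any particular biological dataset will behave
identically.

## Numerical and design choices

- **Watershed flavor.** Seeded watershed on the thresholded smoothed
  image via `EBImage::watershed`, with a merge tolerance expressed as a
  fraction (default 0.4) of the seeding threshold: basins whose maxima
  rise less than that above the separating ridge are merged. The
  relative form keeps segmentation exactly invariant under uniform
  intensity rescaling; the value is ~3× the smoothed shot-noise sd on
  the brightest structures, so noise cannot fragment a shaft into
  punctum-sized pieces, while real puncta (which rise far above their
  saddles) are unaffected.
- **Center from the smoothed image.** The ROI center is the brightest
  *smoothed* pixel of a segment; raw data is used only for intensity.
  Smoothing suppresses single-pixel noise maxima.
- **Background pairing.** With two images per hemisphere, images are
  paired across hemispheres by acquisition index and each pair shares
  the lesser-mode background.
- **Focal series.** ROIs are detected on the reference plane and
  re-measured as fixed masks at depth (`focal_series_tables`);
  re-detecting per plane injects a depth-dependent max-selection bias on
  the red channel. The background is likewise estimated once on the
  reference plane: the pedestal does not change with depth, and
  per-plane integer-mode estimates jitter by ±1 DN, which would add
  coherent step effects. The repeated-measures ANOVA runs on relative
  values of steps 1..K−1 (step 0 is the reference, identically 1 with
  zero variance, and would degenerate the model).
- **Region ratio.** The slice generator mirrors punctum layout and
  amplitude draws between the high-gain and neighbor regions and samples
  both with the same translated 4-square ROI layout, so the expected
  ratio equals the planted gain exactly; the reference (background)
  region is punctum-free. Identical high/neighbor/background intensities
  would make the denominator zero; that case errors rather than
  returning a value, per the non-positive-denominator rule.
- **Degenerate inputs.** Empty label maps warn and return zero
  segments; an all-excluded image errors with its id; `top_n_sum` with
  `n` above the ROI count errors with the counts; division guards return
  `NA` (histogram bins) or errors (ratios) as documented.
- **Monte-Carlo calibration path.** Cohort-level power/type-I
  calibrations and the colocalization calibration run on a table-level
  simulator (`simulate_roi_table`) that draws ROI measurements from the
  same generative model — identical amplitude and mixture draws, the
  analytic 13-pixel mask gain `psf_mask_gain`, and the matching
  shot/read noise on ROI means — without rendering pixels. Detection
  fidelity is validated separately on rendered fields, and a test pins
  the image-path and table-path effect sizes to each other. Problem
  sizes used by the tests and acceptance script: 256×256 fields with 250
  spines for detection; 128×128/60-spine series × 200 replicates for
  focal stability; 8-animal cohorts × 200 (power) and 1000 (null)
  replicates; 5000-ROI images × 200 replicates for colocalization.

## Known limitations

- The 90th-percentile seeding threshold ties detection to the fraction
  of the field covered by signal; fields much sparser than the defaults
  push the threshold into the noise floor (spurious specks), much denser
  fields cut into the dim amplitude tail. The area band and percentile
  are configurable per dataset.
- The mode-based background assumes the pedestal is the most frequent
  value; images dominated by structure would need a different estimator.
- cn-normalization divides by a single extreme ROI per animal; with
  very heavy-tailed brightness distributions this adds animal-level
  scale variance to all normalized statistics (the paired design
  absorbs it, but confidence intervals on pooled cn values should be
  read with care).
- The paired t-test is exact under normality of per-animal differences;
  the calibration shown by the tests is for the default generator, not
  a guarantee for arbitrary parameter settings.
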