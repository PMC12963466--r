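---
title: "Half-value window measurement of dense objects in CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-value window measurement of dense objects in CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stonewindow)
```

## The measurement problem

The size of a calcified object in non-contrast CT depends on how it is
displayed. A CT display window maps attenuation (Hounsfield units, HU) to
gray: values below the lower gray level `WC - WW/2` render black, values
above the upper level `WC + WW/2` render white, with a linear ramp in
between. A scanner does not image a dense object as a sharp step: the
point-spread function (PSF) smears the edge over roughly its own width.
When such a blurred object is displayed in a wide, low window (e.g. soft
tissue, WC 50 / WW 400), gray values far below the object's plateau still
render bright, so the visible blob extends beyond the true edge — the
*blooming* artifact. Conversely, tracing the border where the display is
nearly saturated (close to the object's peak) cuts inside the true edge.

For a symmetric PSF there is one threshold that is exactly right: half of
the object-to-background attenuation difference. A blurred 1D step crosses
its half-amplitude level exactly at the position of the original edge,
independent of the PSF width. The *half-value window* operationalizes this
as a display setting: window center at `background + (peak - background)/2`
and window width 0, so the white set of the display is exactly the
supra-half-maximum set. With the conventional predefined background of
0 HU, the center is simply half the object's peak statistic. Two variants
differ in the peak statistic: the ROI mean of an inner circle
(*half-value MEAN*) or the ROI maximum of an enclosing circle
(*half-value MAX*).

## The measurement protocol

`measure_stone()` implements the protocol end to end:

1. For each reformation plane (axial, coronal, sagittal), build the stack
   of MPR slabs (default 3 mm, mean-intensity projection, half-open
   intervals tiling the axis from the first voxel boundary) and select the
   slab where the stone appears largest in the soft-tissue window
   (maximum supra-upper-level area; ties break to the lowest slab index).
   "Perceived as largest" is a human judgment; maximal saturated area is
   our deterministic operationalization.
2. Place the histogram-circle ROI at the centroid of the apparent stone:
   the largest circle inside the one-pixel-eroded apparent region for the
   MEAN statistic (the erosion is the "stay inside the border" margin that
   avoids partial-volume contamination), or the smallest centroid-centered
   circle containing the region plus a one-pixel margin for MAX. ROI
   statistics are computed on raw HU of the slab, not on windowed values.
3. Derive the half-value window from the ROI statistic and threshold the
   slab at its center; for soft-tissue and bone windows, threshold at the
   perception-policy level instead (below). Only the connected component
   containing the seed is retained.
4. Report the maximum Feret diameter (largest pairwise distance between
   boundary-pixel centers) per plane, and the maximum over the three
   planes as the measurement.

The only user input is a seed voxel inside the stone, which is what makes
the half-value MAX variant suitable for semi-automated use: the enclosing
ROI, its maximum, and the derived window depend only on the stone's
connected component, so any interior seed yields the identical result
(this is asserted by tests).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `slab_thickness` | 3 mm | MPR slab; the clinical reconstruction. Thick slabs average the object with its surroundings through-plane; a 6 mm sphere measured in a 3 mm slab loses ~0.3–0.4 mm of half-max diameter. Fine-grid recovery checks therefore use native-spacing slabs. |
| `background_hu` | 0 HU | Predefined background for the half-value arithmetic (peri-ureteral fat/soft tissue approximation). Configurable for objects on denser backgrounds. |
| `psf_fwhm` | 0.9 mm | Isotropic Gaussian PSF FWHM (`FWHM = 2*sqrt(2*log 2)*sigma`). Real scanners and kernels differ; only the symmetry of the blur matters for the half-value argument. |
| `edge_fraction` | 0.3–0.7 across observers | Where within the displayed contrast an observer perceives the border in nonzero-width windows. |
| `roi_max_quantile` | 1 | The MAX statistic is the true ROI maximum, which is noise-sensitive; a percentile alternative (e.g. 0.99) is available. |

Zoom level is display-only and has no computational counterpart here.

## Numerical choices

* **Width-0 display convention.** At `WW = 0` a value exactly equal to the
  center displays white (`>=`, closed set). This makes the supra-threshold
  region closed so a voxel at exactly half-maximum counts as stone, and
  segmentation is bit-reproducible. Whether a PACS renders the boundary
  value black or white at zero width is unspecified in practice; `>=` is
  this package's choice.
* **Display range.** Windowed values live in [0, 1]; 8-bit export is an
  I/O concern only.
* **Phantom rendering.** The ellipsoid indicator is sampled on a
  supersampled subgrid (default factor 3), convolved with the Gaussian
  PSF, and block-averaged to voxel resolution. Because box (voxel) and
  Gaussian convolution commute, the blur runs on the down-averaged grid
  whenever `sigma >= 0.8 *` voxel spacing — identical result, much
  cheaper. The kernel is a normalized sampled Gaussian truncated at
  4 sigma, so integrated attenuation is conserved to machine precision for
  interior objects (tested at < 0.5%).
* **Half-max edge recovery in 1D vs 3D.** The half-amplitude crossing
  recovers the edge *exactly* only for the 1D profile. For a 3D ball the
  isotropic blur mixes in the curved neighborhood and the half-peak
  crossing sits inside the true edge by approximately `sigma^2 / r`
  (about 0.06 mm per edge for a 3 mm radius at FWHM 1 mm, growing to
  ~0.4 mm at FWHM equal to the radius). Tests assert the exact property on
  1D profiles and the quantified approximation in 3D.
* **Feret diameter.** Computed between boundary-pixel centers without the
  +1-pixel augmentation some packages apply; the rasterization error is
  bounded by one pixel diagonal and tested against exhaustive all-pairs
  enumeration. A single-pixel mask reports 0 by convention.
* **Circle membership.** Strict (`<`): boundary pixel centers are
  excluded, and a circle catching no pixel center is an error.
* **Ties and degeneracies.** Slab ties break to the lowest index;
  apparent stones of two pixels or fewer fall back to a one-pixel ROI at
  the brightest pixel; an empty threshold mask is a zero-size result (the
  stone is invisible in that window), not an error. Stones too faint to
  saturate the soft-tissue display after slab averaging use half their
  apparent peak as the apparent-region threshold.

## The simulated observer model

Human readers differ mainly in where they place the border when it is a
gray ramp. Each `observer_profile()` has a fixed `edge_fraction` plus
per-reading caliper jitter (per-plane, truncated at zero) and
histogram-circle placement jitter. Half-value modes ignore the edge
fraction entirely — their threshold is algorithmic — which is the
mechanistic reason their interreader variability is smallest.

The default perception policy is *display-contrast-relative*: the
perceived border sits at a fixed fraction of the object's displayed
contrast above the background's display value. This encodes the gray-level
explanation of bone-window variability: a stone peaking near 857 HU never
saturates under the bone window's 860 HU upper level, so its border is an
ill-defined ramp spanning the full attenuation range and observer
thresholds spread over the whole profile; under the soft-tissue window the
stone saturates and plausible borders are confined to the narrow
sub-saturation band. A simpler policy (threshold at a fixed fraction of
the window width above the lower gray level) is available as
`perception_policy("window")`; in our calibration experiments it makes
bone- and soft-tissue-window spread nearly equal, because the wide
window's larger HU spread is cancelled by the shallower profile slope at
low soft-tissue thresholds, and it therefore cannot reproduce the
clinically observed variability ordering.

Observer trait defaults (edge fractions 0.3–0.7, caliper SD 0.1 mm, ROI
placement SD 0.3 mm) are *calibration choices*, tuned once so the
simulated study reproduces the qualitative ordering of interreader
variability (bone > soft tissue > half-value MEAN > half-value MAX); they
are not measured human parameters, and the simulation validates the
method, not the clinical magnitudes.

## The synthetic cohort

`make_cohort()` emulates a proximal ureteral stone cohort: lognormal
largest diameters (mean ≈ 5 mm, truncated below at the 2.0 mm inclusion
floor), mildly anisotropic ellipsoids with a random major axis, stone
attenuation normal with mean 940 HU (chosen so the *measured* mean
maximum attenuation on 3 mm slabs lands near the ~857 HU typical of such
cohorts), white HU noise of 10 HU, 0.45 mm isotropic voxels, and a
logistic size–passage truth (intercept 5.24, slope −0.95 per mm, giving
~55% passage overall and ~90% passage near 3.2 mm). These are emulation
choices, not study-derived distributions; no real patient data enters the
package. What passing tests show is that the estimators and the
measurement algorithm behave correctly under this generative model — they
do not certify performance on real CT, where stone morphology, textured
backgrounds, non-Gaussian reconstruction kernels and correlated noise all
depart from the phantom.

## Agreement statistics

The limits of agreement with the mean (LOAM) quantify how far a single
observer's measurement may deviate from the all-observer mean for a
subject, under the additive two-way random-effects model
`y_ij = mu + subject_i + observer_j + e_ij`. The deviation
`y_ij - mean_j(y_ij)` has variance `(1 - 1/m)(var_observer +
var_residual)`, so `loam = z * sqrt((1 - 1/m)(var_observer +
var_residual))`. Balanced tables use closed-form ANOVA moment estimators
(negative estimates truncated at zero with a warning); unbalanced tables
use REML via lme4. For the 95% CI we use a Graybill–Wang
modified-large-sample interval on the variance sum: in coverage
simulations at the study design size (n = 124 subjects, m = 5 observers)
it holds ~95% coverage, whereas a plain Satterthwaite chi-square interval
undercovers badly (~84%) because the observer mean square has only
4 degrees of freedom. A parametric bootstrap is available via
`ci_method = "bootstrap"` and is the automatic choice for unbalanced
tables. The exact interval construction behind published LOAM CIs is
generally not stated; we validate ours by simulated coverage rather than
formula identity.

## Passage prediction

`fit_logistic()` fits `logit P(pass) = b0 + b1 * size` by plain maximum
likelihood (no penalization); complete separation is detected and
surfaced (`status = "separation"`), never silently corrected, since
penalization would change the interpretation of the curves.
`curve_family()` fits one curve per observer × window and evaluates them
on a common grid; because windows differ systematically in measured size,
the curve families shift horizontally — the half-value windows' smaller
sizes shift their curves left relative to soft tissue, and tighter
interreader agreement shows as tighter curve bundles.

## Problem sizes

The shipped demonstration (`run_demo()`, also used by the acceptance
script) uses 60 stones × 5 observers × 4 windows; the test suite uses
24–36 stones for the end-to-end checks, 500 replicates for LOAM coverage,
and a 0.2 mm-voxel sphere for fine-grid recovery. These sizes were chosen
as the smallest that leave the Monte-Carlo checks comfortably away from
their tolerances.

## Known limitations

* Ellipsoid phantoms with analytic ground truth, not realistic stone
  morphology; uniform background, no anatomy, no beam hardening or
  spectral effects, no scanner-specific kernels.
* The observer model is mechanistic; it supports method validation and
  designed parameter-recovery experiments, not re-derivation of clinical
  interreader values.
* Measurements are in-plane Feret diameters on three orthogonal planes;
  free-angle 3D diameters are out of scope, as is automatic stone
  detection (the seed point is user input).
* The ANOVA/MLS interval assumes the additive model with homoscedastic
  normal effects; proportional (multiplicative) disagreement calls for a
  different model.
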