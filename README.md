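# stonewindow

Reproducible size measurement of dense (calcified) objects — urinary
stones — in non-contrast CT, built around the **half-value window**
principle, with a synthetic phantom simulator, a simulated multi-observer
study, **LOAM** interreader-agreement statistics, and logistic prediction
curves for spontaneous stone passage.

## The problem and the method

A CT display window (center WC, width WW) renders attenuation values
below `WC − WW/2` black and above `WC + WW/2` white. Because the scanner
point-spread function blurs every edge, the apparent size of a dense
object depends on the window: low thresholds make it *bloom* (appear too
large), near-peak thresholds shrink it. For a symmetric point-spread
function the blurred edge profile crosses its **half-amplitude** level at
the true edge, so a window with

```
WC = background + (peak − background) / 2,   WW = 0
```

displays the object at its true size. With the conventional 0 HU
background, `WC = peak/2`; the peak statistic is either the ROI mean of
an inner histogram circle (*half-value MEAN*) or the ROI maximum of an
enclosing circle (*half-value MAX*). The package implements this as a
semi-automated algorithm — seed point in, largest Feret diameter over
axial/coronal/sagittal 3 mm reformations out — plus everything needed to
study it without patient data: ellipsoid phantoms with Gaussian PSF blur
and noise, simulated observers with explicit edge-perception policies,
limits of agreement with the mean (`loam = z·sqrt((1−1/m)(σ²_observer +
σ²_residual))`) under an additive two-way random-effects model with
modified-large-sample CIs, and per-observer logistic passage curves.

Who it is for: researchers studying measurement variability in CT sizing
protocols, and developers prototyping reproducible (semi-automated) stone
measurement before PACS integration.

## Worked example

Measure a blurred 6 mm, 800 HU sphere (1 mm PSF, 0.2 mm voxels) with the
half-value MAX algorithm:

```r
library(stonewindow)

spec <- phantom_spec(semi_axes = c(3, 3, 3), stone_hu = 800,
                     psf_fwhm = 1.0, voxel_spacing = rep(0.2, 3))
ph <- render_phantom(spec, supersample = 2)
half_value_max_semiauto(ph$volume, c(31, 31, 31), slab_thickness = 0.2)
#>           window d_axial_mm d_largest_mm roi_max_hu plane_of_largest
#> 1 half_value_max   5.824088     5.824088        800            axial
```

The algorithm recovers 5.82 mm of the true 6.00 mm (the small deficit is
the curvature bias of half-max thresholding on a 3D ball plus
rasterization); thresholding the same sphere at 100 HU instead yields
6.85 mm (blooming), at 700 HU only 4.87 mm.

Run a full simulated study — 24 phantom stones, five observers with
heterogeneous edge perception, four window settings — and estimate the
interreader variability per window:

```r
demo <- run_demo(study_config(n_stones = 24, seed = 7))
demo
#> <stone_study> 24 stones x 5 observers x 4 windows (456 rows)
#>   LOAM bone             +-0.64 mm (95% CI 0.43-2.16)
#>   LOAM half_value_max   +-0.15 mm (95% CI 0.14-0.20)
#>   LOAM half_value_mean  +-0.18 mm (95% CI 0.16-0.22)
#>   LOAM soft_tissue      +-0.43 mm (95% CI 0.31-1.10)
```

The bone window is the least reproducible and half-value MAX the most —
the ordering bone > soft tissue > half-value MEAN > half-value MAX that
motivates half-value windows in the first place. (One observer's
bone-window arm is excluded by default, emulating a lost study arm, so
bone is analyzed with four observers.) `autoplot(demo)` draws the
per-window multi-observer Bland–Altman panels; `demo$curves` holds the
per-observer passage-prediction curves.

Passage prediction from the packaged synthetic fixture:

```r
fx <- read.csv(system.file("extdata", "passage_fixture.csv",
                           package = "stonewindow"))
fit <- fit_logistic(fx$size_mm, fx$passed)
fit
#> <passage_fit> logit P = 4.64 -1.038 * size_mm (n=20, converged)
size_at_prob(fit, 0.9)  # 2.35 mm at 90% predicted passage
```

A thin CLI over the same functions lives at `inst/cli/stonewindow.R`
(`simulate-cohort`, `measure`, `simulate-study`, `agree`, `curves`,
`run-demo`).

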