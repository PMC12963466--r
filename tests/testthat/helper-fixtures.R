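# Shared phantoms, rendered lazily once per test run.
.fixture_env <- new.env(parent = emptyenv())

# the canonical fine-grid sphere: 6 mm, 800 HU, psf 1 mm, 0.2 mm voxels
fig1_sphere <- function() {
  if (is.null(.fixture_env$fig1)) {
    spec <- phantom_spec(semi_axes = c(3, 3, 3), stone_hu = 800,
                         background_hu = 0, psf_fwhm = 1.0, noise_sd = 0,
                         voxel_spacing = rep(0.2, 3))
    .fixture_env$fig1 <- c(render_phantom(spec, supersample = 2),
                           list(spec = spec,
                                center_vox = round(spec$center / 0.2) + 1))
  }
  .fixture_env$fig1
}

# a small anisotropic phantom at coarse spacing for cheap unit tests
coarse_phantom <- function() {
  if (is.null(.fixture_env$coarse)) {
    spec <- phantom_spec(semi_axes = c(2.5, 2.2, 2.0), stone_hu = 900,
                         psf_fwhm = 0.9, noise_sd = 0,
                         voxel_spacing = rep(0.45, 3))
    .fixture_env$coarse <- c(render_phantom(spec),
                             list(spec = spec,
                                  center_vox = round(spec$center / 0.45) + 1))
  }
  .fixture_env$coarse
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "stonewindow")
  if (nzchar(p)) p else testthat::test_path("..", "..", "inst", "extdata", file)
}
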