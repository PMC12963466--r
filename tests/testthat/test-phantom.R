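test_that("unblurred noiseless phantom is a sampled indicator", {
  spec <- phantom_spec(semi_axes = c(3, 3, 3), stone_hu = 800, psf_fwhm = 0,
                       noise_sd = 0, voxel_spacing = rep(0.5, 3))
  ph <- render_phantom(spec)
  cv <- round(spec$center / 0.5) + 1
  expect_equal(ph$volume$voxels[cv[1], cv[2], cv[3]], 800)
  expect_equal(ph$volume$voxels[1, 1, 1], 0)
  expect_equal(unname(ph$ground_truth), c(6, 6, 6))
})

test_that("rendering errors when the ellipsoid does not fit", {
  spec <- phantom_spec(semi_axes = c(6, 6, 6), psf_fwhm = 1,
                       voxel_spacing = rep(0.5, 3), volume_shape = rep(20, 3))
  expect_error(render_phantom(spec), "bounds error")
})

test_that("blur reduces the peak but conserves mass", {
  peak0 <- NULL
  mass <- c()
  for (f in c(0, 0.5, 1, 2, 2.5)) {
    spec <- phantom_spec(semi_axes = c(3, 2.5, 2), stone_hu = 800,
                         psf_fwhm = f, noise_sd = 0,
                         voxel_spacing = rep(0.4, 3),
                         volume_shape = rep(56, 3))
    v <- render_phantom(spec)$volume$voxels
    if (f == 0) peak0 <- max(v) else expect_lt(max(v), peak0)
    mass <- c(mass, sum(v) * 0.4^3)
  }
  # mass invariant to psf within 0.5%
  expect_lt(max(abs(mass - mass[1])) / mass[1], 0.005)
})

test_that("rendering is bit-identical for identical spec and seed", {
  spec <- phantom_spec(semi_axes = c(2, 2, 2), noise_sd = 20,
                       voxel_spacing = rep(0.5, 3), seed = 99L)
  a <- render_phantom(spec)$volume$voxels
  b <- render_phantom(spec)$volume$voxels
  expect_identical(a, b)
  spec2 <- phantom_spec(semi_axes = c(2, 2, 2), noise_sd = 20,
                        voxel_spacing = rep(0.5, 3), seed = 100L)
  expect_false(identical(a, render_phantom(spec2)$volume$voxels))
})

test_that("1D profile: no blur means ideal; blur preserves area and max", {
  spec0 <- phantom_spec(semi_axes = c(3, 3, 3), stone_hu = 1000, psf_fwhm = 0,
                        voxel_spacing = rep(0.25, 3))
  p0 <- profile_1d(spec0, n_samples = 501)
  expect_equal(p0$blurred_hu, p0$ideal_hu)
  for (f in c(0.5, 1, 2, 3)) {
    spec <- phantom_spec(semi_axes = c(3, 3, 3), stone_hu = 1000, psf_fwhm = f,
                         voxel_spacing = rep(0.25, 3))
    p <- profile_1d(spec, n_samples = 2001)
    expect_lte(max(p$blurred_hu), max(p$ideal_hu))
    h <- diff(p$position_mm[1:2])
    expect_equal(sum(p$blurred_hu) * h, sum(p$ideal_hu) * h, tolerance = 1e-3)
  }
})

test_that("blurred 1D profile crosses half-amplitude at the true edge for any psf", {
  for (f in c(0.3, 0.8, 1.5, 2.4, 3.0)) {
    spec <- phantom_spec(semi_axes = c(3, 3, 3), stone_hu = 1000, psf_fwhm = f,
                         voxel_spacing = rep(0.25, 3))
    p <- profile_1d(spec, n_samples = 4001)
    h <- diff(p$position_mm[1:2])
    above <- p$position_mm[p$blurred_hu >= 500]
    expect_equal(min(above), -3, tolerance = 2 * h)
    expect_equal(max(above), 3, tolerance = 2 * h)
    # and the closed form agrees with a brute-force numeric convolution
    xs <- c(-3.4, -3, -2.1, 0, 2.9, 3.2)
    num <- 1000 * tophat_blur_numeric(xs, 3, f / (2 * sqrt(2 * log(2))))
    got <- approx(p$position_mm, p$blurred_hu, xs)$y
    expect_equal(got, num, tolerance = 1)
  }
})

test_that("mpr slabs average voxels in half-open intervals", {
  vox <- array(0, c(8, 8, 8))
  vox[, , 5] <- 100
  vol <- ct_volume(vox, spacing = c(1, 1, 1))
  # native-thickness slab equals the voxel plane
  sl <- mpr_slab(vol, "axial", slab_thickness = 1, slab_index = 5)
  expect_equal(sl$slice, vox[, , 5])
  # a 2 mm slab over planes 5 and 6 averages them
  sl2 <- mpr_slab(vol, "axial", slab_thickness = 2, slab_index = 3)
  expect_equal(unique(as.vector(sl2$slice)), 50)
  # uniform volume: every slab is the uniform value in every plane
  u <- ct_volume(array(7, c(6, 5, 4)), spacing = c(0.5, 0.6, 0.7))
  for (pl in c("axial", "coronal", "sagittal")) {
    expect_equal(unique(as.vector(mpr_slab(u, pl, 1.1, 1)$slice)), 7)
  }
  expect_error(mpr_slab(vol, "axial", slab_thickness = 1, slab_index = 99),
               "empty slab")
})

test_that("thick slabs through a small sphere lose peak intensity", {
  spec <- phantom_spec(semi_axes = c(1, 1, 1), stone_hu = 800, psf_fwhm = 0.5,
                       noise_sd = 0, voxel_spacing = rep(0.25, 3),
                       volume_shape = rep(41, 3))
  vol <- render_phantom(spec)$volume
  thin_peak <- max(mpr_slab(vol, "axial", 0.25, 21)$slice)
  # brute-force 3 mm averaging around the center
  thick <- mpr_slab(vol, "axial", 3, 2)$slice
  expect_lt(max(thick), thin_peak)
})

test_that("slab_stack agrees with mpr_slab at every index", {
  ph <- coarse_phantom()
  for (pl in c("axial", "coronal", "sagittal")) {
    st <- stonewindow:::slab_stack(ph$volume, pl, 3)
    for (i in seq_len(dim(st)[3])) {
      expect_equal(st[, , i], mpr_slab(ph$volume, pl, 3, i)$slice)
    }
  }
})

test_that("cohort generation is reproducible, truncated and well-formed", {
  expect_error(make_cohort(0), ">= 1")
  c1 <- make_cohort(5, seed = 11)
  c2 <- make_cohort(5, seed = 11)
  expect_identical(c1$true_diameter_mm, c2$true_diameter_mm)
  expect_identical(c1$spec[[3]], c2$spec[[3]])
  big <- make_cohort(400, seed = 4)
  expect_gte(min(big$true_diameter_mm), 2.0)
  expect_true(all(big$passed %in% 0:1))
  # per-axis ground truth: largest diameter equals 2 * max semi-axis
  expect_equal(2 * max(c1$spec[[1]]$semi_axes), c1$true_diameter_mm[1])
})

test_that("with zero passage slope the event rate matches the intercept", {
  co <- make_cohort(2000, passage_intercept = qlogis(0.4), passage_slope = 0,
                    seed = 8)
  rate <- mean(co$passed)
  se <- sqrt(0.4 * 0.6 / 2000)
  expect_lt(abs(rate - 0.4), 4 * se)
})
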