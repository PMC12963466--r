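test_that("circle_stats matches a brute-force pixel scan", {
  set.seed(31)
  slice <- matrix(runif(30 * 25, -100, 900), 30, 25)
  spacing <- c(0.4, 0.55)
  for (k in 1:6) {
    center <- c(runif(1, 2, 9), runif(1, 2, 9))
    radius <- runif(1, 0.8, 4)
    roi <- roi_circle(center, radius)
    got <- circle_stats(slice, spacing, roi)
    want <- circle_stats_brute(slice, spacing, center, radius)
    expect_equal(got$mean, want$mean)
    expect_equal(got$max, want$max)
    expect_equal(got$n_pixels, want$n_pixels)
  }
})

test_that("circle_stats on a uniform slice returns the constant", {
  slice <- matrix(42, 20, 20)
  s <- circle_stats(slice, c(0.5, 0.5), roi_circle(c(4, 4), 2))
  expect_equal(s$mean, 42)
  expect_equal(s$max, 42)
  expect_gt(s$n_pixels, 0)
})

test_that("a circle catching no pixel center errors", {
  slice <- matrix(1, 10, 10)
  # centered between pixel centers with radius below half the spacing
  expect_error(circle_stats(slice, c(1, 1), roi_circle(c(2.5, 2.5), 0.2)),
               "empty circle")
})

test_that("inner ROI fills a disk minus the erosion margin", {
  # 0.5 mm pixels, disk of radius 5 mm of supra-threshold values
  n <- 41; spacing <- c(0.5, 0.5)
  cx <- (n - 1) / 2 * 0.5
  d2 <- outer(((seq_len(n) - 1) * 0.5 - cx)^2, ((seq_len(n) - 1) * 0.5 - cx)^2, "+")
  slice <- ifelse(d2 <= 5^2, 600, 0)
  roi <- fit_inner_roi(slice, spacing, c(21, 21))
  # largest inscribed circle after a one-pixel erosion: radius 5 - ~1 px
  expect_equal(roi$radius, 5 - 0.5, tolerance = 0.55)
  expect_equal(roi$center, c(cx, cx), tolerance = 0.1)
  # enclosing ROI: disk radius plus a one-pixel margin
  roi2 <- fit_enclosing_roi(slice, spacing, c(21, 21))
  expect_equal(roi2$radius, 5 + 0.5, tolerance = 0.55)
  # enclosing max >= inner max on the same object
  s1 <- circle_stats(slice, spacing, roi)
  s2 <- circle_stats(slice, spacing, roi2)
  expect_gte(s2$max, s1$max)
})

test_that("degenerate two-pixel objects fall back to the brightest pixel", {
  slice <- matrix(0, 15, 15)
  slice[7, 7] <- 500; slice[7, 8] <- 400
  roi <- fit_inner_roi(slice, c(1, 1), c(7, 7))
  s <- circle_stats(slice, c(1, 1), roi)
  expect_equal(s$n_pixels, 1)
  expect_equal(s$max, 500)
})

test_that("a background seed is rejected", {
  slice <- matrix(0, 15, 15)
  slice[7, 7] <- 500
  expect_error(fit_inner_roi(slice, c(1, 1), c(2, 2)), "not a stone")
  expect_error(fit_enclosing_roi(slice, c(1, 1), c(2, 2)), "not a stone")
})

test_that("threshold_mask keeps only the seed component and handles extremes", {
  slice <- matrix(0, 20, 20)
  slice[3:5, 3:5] <- 800    # stone A
  slice[14:16, 14:16] <- 700 # distractor B
  m <- threshold_mask(slice, threshold = 500, seed_px = c(4, 4))
  expect_equal(sum(m), 9)
  expect_true(all(which(m, arr.ind = TRUE)[, 1] %in% 3:5))
  # center above the slice max: empty mask, not an error
  m2 <- threshold_mask(slice, window = window_setting(1000, 0), seed_px = c(4, 4))
  expect_equal(sum(m2), 0)
  # center below the slice min: the full slice is one component
  m3 <- threshold_mask(slice, window = window_setting(-10, 0), seed_px = c(4, 4))
  expect_equal(sum(m3), 400)
})

test_that("zero-width threshold mask area approximates the half-max disk", {
  ph <- fig1_sphere()
  cv <- ph$center_vox
  sl <- mpr_slab(ph$volume, "axial", 0.2, cv[3])
  mask <- threshold_mask(sl$slice, threshold = max(sl$slice) / 2,
                         seed_px = cv[1:2])
  area <- sum(mask) * prod(sl$spacing)
  expect_equal(area, pi * 3^2, tolerance = 0.05 * pi * 9)
})

test_that("max Feret diameter equals exhaustive all-pairs on assorted masks", {
  # two pixels 10 apart along x at 0.5 mm spacing -> 5 mm
  m <- matrix(FALSE, 20, 20)
  m[3, 4] <- TRUE; m[13, 4] <- TRUE
  expect_equal(max_feret_diameter(m, c(0.5, 0.5)), 5)
  # empty and single-pixel masks -> 0 by convention
  expect_equal(max_feret_diameter(m & FALSE, c(0.5, 0.5)), 0)
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  expect_equal(max_feret_diameter(m1, c(0.5, 0.5)), 0)
  # random blobs vs the oracle
  set.seed(77)
  for (k in 1:12) {
    nr <- sample(5:40, 1); nc <- sample(5:40, 1)
    mask <- matrix(runif(nr * nc) < 0.25, nr, nc)
    if (!any(mask)) mask[2, 2] <- TRUE
    sp <- runif(2, 0.2, 1.2)
    expect_equal(max_feret_diameter(mask, sp), feret_all_pairs(mask, sp))
  }
})

test_that("Feret of a rasterized disk is close to its true diameter", {
  n <- 81; spacing <- c(0.25, 0.25)
  cx <- (n - 1) / 2 * 0.25
  d2 <- outer(((seq_len(n) - 1) * 0.25 - cx)^2, ((seq_len(n) - 1) * 0.25 - cx)^2, "+")
  mask <- d2 <= 7^2
  expect_equal(max_feret_diameter(mask, spacing), 14,
               tolerance = sqrt(2) * 0.25)
})

test_that("Feret is robust to rotation of a rasterized ellipse", {
  n <- 101; spacing <- c(0.2, 0.2)
  cx <- (n - 1) / 2 * 0.2
  xs <- (seq_len(n) - 1) * 0.2 - cx
  base <- NULL
  for (th in c(0, 30, 63) * pi / 180) {
    u <- outer(xs * cos(th), xs * sin(th), "+")
    v <- outer(-xs * sin(th), xs * cos(th), "+")
    mask <- (u / 6)^2 + (v / 3)^2 <= 1
    d <- max_feret_diameter(mask, spacing)
    if (is.null(base)) base <- d
    expect_equal(d, base, tolerance = sqrt(2) * 0.2)
  }
  expect_equal(base, 12, tolerance = sqrt(2) * 0.2)
})

test_that("half-value MAX measurement recovers a blurred sphere's diameter", {
  ph <- fig1_sphere()
  m <- half_value_max_semiauto(ph$volume, ph$center_vox, slab_thickness = 0.2)
  expect_equal(m$d_largest_mm, 6.0, tolerance = 0.2)
  expect_equal(m$d_axial_mm, m$d_coronal_mm)
  expect_equal(m$d_largest_mm, max(m$d_axial_mm, m$d_coronal_mm, m$d_sagittal_mm))
  expect_gte(m$roi_max_hu, m$roi_mean_hu)
})

test_that("low thresholds bloom and high thresholds shrink the sphere", {
  ph <- fig1_sphere()
  cv <- ph$center_vox
  bloom <- measure_stone(ph$volume, cv, "soft_tissue", slab_thickness = 0.2,
                         policy = perception_policy("absolute", threshold_hu = 100))
  shrink <- measure_stone(ph$volume, cv, "soft_tissue", slab_thickness = 0.2,
                          policy = perception_policy("absolute", threshold_hu = 700))
  half <- half_value_max_semiauto(ph$volume, cv, slab_thickness = 0.2)
  expect_gt(bloom$d_largest_mm, 6.0)
  expect_lt(shrink$d_largest_mm, 6.0)
  expect_gt(bloom$d_largest_mm, half$d_largest_mm)
  expect_lt(shrink$d_largest_mm, half$d_largest_mm)
})

test_that("raising a zero-width threshold never grows the Feret diameter", {
  ph <- fig1_sphere()
  cv <- ph$center_vox
  sl <- mpr_slab(ph$volume, "axial", 0.2, cv[3])
  prev <- Inf
  for (thr in seq(100, 700, by = 100)) {
    mask <- threshold_mask(sl$slice, threshold = thr, seed_px = cv[1:2])
    d <- max_feret_diameter(mask, sl$spacing)
    expect_lte(d, prev)
    prev <- d
  }
})

test_that("the measurement is deterministic and seed-position independent", {
  ph <- coarse_phantom()
  cv <- ph$center_vox
  m1 <- half_value_max_semiauto(ph$volume, cv)
  m2 <- half_value_max_semiauto(ph$volume, cv)
  expect_identical(m1, m2)
  # a different interior seed gives the identical measurement
  m3 <- half_value_max_semiauto(ph$volume, cv + c(2, -1, 1))
  expect_equal(m1$d_largest_mm, m3$d_largest_mm)
  # background seed errors
  expect_error(half_value_max_semiauto(ph$volume, c(1, 1, 1)), "not a stone")
})

test_that("per-plane diameters track the anisotropic ground truth", {
  spec <- phantom_spec(semi_axes = c(4, 3, 2.4), stone_hu = 800,
                       psf_fwhm = 0.8, noise_sd = 0,
                       voxel_spacing = rep(0.3, 3))
  ph <- render_phantom(spec)
  cv <- round(spec$center / 0.3) + 1
  m <- half_value_max_semiauto(ph$volume, cv, slab_thickness = 0.3)
  # axial plane sees the (x, y) extents: largest in-plane diameter 8 mm
  expect_equal(m$d_axial_mm, 8, tolerance = 0.45)
  expect_equal(m$d_sagittal_mm, 6, tolerance = 0.45) # (y, z): max 6 mm
  expect_equal(m$d_largest_mm, 8, tolerance = 0.45)
  expect_equal(m$plane_of_largest, "axial")
})
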