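#' Specify a synthetic stone phantom
#'
#' Ground truth is an axis-aligned ellipsoid of uniform attenuation on a
#' uniform background. Rendering convolves the ellipsoid indicator with an
#' isotropic Gaussian point-spread function (PSF) parameterized by its
#' full width at half maximum (`FWHM = 2 * sqrt(2 * log(2)) * sigma`),
#' which is what produces blooming/partial-volume behavior at the edge,
#' then samples at voxel centers and optionally adds white HU noise.
#'
#' @param semi_axes Ellipsoid semi-axes in mm along world (x, y, z); the
#'   ground-truth diameter along axis k is `2 * semi_axes[k]`.
#' @param center Ellipsoid center in mm (world coordinates).
#' @param stone_hu,background_hu Attenuation of stone and background (HU);
#'   `stone_hu > background_hu` required.
#' @param psf_fwhm Isotropic Gaussian PSF FWHM in mm (`>= 0`; 0 disables blur).
#' @param noise_sd SD of additive white noise in HU (`>= 0`).
#' @param voxel_spacing Voxel spacing in mm, length 3.
#' @param volume_shape Voxel counts, length 3.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes, center = NULL, stone_hu = 800,
                         background_hu = 0, psf_fwhm = 0.9, noise_sd = 0,
                         voxel_spacing = c(0.7, 0.7, 0.7),
                         volume_shape = NULL, seed = 1L) {
  semi_axes <- rep_len(as.numeric(semi_axes), 3L)
  assert_that(all(semi_axes > 0), "`semi_axes` must all be > 0")
  assert_that(stone_hu > background_hu, "`stone_hu` must exceed `background_hu`")
  assert_that(psf_fwhm >= 0, "`psf_fwhm` must be >= 0")
  assert_that(noise_sd >= 0, "`noise_sd` must be >= 0")
  voxel_spacing <- rep_len(as.numeric(voxel_spacing), 3L)
  assert_that(all(voxel_spacing > 0), "`voxel_spacing` must be positive")
  if (is.null(volume_shape)) {
    margin <- pmax(3 * psf_fwhm, 2)
    volume_shape <- ceiling((2 * (semi_axes + margin)) / voxel_spacing) + 1
  }
  volume_shape <- as.integer(rep_len(volume_shape, 3L))
  if (is.null(center)) {
    center <- (volume_shape - 1) * voxel_spacing / 2
  }
  center <- rep_len(as.numeric(center), 3L)
  structure(
    list(semi_axes = semi_axes, center = center,
         stone_hu = as.numeric(stone_hu), background_hu = as.numeric(background_hu),
         psf_fwhm = as.numeric(psf_fwhm), noise_sd = as.numeric(noise_sd),
         voxel_spacing = voxel_spacing, volume_shape = volume_shape,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> ellipsoid %.2f x %.2f x %.2f mm (diameters), %g HU on %g HU, psf %g mm, noise %g HU\n",
              2 * x$semi_axes[1], 2 * x$semi_axes[2], 2 * x$semi_axes[3],
              x$stone_hu, x$background_hu, x$psf_fwhm, x$noise_sd))
  invisible(x)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Separable Gaussian convolution along one array axis, zero-padded.
# Kernel is a normalized sampled Gaussian truncated at 4 sigma, so mass of
# an interior object is conserved.
blur_axis <- function(a, sigma_mm, spacing_mm, axis) {
  if (sigma_mm <= 0) return(a)
  d <- dim(a)
  r <- max(1L, as.integer(ceiling(4 * sigma_mm / spacing_mm)))
  k <- stats::dnorm((-r:r) * spacing_mm, sd = sigma_mm)
  k <- k / sum(k)
  n <- d[axis]
  # dense banded convolution matrix; n stays modest (few hundred)
  C <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    C[cbind(i[ok], j[ok])] <- k[off + r + 1]
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- C %*% matrix(ap, dp[1], dp[2] * dp[3])
  dim(m) <- dp
  aperm(m, order(perm))
}

# Block-average an array whose dims are s * shape down to shape.
downsample_block <- function(a, shape, s) {
  if (s == 1L) return(a)
  dim(a) <- c(s, shape[1], s, shape[2], s, shape[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(s^3, prod(shape))
  out <- colMeans(a)
  dim(out) <- shape
  out
}

#' Render a phantom to a CT volume
#'
#' The ellipsoid indicator is sampled on a supersampled subgrid (factor
#' `supersample` per axis), convolved with the Gaussian PSF on that subgrid
#' (accurate discrete approximation of the continuous convolution), then
#' block-averaged to voxel resolution; white noise is added last from the
#' spec's seed. Identical spec + seed gives a bit-identical volume.
#'
#' @param spec A [phantom_spec()].
#' @param supersample Subgrid factor per axis (default 3).
#' @return List with `volume` (a [ct_volume()]) and `ground_truth` (named
#'   per-axis true diameters in mm, `2 * semi_axes`).
#' @export
render_phantom <- function(spec, supersample = 3L) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- as.integer(supersample)
  assert_that(s >= 1L, "`supersample` must be >= 1")
  shape <- spec$volume_shape
  sp <- spec$voxel_spacing
  lo <- -sp / 2
  hi <- (shape - 1) * sp + sp / 2
  need_lo <- spec$center - spec$semi_axes - 3 * spec$psf_fwhm
  need_hi <- spec$center + spec$semi_axes + 3 * spec$psf_fwhm
  if (any(need_lo < lo) || any(need_hi > hi)) {
    stop("bounds error: ellipsoid plus 3 x psf_fwhm margin does not fit in the volume",
         call. = FALSE)
  }
  # subvoxel centers along each axis
  coords <- lapply(1:3, function(ax) {
    base <- (seq_len(shape[ax]) - 1) * sp[ax]
    off <- ((2 * seq_len(s) - 1) / (2 * s) - 0.5) * sp[ax]
    as.vector(outer(off, base, "+")) # voxel-major: offset index fastest
  })
  q <- lapply(1:3, function(ax) ((coords[[ax]] - spec$center[ax]) / spec$semi_axes[ax])^2)
  ind <- outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+") <= 1
  ind <- array(as.numeric(ind), dim = shape * s)
  sigma <- fwhm_to_sigma(spec$psf_fwhm)
  # box (voxel averaging) and Gaussian convolution commute, so when the
  # PSF is well resolved at native spacing the blur can run on the
  # down-averaged grid; only a PSF narrower than the voxel needs the
  # supersampled grid
  blur_native <- sigma >= 0.8 * max(sp)
  if (sigma > 0 && !blur_native) {
    for (ax in 1:3) ind <- blur_axis(ind, sigma, sp[ax] / s, ax)
  }
  frac <- downsample_block(ind, shape, s)
  if (sigma > 0 && blur_native) {
    for (ax in 1:3) frac <- blur_axis(frac, sigma, sp[ax], ax)
  }
  vox <- spec$background_hu + (spec$stone_hu - spec$background_hu) * frac
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(spec$seed,
      array(stats::rnorm(prod(shape), 0, spec$noise_sd), dim = shape))
    vox <- vox + noise
  }
  list(volume = ct_volume(vox, spacing = sp),
       ground_truth = c(x = 2 * spec$semi_axes[1],
                        y = 2 * spec$semi_axes[2],
                        z = 2 * spec$semi_axes[3]))
}

#' Ideal and blurred 1D attenuation profile through the phantom center
#'
#' Returns the ideal top-hat attenuation profile along a center line and
#' its Gaussian-blurred counterpart (closed form via the normal CDF). For
#' any PSF width, the blurred profile crosses the half-amplitude level
#' exactly at the ideal edges -- the principle behind the half-value
#' window.
#'
#' @param spec A [phantom_spec()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @param n_samples Number of sample positions (`>= 2`).
#' @return Tibble with `position_mm` (relative to the ellipsoid center),
#'   `ideal_hu`, `blurred_hu`.
#' @export
profile_1d <- function(spec, axis = 1L, n_samples = 401L) {
  stopifnot(inherits(spec, "phantom_spec"))
  assert_that(n_samples >= 2, "`n_samples` must be >= 2")
  axis <- as.integer(axis)
  assert_that(axis %in% 1:3, "`axis` must be 1, 2 or 3")
  a <- spec$semi_axes[axis]
  half_extent <- spec$volume_shape[axis] * spec$voxel_spacing[axis] / 2
  x <- seq(-half_extent, half_extent, length.out = n_samples)
  amp <- spec$stone_hu - spec$background_hu
  ideal <- spec$background_hu + amp * as.numeric(abs(x) <= a)
  if (spec$psf_fwhm > 0) {
    sigma <- fwhm_to_sigma(spec$psf_fwhm)
    blurred <- spec$background_hu +
      amp * (stats::pnorm((x + a) / sigma) - stats::pnorm((x - a) / sigma))
  } else {
    blurred <- ideal
  }
  tibble::tibble(position_mm = x, ideal_hu = ideal, blurred_hu = blurred)
}

#' Generate a synthetic stone cohort
#'
#' Samples a cohort of ellipsoidal stone phantoms emulating proximal
#' ureteral stones: largest diameters from a right-skewed lognormal
#' truncated below at 2.0 mm, stone attenuation from a truncated normal,
#' mild random anisotropy, and Bernoulli spontaneous-passage outcomes from
#' a logistic size-outcome truth. All draws are reproducible from `seed`.
#' Distribution defaults are emulation choices (see the package vignette),
#' anchored only by the ~857 HU mean maximum stone attenuation typical of
#' such cohorts.
#'
#' @param n Number of stones (`>= 1`).
#' @param size_meanlog,size_sdlog Lognormal parameters of the largest
#'   diameter in mm (defaults give mean near 5 mm).
#' @param size_min,size_max Truncation bounds in mm (study inclusion floor
#'   2.0 mm).
#' @param hu_mean,hu_sd,hu_min Stone attenuation distribution (HU).
#' @param anisotropy Range of the ratio of the two minor semi-axes to the
#'   major one.
#' @param passage_intercept,passage_slope Logistic truth for spontaneous
#'   passage: `logit P(pass) = intercept + slope * diameter_mm`.
#' @param psf_fwhm,noise_sd,voxel_spacing Rendering parameters shared by
#'   all phantoms (see [phantom_spec()]).
#' @param seed Master seed.
#' @return Tibble with one row per stone: `stone_id`, `spec` (list column
#'   of [phantom_spec()]), `true_diameter_mm`, `stone_hu`, `passed` (0/1).
#' @export
make_cohort <- function(n,
                        size_meanlog = log(5) - 0.4^2 / 2, size_sdlog = 0.4,
                        size_min = 2, size_max = 13,
                        hu_mean = 940, hu_sd = 130, hu_min = 350,
                        anisotropy = c(0.75, 0.95),
                        passage_intercept = 5.24, passage_slope = -0.95,
                        psf_fwhm = 0.9, noise_sd = 10,
                        voxel_spacing = c(0.45, 0.45, 0.45),
                        seed = 1L) {
  assert_that(is_scalar_number(n) && n >= 1, "`n` must be >= 1")
  assert_that(size_sdlog > 0 && size_min >= 0 && size_max > size_min,
              "invalid size distribution parameters")
  assert_that(hu_sd > 0 && hu_min > 0, "invalid attenuation distribution parameters")
  n <- as.integer(n)
  rows <- withr::with_seed(mix_seed(seed, "cohort"), {
    lapply(seq_len(n), function(i) {
      d <- Inf
      while (d < size_min || d > size_max) d <- stats::rlnorm(1, size_meanlog, size_sdlog)
      hu <- -Inf
      while (hu < hu_min) hu <- stats::rnorm(1, hu_mean, hu_sd)
      ratios <- stats::runif(2, anisotropy[1], anisotropy[2])
      major_axis <- sample.int(3, 1)
      semi <- numeric(3)
      semi[major_axis] <- d / 2
      semi[setdiff(1:3, major_axis)] <- d / 2 * ratios
      p <- stats::plogis(passage_intercept + passage_slope * d)
      passed <- stats::rbinom(1, 1, p)
      list(diameter = d, hu = hu, semi = semi, passed = passed)
    })
  })
  specs <- lapply(seq_len(n), function(i) {
    phantom_spec(semi_axes = rows[[i]]$semi,
                 stone_hu = rows[[i]]$hu,
                 background_hu = 0,
                 psf_fwhm = psf_fwhm, noise_sd = noise_sd,
                 voxel_spacing = voxel_spacing,
                 seed = mix_seed(seed, "noise", i))
  })
  tibble::tibble(
    stone_id = sprintf("stone_%03d", seq_len(n)),
    spec = specs,
    true_diameter_mm = vapply(rows, function(r) r$diameter, numeric(1)),
    stone_hu = vapply(rows, function(r) r$hu, numeric(1)),
    passed = vapply(rows, function(r) as.integer(r$passed), integer(1))
  )
}
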