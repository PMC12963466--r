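#' Circular ROI ("histogram circle")
#'
#' @param center In-plane center in mm (length 2; pixel (1,1) center is at
#'   0 mm).
#' @param radius Radius in mm (`> 0`).
#' @param plane,slab_index Where the circle lives (bookkeeping only).
#' @return An object of class `roi_circle`.
#' @export
roi_circle <- function(center, radius, plane = NA_character_, slab_index = NA_integer_) {
  assert_that(length(center) == 2L && all(is.finite(center)),
              "`center` must be two finite numbers (mm)")
  assert_that(is_scalar_number(radius) && radius > 0, "`radius` must be > 0")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 plane = plane, slab_index = slab_index),
            class = "roi_circle")
}

pixel_coords <- function(slice, spacing) {
  list(x = (seq_len(nrow(slice)) - 1) * spacing[1],
       y = (seq_len(ncol(slice)) - 1) * spacing[2])
}

# squared distance of every pixel center to a point (mm)
pixel_dist2 <- function(slice, spacing, point) {
  pc <- pixel_coords(slice, spacing)
  outer((pc$x - point[1])^2, (pc$y - point[2])^2, "+")
}

#' ROI statistics over pixels strictly inside a circle
#'
#' Mean and maximum HU over pixels whose centers fall strictly inside the
#' circle (`<` convention; boundary pixel centers are excluded).
#'
#' @param slice 2D HU matrix.
#' @param spacing In-plane spacing in mm (length 2).
#' @param roi A [roi_circle()].
#' @param max_quantile Quantile used for the reported "max" (default 1,
#'   the true maximum; a value like 0.99 gives a noise-robust alternative).
#' @return List with `mean`, `max`, `n_pixels`.
#' @export
circle_stats <- function(slice, spacing, roi, max_quantile = 1) {
  stopifnot(inherits(roi, "roi_circle"))
  sel <- pixel_dist2(slice, spacing, roi$center) < roi$radius^2
  if (!any(sel)) {
    stop("empty circle: no pixel centers strictly inside the ROI", call. = FALSE)
  }
  vals <- slice[sel]
  mx <- if (max_quantile >= 1) max(vals) else as.numeric(stats::quantile(vals, max_quantile, names = FALSE))
  list(mean = mean(vals), max = mx, n_pixels = sum(sel))
}

# connected-component labeling (8-connectivity) via EBImage
label_mask <- function(mask) {
  EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
}

component_at <- function(mask, seed_px) {
  if (!mask[seed_px[1], seed_px[2]]) return(NULL)
  lab <- label_mask(mask)
  lab == lab[seed_px[1], seed_px[2]]
}

# 4-neighbour erosion; image border counts as background
erode1 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  mask &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
}

apparent_component <- function(slice, spacing, seed_px, window, threshold = NULL) {
  if (is.null(threshold)) threshold <- gray_levels(window)[["upper"]]
  supra <- slice >= threshold
  comp <- component_at(supra, seed_px)
  if (is.null(comp)) {
    stop("not a stone: seed pixel is not inside a supra-threshold region of the ",
         "display window", call. = FALSE)
  }
  comp
}

component_centroid <- function(comp, spacing) {
  idx <- which(comp, arr.ind = TRUE)
  c((mean(idx[, 1]) - 1) * spacing[1], (mean(idx[, 2]) - 1) * spacing[2])
}

#' Fit the largest inner ROI inside the apparent stone
#'
#' Emulates the half-value MEAN protocol: a circle centered at the apparent
#' stone's centroid, as large as possible while staying wholly inside the
#' supra-upper-level region of the display window eroded by one pixel (the
#' margin that avoids partial-volume contamination at the border).
#' Deterministic. Degenerate apparent stones (two pixels or fewer, or no
#' interior after erosion) fall back to a one-pixel ROI at the brightest
#' component pixel.
#'
#' @param slice 2D HU matrix.
#' @param spacing In-plane spacing (mm, length 2).
#' @param seed_px 1-based (row, col) pixel index inside the apparent stone.
#' @param window Display window defining the apparent stone (default the
#'   soft-tissue preset).
#' @param offset Optional (mm, length 2) displacement of the circle center
#'   from the centroid (models histogram-circle placement jitter).
#' @param threshold Optional HU threshold overriding the window's upper
#'   gray level as the apparent-stone definition (used for stones too
#'   faint to saturate the display).
#' @return A [roi_circle()].
#' @export
fit_inner_roi <- function(slice, spacing, seed_px,
                          window = window_preset("soft_tissue"),
                          offset = c(0, 0), threshold = NULL) {
  comp <- apparent_component(slice, spacing, seed_px, window, threshold)
  eroded <- erode1(comp)
  if (sum(comp) <= 2 || !any(eroded)) {
    idx <- which(comp, arr.ind = TRUE)
    vals <- slice[comp]
    best <- idx[which.max(vals), ]
    return(roi_circle(center = (best - 1) * spacing, radius = 0.51 * min(spacing)))
  }
  center <- component_centroid(comp, spacing) + offset
  d2 <- pixel_dist2(slice, spacing, center)
  radius <- sqrt(min(d2[!eroded]))
  # guard: the circle must capture at least one pixel center strictly inside
  nearest_in <- sqrt(min(d2[eroded]))
  if (radius <= nearest_in) radius <- nearest_in + 1e-6
  roi_circle(center = center, radius = radius)
}

#' Fit the smallest enclosing ROI around the apparent stone
#'
#' Emulates the half-value MAX protocol: a centroid-centered circle fully
#' including the apparent stone plus a one-pixel margin.
#'
#' @inheritParams fit_inner_roi
#' @return A [roi_circle()].
#' @export
fit_enclosing_roi <- function(slice, spacing, seed_px,
                              window = window_preset("soft_tissue"),
                              offset = c(0, 0), threshold = NULL) {
  comp <- apparent_component(slice, spacing, seed_px, window, threshold)
  center <- component_centroid(comp, spacing) + offset
  d2 <- pixel_dist2(slice, spacing, center)
  radius <- sqrt(max(d2[comp])) + max(spacing)
  roi_circle(center = center, radius = radius)
}

#' Threshold segmentation of a slice
#'
#' Builds the binary mask `slice >= threshold`; for a zero-width window the
#' threshold is the window center (the set displayed white). When a seed is
#' given, only the connected component containing it is retained; otherwise
#' the largest component. An empty result is returned as an all-`FALSE`
#' mask (the stone is invisible in this window), not an error.
#'
#' @param slice 2D HU matrix.
#' @param window Optional zero-width [window_setting()]; its center is the
#'   threshold.
#' @param threshold Explicit threshold in HU (overrides `window`).
#' @param seed_px Optional 1-based (row, col) seed pixel.
#' @return Logical matrix of the retained component.
#' @export
threshold_mask <- function(slice, window = NULL, threshold = NULL, seed_px = NULL) {
  if (is.null(threshold)) {
    stopifnot(inherits(window, "window_setting"))
    threshold <- window$center
  }
  mask <- slice >= threshold
  if (!any(mask)) return(mask & FALSE)
  if (!is.null(seed_px)) {
    comp <- component_at(mask, seed_px)
    if (is.null(comp)) return(mask & FALSE)
    return(comp)
  }
  lab <- label_mask(mask)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Maximum Feret diameter of a binary mask
#'
#' Maximum pairwise Euclidean distance between boundary-pixel centers of
#' the mask, in mm (the computational surrogate for a PACS caliper's
#' largest diameter). A single-pixel or empty mask returns 0 by
#' convention. Boundary pixels are those with a 4-neighbour outside the
#' mask; the candidate set is reduced to its convex hull before the
#' pairwise scan.
#'
#' @param mask Logical 2D matrix.
#' @param spacing In-plane spacing (mm, length 2).
#' @return Diameter in mm.
#' @export
max_feret_diameter <- function(mask, spacing) {
  npix <- sum(mask)
  if (npix <= 1L) return(0)
  boundary <- mask & !erode1(mask)
  idx <- which(boundary, arr.ind = TRUE)
  pts <- cbind((idx[, 1] - 1) * spacing[1], (idx[, 2] - 1) * spacing[2])
  if (nrow(pts) > 3L) {
    hull <- grDevices::chull(pts)
    pts <- pts[hull, , drop = FALSE]
  }
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2))
}

#' Observer edge-perception policy for windows with nonzero width
#'
#' In windows of nonzero width the stone border is a gray ramp and a human
#' picks the edge visually; the policy makes that choice an explicit
#' threshold. `"contrast"` (default) places the perceived edge at a fixed
#' fraction of the object's *displayed* contrast above the background's
#' display value -- in a wide window where the stone never saturates (the
#' bone-window situation) thresholds then range over the whole attenuation
#' ramp, while in a saturating window they are confined to the narrow
#' sub-saturation band, which is what makes the bone-window border
#' ill-defined. `"window"` places it at a fixed fraction of the window
#' width above the lower gray level. `"absolute"` uses a fixed HU
#' threshold.
#'
#' @param type Policy type.
#' @param edge_fraction Fraction in `[0, 1]`.
#' @param threshold_hu Threshold for `type = "absolute"`.
#' @return An object of class `perception_policy`.
#' @export
perception_policy <- function(type = c("contrast", "window", "absolute"),
                              edge_fraction = 0.5, threshold_hu = NULL) {
  type <- match.arg(type)
  assert_that(edge_fraction >= 0 && edge_fraction <= 1,
              "`edge_fraction` must be in [0, 1]")
  if (type == "absolute") {
    assert_that(is_scalar_number(threshold_hu),
                "`threshold_hu` required for an absolute policy")
  }
  structure(list(type = type, edge_fraction = edge_fraction,
                 threshold_hu = threshold_hu),
            class = "perception_policy")
}

policy_threshold <- function(policy, window, apparent_peak_hu, background_hu) {
  gl <- gray_levels(window)
  switch(policy$type,
    absolute = policy$threshold_hu,
    window = gl[["lower"]] + policy$edge_fraction * window$width,
    contrast = {
      disp <- function(v) apply_window(v, window)
      bgd <- disp(background_hu)
      topd <- disp(apparent_peak_hu)
      td <- bgd + policy$edge_fraction * (topd - bgd)
      gl[["lower"]] + td * window$width
    })
}

# Per-plane preparation shared by every window mode and observer: pick, in
# the soft-tissue window, the slab where the stone appears largest
# (maximum supra-upper-level area; ties -> lowest slab index).
prepare_planes <- function(vol, seed_point, slab_thickness = 3,
                           soft_window = window_preset("soft_tissue")) {
  stopifnot(inherits(vol, "ct_volume"))
  seed_point <- as.integer(seed_point)
  assert_that(length(seed_point) == 3L, "`seed_point` must be 3 voxel indices")
  d <- dim(vol$voxels)
  assert_that(all(seed_point >= 1L) && all(seed_point <= d),
              "`seed_point` outside the volume")
  upper <- gray_levels(soft_window)[["upper"]]
  planes <- c("axial", "coronal", "sagittal")
  stacks <- lapply(planes, function(pl) slab_stack(vol, pl, slab_thickness))
  names(stacks) <- planes
  # apparent-stone threshold: the saturation (upper gray) level of the
  # display window; stones too faint to saturate after slab averaging
  # fall back to half their apparent peak (they still show as a gray blob)
  smax <- max(vapply(stacks, max, numeric(1)))
  thr <- min(upper, 0.5 * smax)
  if (vol$voxels[seed_point[1], seed_point[2], seed_point[3]] < thr) {
    stop("not a stone: seed voxel (", vol$voxels[seed_point[1], seed_point[2],
         seed_point[3]], " HU) lies below the apparent-stone threshold (",
         signif(thr, 4), " HU)", call. = FALSE)
  }
  out <- lapply(planes, function(pl) {
    stack <- stacks[[pl]]
    areas <- colSums(matrix(stack >= thr, ncol = dim(stack)[3]))
    best <- which.max(areas) # which.max returns the lowest index on ties
    slice <- stack[, , best]
    inpl <- plane_inplane(pl)
    seed_px <- seed_point[inpl]
    # snap the seed to the nearest supra-threshold pixel of the chosen slab
    supra <- slice >= thr
    if (!supra[seed_px[1], seed_px[2]]) {
      idx <- which(supra, arr.ind = TRUE)
      dd <- (idx[, 1] - seed_px[1])^2 + (idx[, 2] - seed_px[2])^2
      seed_px <- as.integer(idx[which.min(dd), ])
    }
    list(plane = pl, slice = slice, spacing = vol$spacing[inpl],
         slab_index = best, seed_px = seed_px, apparent_threshold = thr)
  })
  names(out) <- planes
  out
}

measure_plane <- function(pp, mode, policy, background_hu, roi_offset,
                          roi_max_quantile,
                          soft_window = window_preset("soft_tissue"),
                          bone_window = window_preset("bone")) {
  thr <- pp$apparent_threshold %||% NULL
  inner <- fit_inner_roi(pp$slice, pp$spacing, pp$seed_px, soft_window,
                         roi_offset, threshold = thr)
  encl <- fit_enclosing_roi(pp$slice, pp$spacing, pp$seed_px, soft_window,
                            roi_offset, threshold = thr)
  roi_mean <- circle_stats(pp$slice, pp$spacing, inner)$mean
  roi_max <- circle_stats(pp$slice, pp$spacing, encl, max_quantile = roi_max_quantile)$max
  threshold <- switch(mode,
    half_value_mean = half_value_window(roi_mean, background_hu, "mean")$center,
    half_value_max = half_value_window(roi_max, background_hu, "max")$center,
    soft_tissue = policy_threshold(policy, soft_window, roi_max, background_hu),
    bone = policy_threshold(policy, bone_window, roi_max, background_hu),
    stop("unknown window mode: ", mode, call. = FALSE))
  mask <- threshold_mask(pp$slice, threshold = threshold, seed_px = pp$seed_px)
  list(diameter = max_feret_diameter(mask, pp$spacing),
       roi_mean = roi_mean, roi_max = roi_max, threshold = threshold)
}

#' Measure a stone in a CT volume
#'
#' The semi-automated measurement protocol: in each of the axial, coronal
#' and sagittal reformations, select the slab where the stone appears
#' largest in the soft-tissue window; place the histogram-circle ROI (an
#' inner circle for the MEAN statistic, an enclosing circle for MAX); for
#' the half-value modes derive the zero-width window from the ROI
#' statistic and threshold at its center, for soft-tissue/bone modes
#' threshold at the perception-policy level; measure the maximum Feret
#' diameter of the retained component. The largest of the three per-plane
#' diameters is the protocol's reported size. ROI statistics are computed
#' on raw HU of the MPR slab and reported from the plane of the largest
#' diameter.
#'
#' @param vol A [ct_volume()].
#' @param seed_point 1-based voxel index (x, y, z) inside the apparent
#'   stone (the "semi-automated" user input).
#' @param window_mode One of `"half_value_max"`, `"half_value_mean"`,
#'   `"soft_tissue"`, `"bone"`.
#' @param slab_thickness MPR slab thickness in mm (default 3, the clinical
#'   protocol; use the native spacing for thin-slice measurements).
#' @param policy A [perception_policy()] for the nonzero-width windows
#'   (ignored by the half-value modes, whose threshold is algorithmic).
#' @param background_hu Predefined background attenuation for the
#'   half-value windows (default 0 HU).
#' @param roi_offset In-plane ROI placement offset in mm (length 2;
#'   models histogram-circle jitter, default none).
#' @param roi_max_quantile Quantile for the ROI "max" statistic (default
#'   1 = true maximum).
#' @param stone_id,observer_id Identifiers carried into the output.
#' @return One-row tibble: `stone_id`, `observer_id`, `window`,
#'   `d_axial_mm`, `d_coronal_mm`, `d_sagittal_mm`, `d_largest_mm`,
#'   `roi_mean_hu`, `roi_max_hu`, `plane_of_largest`.
#' @export
measure_stone <- function(vol, seed_point,
                          window_mode = c("half_value_max", "half_value_mean",
                                          "soft_tissue", "bone"),
                          slab_thickness = 3,
                          policy = perception_policy(),
                          background_hu = 0,
                          roi_offset = c(0, 0),
                          roi_max_quantile = 1,
                          stone_id = "stone", observer_id = NA_character_) {
  window_mode <- match.arg(window_mode)
  prep <- prepare_planes(vol, seed_point, slab_thickness)
  measure_prepared(prep, window_mode, policy = policy,
                   background_hu = background_hu, roi_offset = roi_offset,
                   roi_max_quantile = roi_max_quantile,
                   stone_id = stone_id, observer_id = observer_id)
}

# Measurement on pre-selected slabs (lets a simulated study reuse the
# slab selection across observers and windows).
measure_prepared <- function(prep, window_mode, policy = perception_policy(),
                             background_hu = 0, roi_offset = c(0, 0),
                             roi_max_quantile = 1, caliper_noise = c(0, 0, 0),
                             stone_id = "stone", observer_id = NA_character_) {
  res <- lapply(prep, function(pp)
    measure_plane(pp, window_mode, policy, background_hu, roi_offset,
                  roi_max_quantile))
  d <- vapply(res, function(r) r$diameter, numeric(1))
  d <- pmax(d + caliper_noise, 0)
  largest <- which.max(d)
  tibble::tibble(
    stone_id = stone_id, observer_id = observer_id, window = window_mode,
    d_axial_mm = d[["axial"]], d_coronal_mm = d[["coronal"]],
    d_sagittal_mm = d[["sagittal"]], d_largest_mm = max(d),
    roi_mean_hu = res[[largest]]$roi_mean, roi_max_hu = res[[largest]]$roi_max,
    plane_of_largest = names(d)[largest]
  )
}

#' Fully deterministic half-value MAX measurement
#'
#' Convenience composition of [measure_stone()] with
#' `window_mode = "half_value_max"` and deterministic ROI fitting: no free
#' parameters besides the seed point. Because the enclosing ROI, its
#' maximum, and the derived window depend only on the stone's connected
#' component, any seed inside the same stone yields the same measurement
#' -- the property that makes half-value MAX suitable for semi-automated
#' use.
#'
#' @inheritParams measure_stone
#' @param ... Passed to [measure_stone()].
#' @return One-row tibble as for [measure_stone()].
#' @export
half_value_max_semiauto <- function(vol, seed_point, slab_thickness = 3, ...) {
  measure_stone(vol, seed_point, window_mode = "half_value_max",
                slab_thickness = slab_thickness, ...)
}
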