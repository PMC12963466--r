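#' Create a CT volume
#'
#' A minimal HU voxel-grid container. The voxel array uses axis order
#' (x, y, z); the world coordinate of voxel index `(i, j, k)` (0-based) is
#' `origin + index * spacing`, so R's 1-based index `i` sits at
#' `origin[1] + (i - 1) * spacing[1]` mm.
#'
#' @param voxels 3D numeric array of HU values, axis order (x, y, z).
#' @param spacing Numeric length-3, voxel spacing in mm (all `> 0`).
#' @param origin Numeric length-3, world position of voxel (0,0,0) in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  assert_that(is.array(voxels) && length(dim(voxels)) == 3L,
              "`voxels` must be a 3D array")
  spacing <- as.numeric(spacing)
  assert_that(length(spacing) == 3L && all(is.finite(spacing)) && all(spacing > 0),
              "`spacing` must be three positive numbers (mm)")
  origin <- as.numeric(origin)
  assert_that(length(origin) == 3L && all(is.finite(origin)),
              "`origin` must be three finite numbers (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

# axis index (into dims/spacing) orthogonal to each reformation plane
plane_axis <- function(plane) {
  switch(plane, axial = 3L, coronal = 2L, sagittal = 1L,
         stop("`plane` must be one of 'axial', 'coronal', 'sagittal'", call. = FALSE))
}

# the two in-plane axes, in (row, col) order of the returned slice matrix
plane_inplane <- function(plane) {
  switch(plane, axial = c(1L, 2L), coronal = c(1L, 3L), sagittal = c(2L, 3L))
}

#' Multiplanar reformation (MPR) slab
#'
#' Mean-intensity projection over a slab of the volume. Slabs tile the
#' chosen axis contiguously starting at the first voxel's boundary
#' (`origin - spacing/2`); a voxel contributes when its center falls in the
#' half-open interval `[start, start + thickness)`. With
#' `thickness = spacing` along the axis, each slab is a native voxel plane.
#'
#' @param vol A [ct_volume()].
#' @param plane `"axial"` (slab along z), `"coronal"` (y) or `"sagittal"` (x).
#' @param slab_thickness Slab thickness in mm (default 3, the usual MPR
#'   reconstruction for urinary-tract CT).
#' @param slab_index 1-based slab number along the axis.
#' @return List with `slice` (2D HU matrix; rows/cols follow the remaining
#'   axes in (x,y), (x,z) or (y,z) order), `spacing` (in-plane mm pair),
#'   `plane`, `slab_index`, `slab_start` and `slab_end` (mm, world).
#' @export
mpr_slab <- function(vol, plane = c("axial", "coronal", "sagittal"),
                     slab_thickness = 3, slab_index = 1L) {
  stopifnot(inherits(vol, "ct_volume"))
  plane <- match.arg(plane)
  assert_that(is_scalar_number(slab_thickness) && slab_thickness > 0,
              "`slab_thickness` must be a positive number (mm)")
  ax <- plane_axis(plane)
  n <- dim(vol$voxels)[ax]
  centers <- vol$origin[ax] + (seq_len(n) - 1) * vol$spacing[ax]
  axis_start <- vol$origin[ax] - vol$spacing[ax] / 2
  start <- axis_start + (slab_index - 1) * slab_thickness
  end <- start + slab_thickness
  keep <- which(centers >= start & centers < end)
  if (length(keep) == 0L) {
    stop("empty slab: no voxel centers in [", signif(start, 6), ", ",
         signif(end, 6), ") mm along the ", plane, " axis", call. = FALSE)
  }
  idx <- list(TRUE, TRUE, TRUE)
  idx[[ax]] <- keep
  sub <- vol$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  perm <- c(plane_inplane(plane), ax)
  sub <- aperm(sub, perm)
  slice <- rowSums(sub, dims = 2) / length(keep)
  list(slice = slice,
       spacing = vol$spacing[plane_inplane(plane)],
       plane = plane, slab_index = as.integer(slab_index),
       slab_start = start, slab_end = end)
}

#' Number of full slabs along a plane's axis
#' @inheritParams mpr_slab
#' @return Integer count of slabs that contain at least one voxel center.
#' @export
n_slabs <- function(vol, plane, slab_thickness = 3) {
  ax <- plane_axis(plane)
  n <- dim(vol$voxels)[ax]
  extent <- n * vol$spacing[ax]
  max(1L, as.integer(floor(extent / slab_thickness + 1e-9)))
}

# All slab slices of a plane at once (mean projection per slab), as a
# 3D array (inplane1, inplane2, slab). Equivalent to mpr_slab() over all
# slab indices but computed with one pass.
slab_stack <- function(vol, plane, slab_thickness = 3) {
  ax <- plane_axis(plane)
  n <- dim(vol$voxels)[ax]
  centers <- vol$origin[ax] + (seq_len(n) - 1) * vol$spacing[ax]
  axis_start <- vol$origin[ax] - vol$spacing[ax] / 2
  g <- floor((centers - axis_start) / slab_thickness) + 1
  ns <- n_slabs(vol, plane, slab_thickness)
  keep <- g <= ns
  perm <- c(plane_inplane(plane), ax)
  a <- aperm(vol$voxels, perm)
  d <- dim(a)
  M <- matrix(a, d[1] * d[2], d[3])[, keep, drop = FALSE]
  gk <- g[keep]
  sums <- t(rowsum(t(M), gk))
  cnt <- tabulate(gk, nbins = ns)
  slabs <- sweep(sums, 2, cnt, "/")
  array(slabs, dim = c(d[1], d[2], ns))
}

#' Read a CT volume from NIfTI
#'
#' @param path Path to a `.nii` / `.nii.gz` file with HU-valued voxels and
#'   spacing metadata.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D volume, got ", length(dim(arr)), " dimensions", call. = FALSE)
  }
  arr <- array(as.numeric(arr), dim(arr)) # drop NIfTI attributes
  spac <- RNifti::pixdim(img)
  if (length(spac) < 3L || any(!is.finite(spac[1:3])) || any(spac[1:3] <= 0)) {
    stop("volume is missing positive voxel spacing metadata", call. = FALSE)
  }
  # the header stores pixdim as float32; recover the intended decimal value
  ct_volume(arr, spacing = signif(spac[1:3], 6))
}

#' Write a CT volume to NIfTI
#'
#' @param vol A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  arr <- vol$voxels
  attr(arr, "pixdim") <- vol$spacing
  attr(arr, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}
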