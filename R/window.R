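#' Create a CT display window
#'
#' A display window maps Hounsfield units (HU) to gray levels. Values at or
#' below the lower gray level (`center - width/2`) display black, values at
#' or above the upper gray level (`center + width/2`) display white, with a
#' linear ramp in between. A width of zero is legal and denotes the binary
#' half-value display: the window collapses to a step at the center.
#'
#' @param center Window center (WC) in HU.
#' @param width Window width (WW) in HU; must be `>= 0`. `width = 0` gives a
#'   binary display thresholded at `center`.
#' @param label Free-text label (e.g. `"bone"`, `"half_value_max"`).
#' @return An object of class `window_setting`.
#' @examples
#' w <- window_setting(300, 1120, "bone")
#' gray_levels(w)
#' @export
window_setting <- function(center, width, label = "") {
  assert_that(is_scalar_number(center), "`center` must be a single finite number (HU)")
  assert_that(is_scalar_number(width) && width >= 0,
              "`width` must be a single non-negative number (HU)")
  structure(
    list(center = as.numeric(center), width = as.numeric(width),
         label = as.character(label)),
    class = "window_setting"
  )
}

#' @export
print.window_setting <- function(x, ...) {
  gl <- gray_levels(x)
  cat(sprintf("<window_setting> %s: WC %g HU, WW %g HU (gray levels %g to %g HU)\n",
              if (nzchar(x$label)) x$label else "unlabeled",
              x$center, x$width, gl[["lower"]], gl[["upper"]]))
  invisible(x)
}

#' Lower and upper gray levels of a window
#'
#' Attenuation values display white above the upper level `WC + WW/2` and
#' black below the lower level `WC - WW/2`.
#'
#' @param w A [window_setting()].
#' @return Named numeric vector `c(lower =, upper =)` in HU.
#' @examples
#' gray_levels(window_setting(300, 1120)) # c(lower = -260, upper = 860)
#' @export
gray_levels <- function(w) {
  stopifnot(inherits(w, "window_setting"))
  c(lower = w$center - w$width / 2, upper = w$center + w$width / 2)
}

#' Derive a half-value window from object and background attenuation
#'
#' The half-value window places the window center halfway between the
#' background attenuation and a peak statistic of the object (its mean or
#' maximum attenuation from a histogram-circle ROI) and sets the window
#' width to zero. Displayed at this window, a blurred dense object's
#' apparent border falls at the half-amplitude crossing of its attenuation
#' profile, which for a symmetric point-spread function is the true edge --
#' the blooming artifact is eliminated. With the conventional predefined
#' background of 0 HU the center is simply `peak / 2`.
#'
#' @param peak Peak statistic of the object in HU (ROI mean for the
#'   half-value MEAN variant, ROI maximum for half-value MAX).
#' @param background Background attenuation in HU (default 0).
#' @param mode `"mean"` or `"max"`; recorded in the label.
#' @return A [window_setting()] with width 0 and label
#'   `"half_value_<mode>"`.
#' @examples
#' half_value_window(620, mode = "mean") # WC 310
#' half_value_window(736, mode = "max")  # WC 368
#' @export
half_value_window <- function(peak, background = 0, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  assert_that(is_scalar_number(peak), "`peak` must be a single finite number (HU)")
  assert_that(is_scalar_number(background), "`background` must be a single finite number (HU)")
  if (peak <= background) {
    stop("invalid contrast: `peak` (", peak, " HU) must exceed `background` (",
         background, " HU); object is not denser than its background", call. = FALSE)
  }
  window_setting(center = background + (peak - background) / 2,
                 width = 0,
                 label = paste0("half_value_", mode))
}

#' Apply a display window to HU values
#'
#' Maps HU values to normalized display gray in `[0, 1]`: 0 at or below the
#' lower gray level, 1 at or above the upper gray level, linear in between.
#' For a zero-width window the transform is a step: values `>= center`
#' display as 1 (white), values below as 0. The closed (`>=`) convention at
#' zero width makes the supra-threshold region include a voxel at exactly
#' half-maximum, so half-value segmentation is bit-reproducible.
#'
#' @param values Numeric vector/array of HU values.
#' @param w A [window_setting()].
#' @return Numeric object of the same shape with values in `[0, 1]`.
#' @examples
#' apply_window(c(-300, 300, 860), window_setting(300, 1120))
#' @export
apply_window <- function(values, w) {
  stopifnot(inherits(w, "window_setting"))
  if (w$width == 0) {
    out <- (values >= w$center) * 1
  } else {
    gl <- gray_levels(w)
    out <- pmin(pmax((values - gl[["lower"]]) / w$width, 0), 1)
  }
  if (!is.null(dim(values))) dim(out) <- dim(values)
  out
}

#' Standard window presets
#'
#' Presets shipped with the package (YAML under `extdata/`): soft tissue
#' (WC 50 HU, WW 400 HU) and bone (WC 300 HU, WW 1120 HU).
#'
#' @param name Preset name, one of `"soft_tissue"`, `"bone"`.
#' @return A [window_setting()].
#' @examples
#' window_preset("soft_tissue")
#' @export
window_preset <- function(name = c("soft_tissue", "bone")) {
  name <- match.arg(name)
  presets <- window_presets()
  p <- presets[[name]]
  window_setting(p$center, p$width, name)
}

#' All shipped window presets
#'
#' @return Named list of `center`/`width` pairs read from the packaged
#'   YAML config.
#' @export
window_presets <- function() {
  path <- system.file("extdata", "window_presets.yaml", package = "stonewindow")
  if (!nzchar(path)) { # during in-source development
    path <- file.path("inst", "extdata", "window_presets.yaml")
  }
  yaml::read_yaml(path)
}
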