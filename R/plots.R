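#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the ideal and blurred attenuation profile of a phantom
#'
#' The classic half-value picture: a top-hat attenuation profile, its
#' blurred counterpart, and the half-amplitude level at which the blurred
#' profile crosses the true edges.
#'
#' @param spec A [phantom_spec()].
#' @param axis Profile axis (1 = x).
#' @return A ggplot.
#' @export
plot_profile <- function(spec, axis = 1L) {
  prof <- profile_1d(spec, axis = axis)
  long <- tidyr::pivot_longer(prof, c("ideal_hu", "blurred_hu"),
                              names_to = "curve", values_to = "hu")
  half <- spec$background_hu + (spec$stone_hu - spec$background_hu) / 2
  a <- spec$semi_axes[axis]
  ggplot2::ggplot(long, ggplot2::aes(.data$position_mm, .data$hu,
                                     color = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = half, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-a, a), linetype = "dotted") +
    ggplot2::scale_color_manual(
      values = c(ideal_hu = "#2166ac", blurred_hu = "#1b7837"),
      labels = c(ideal_hu = "ideal", blurred_hu = "blurred")) +
    ggplot2::labs(x = "position (mm)", y = "attenuation (HU)",
                  color = NULL,
                  title = "Attenuation profile and half-value level")
}

#' @describeIn loam Bland-Altman autoplot of a `loam_fit` (per-subject
#'   mean vs deviation, with the +-LOAM band and its CI).
#' @param object A `loam_fit`.
#' @param ... Ignored.
#' @export
autoplot.loam_fit <- function(object, ...) {
  if (is.null(object$points)) {
    stop("this loam_fit carries no plot data (fitted from a two_way_fit); ",
         "use bland_altman_points() on the table instead", call. = FALSE)
  }
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$subject_mean, .data$deviation,
                               color = .data$observer)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey50") +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$loam,
                        linetype = "dashed") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$ci_low, ymax = object$ci_high,
                      alpha = 0.08) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = -object$ci_high, ymax = -object$ci_low,
                      alpha = 0.08) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "mean of all observers (mm)",
                  y = "deviation from mean (mm)", color = "observer",
                  title = sprintf("LOAM ±%.2f mm (%.0f%% CI %.2f–%.2f)",
                                  object$loam, 100 * object$level,
                                  object$ci_low, object$ci_high))
}

#' @describeIn fit_logistic Prediction-curve autoplot of a `passage_fit`.
#' @param object A `passage_fit`.
#' @param grid Size grid (mm).
#' @param ... Ignored.
#' @export
autoplot.passage_fit <- function(object, grid = seq(2, 12, by = 0.1), ...) {
  df <- tibble::tibble(size_mm = grid, prob = predict_prob(object, grid))
  ggplot2::ggplot(df, ggplot2::aes(.data$size_mm, .data$prob)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "stone size (mm)",
                  y = "probability of spontaneous passage")
}

#' Plot a family of passage-prediction curves
#'
#' One curve per observer, faceted by window setting; the horizontal
#' spread of the curves visualizes how interreader variability propagates
#' into the predicted probability of passage.
#'
#' @param cf Output of [curve_family()].
#' @return A ggplot.
#' @export
plot_curve_family <- function(cf) {
  ggplot2::ggplot(cf$curves,
                  ggplot2::aes(.data$size_mm, .data$prob,
                               color = .data$observer_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~window) +
    ggplot2::labs(x = "measured stone size (mm)",
                  y = "probability of spontaneous passage",
                  color = "observer")
}

#' @describeIn run_demo Study autoplot: per-window Bland-Altman panels.
#' @param object A `stone_study`.
#' @param ... Ignored.
#' @export
autoplot.stone_study <- function(object, ...) {
  lt <- object$loam[, c("window", "loam")]
  ggplot2::ggplot(object$ba_points,
                  ggplot2::aes(.data$subject_mean, .data$deviation,
                               color = .data$observer)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey50") +
    ggplot2::geom_hline(data = lt,
                        ggplot2::aes(yintercept = .data$loam),
                        linetype = "dashed", inherit.aes = FALSE) +
    ggplot2::geom_hline(data = lt,
                        ggplot2::aes(yintercept = -.data$loam),
                        linetype = "dashed", inherit.aes = FALSE) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~window) +
    ggplot2::labs(x = "mean of all observers (mm)",
                  y = "deviation from mean (mm)", color = "observer")
}
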