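#' Logistic model of spontaneous stone passage versus size
#'
#' Fits `logit P(pass) = intercept + slope * size` by maximum likelihood
#' (no penalization). Complete separation is surfaced, not corrected: the
#' fit is returned with `converged = FALSE` and status `"separation"`
#' rather than a silently diverging estimate.
#'
#' @param sizes Numeric vector of measured sizes (mm).
#' @param outcomes Binary vector (0/1 or logical) of spontaneous-passage
#'   outcomes, same length.
#' @return Object of class `passage_fit`: `intercept`, `slope` (log-odds
#'   per mm), `cov` (2x2 covariance of the estimates), `n_obs`,
#'   `converged`, `status`.
#' @export
fit_logistic <- function(sizes, outcomes) {
  sizes <- as.numeric(sizes)
  outcomes <- as.integer(outcomes)
  assert_that(length(sizes) == length(outcomes),
              "`sizes` and `outcomes` must have the same length")
  assert_that(all(outcomes %in% c(0L, 1L)), "`outcomes` must be binary 0/1")
  if (all(outcomes == 1L) || all(outcomes == 0L)) {
    stop("need at least one event and one non-event", call. = FALSE)
  }
  sep_warning <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcomes ~ sizes, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warning <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- unname(stats::coef(fit))
  # complete separation: a size threshold splits events from non-events,
  # the likelihood has no maximum and |slope| diverges
  separated <- sep_warning && abs(co[2]) > 20
  converged <- isTRUE(fit$converged) && !separated && all(is.finite(co))
  structure(list(intercept = co[1], slope = co[2],
                 cov = unname(stats::vcov(fit)), n_obs = length(sizes),
                 converged = converged,
                 status = if (separated) "separation" else
                   if (converged) "converged" else "not_converged"),
            class = "passage_fit")
}

#' @export
print.passage_fit <- function(x, ...) {
  cat(sprintf("<passage_fit> logit P = %.4g %+.4g * size_mm (n=%d, %s)\n",
              x$intercept, x$slope, x$n_obs, x$status))
  invisible(x)
}

#' @export
tidy.passage_fit <- function(x, ...) {
  se <- sqrt(diag(x$cov))
  tibble::tibble(term = c("(Intercept)", "size_mm"),
                 estimate = c(x$intercept, x$slope),
                 std.error = se,
                 statistic = c(x$intercept, x$slope) / se)
}

#' @export
glance.passage_fit <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, slope = x$slope,
                 n_obs = x$n_obs, converged = x$converged, status = x$status)
}

check_converged <- function(fit) {
  stopifnot(inherits(fit, "passage_fit"))
  if (!fit$converged) {
    stop("logistic fit did not converge (status: ", fit$status,
         "); predictions are unavailable", call. = FALSE)
  }
}

#' Predicted passage probability at a given size
#'
#' @param fit A converged [fit_logistic()] result.
#' @param size Size(s) in mm.
#' @return Probabilities in (0, 1); strictly decreasing in size when the
#'   slope is negative.
#' @export
predict_prob <- function(fit, size) {
  check_converged(fit)
  stats::plogis(fit$intercept + fit$slope * size)
}

#' Size at a given passage probability
#'
#' Exact inverse of [predict_prob()]: `(logit(p) - intercept) / slope`.
#' Useful for reading off, e.g., the measured size at 90% expected
#' passage rate.
#'
#' @param fit A converged [fit_logistic()] result with nonzero slope.
#' @param p Probability (strictly between 0 and 1).
#' @return Size in mm.
#' @export
size_at_prob <- function(fit, p) {
  check_converged(fit)
  assert_that(all(p > 0 & p < 1), "`p` must be strictly between 0 and 1")
  if (fit$slope == 0) {
    stop("no inverse: fitted slope is 0, probability does not vary with size",
         call. = FALSE)
  }
  (stats::qlogis(p) - fit$intercept) / fit$slope
}

#' Per-group logistic prediction curves
#'
#' Fits one passage model per group (by default per observer x window,
#' using each observer's largest-diameter measurements) and evaluates all
#' fits on a common size grid, the data behind a family of prediction
#' curves whose spread visualizes interreader variability. Groups whose
#' fit fails or does not converge are reported in the output, not
#' silently dropped.
#'
#' @param table Long study table with outcome column `passed` (see
#'   [simulate_study()]).
#' @param group_by Character vector of grouping columns.
#' @param size Column holding the measured size.
#' @param outcome Column holding the binary outcome.
#' @param grid Numeric vector of sizes (mm) at which to evaluate curves.
#' @return List with `fits` (tibble: group columns, `fit` list column,
#'   `converged`, `status`, `size_at_p90`) and `curves` (long tibble:
#'   group columns, `size_mm`, `prob`).
#' @export
curve_family <- function(table, group_by = c("observer_id", "window"),
                         size = "d_largest_mm", outcome = "passed",
                         grid = seq(2, 12, by = 0.1)) {
  df <- tibble::as_tibble(table)
  fits <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::group_modify(function(d, key) {
      f <- tryCatch(fit_logistic(d[[size]], d[[outcome]]),
                    error = function(e) e)
      tibble::tibble(fit = list(f))
    }) |>
    dplyr::ungroup()
  fits <- fits |>
    dplyr::mutate(
      converged = purrr::map_lgl(.data$fit, function(f)
        inherits(f, "passage_fit") && f$converged),
      status = purrr::map_chr(.data$fit, function(f)
        if (inherits(f, "passage_fit")) f$status else conditionMessage(f)),
      size_at_p90 = purrr::map_dbl(.data$fit, function(f)
        if (inherits(f, "passage_fit") && f$converged)
          size_at_prob(f, 0.9) else NA_real_)
    )
  curves <- fits |>
    dplyr::filter(.data$converged) |>
    dplyr::mutate(curve = purrr::map(.data$fit, function(f)
      tibble::tibble(size_mm = grid, prob = predict_prob(f, grid)))) |>
    dplyr::select(dplyr::all_of(group_by), "curve") |>
    tidyr::unnest("curve")
  list(fits = fits, curves = curves)
}
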