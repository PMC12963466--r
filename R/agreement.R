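#' Fit the additive two-way random-effects model
#'
#' Model: `y_ij = mu + subject_i + observer_j + e_ij` with independent
#' zero-mean random effects. Balanced tables (every subject measured by
#' the same set of observers exactly once) use the closed-form two-way
#' ANOVA moment estimators; unbalanced tables use REML via `lme4`.
#' Negative moment estimates are truncated at zero with a warning.
#'
#' @param table Long-format data frame of measurements.
#' @param subject,observer,value Column names (strings) holding subject
#'   id, observer id and the measured value; defaults match the study
#'   tables produced by [simulate_study()].
#' @param method `"auto"` (ANOVA when balanced, REML otherwise),
#'   `"anova"` (balanced only) or `"reml"`.
#' @return An object of class `two_way_fit` with variance components
#'   `var_subject`, `var_observer`, `var_residual`, the `grand_mean`,
#'   design sizes `n` (subjects) and `m` (observers), the estimation
#'   `method`, and (balanced path) the mean squares and their degrees of
#'   freedom used for interval estimation.
#' @export
fit_two_way <- function(table, subject = "stone_id", observer = "observer_id",
                        value = "d_largest_mm",
                        method = c("auto", "anova", "reml")) {
  method <- match.arg(method)
  df <- tibble::as_tibble(table)[, c(subject, observer, value)]
  names(df) <- c("subject", "observer", "value")
  df$subject <- as.character(df$subject)
  df$observer <- as.character(df$observer)
  assert_that(!anyNA(df$value), "measurement values must not be NA")
  if (anyDuplicated(df[, c("subject", "observer")])) {
    stop("each (subject, observer) pair may appear at most once", call. = FALSE)
  }
  n <- length(unique(df$subject))
  m <- length(unique(df$observer))
  if (n < 2 || m < 2) {
    stop("variance-component estimation needs >= 2 subjects and >= 2 observers",
         call. = FALSE)
  }
  if (stats::var(df$value) == 0) {
    return(structure(list(var_subject = 0, var_observer = 0, var_residual = 0,
                          grand_mean = df$value[1], n = n, m = m,
                          method = "degenerate", ms = NULL),
                     class = "two_way_fit"))
  }
  counts <- table(df$subject, df$observer)
  balanced <- all(counts == 1L)
  if (method == "anova" && !balanced) {
    stop("the ANOVA path requires a balanced table; use method = 'reml'",
         call. = FALSE)
  }
  use_anova <- balanced && method != "reml"
  if (use_anova) {
    y <- matrix(NA_real_, n, m,
                dimnames = list(sort(unique(df$subject)), sort(unique(df$observer))))
    y[cbind(df$subject, df$observer)] <- df$value
    rowm <- rowMeans(y); colm <- colMeans(y); g <- mean(y)
    msa <- m * sum((rowm - g)^2) / (n - 1)
    msb <- n * sum((colm - g)^2) / (m - 1)
    mse <- sum((y - outer(rowm, colm, "+") + g)^2) / ((n - 1) * (m - 1))
    va <- (msa - mse) / m
    vb <- (msb - mse) / n
    if (va < 0 || vb < 0) {
      warning("negative variance-component moment estimate truncated to 0",
              call. = FALSE)
    }
    structure(list(var_subject = max(va, 0), var_observer = max(vb, 0),
                   var_residual = mse, grand_mean = g, n = n, m = m,
                   method = "anova",
                   ms = list(msa = msa, msb = msb, mse = mse,
                             df_a = n - 1, df_b = m - 1,
                             df_e = (n - 1) * (m - 1))),
              class = "two_way_fit")
  } else {
    fit <- suppressMessages(lme4::lmer(
      value ~ 1 + (1 | subject) + (1 | observer), data = df, REML = TRUE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    get <- function(grp) vc$vcov[vc$grp == grp]
    structure(list(var_subject = get("subject"), var_observer = get("observer"),
                   var_residual = get("Residual"),
                   grand_mean = unname(lme4::fixef(fit)[1]),
                   n = n, m = m, method = "reml", ms = NULL),
              class = "two_way_fit")
  }
}

#' @export
print.two_way_fit <- function(x, ...) {
  cat(sprintf("<two_way_fit> (%s) n=%d subjects, m=%d observers\n",
              x$method, x$n, x$m))
  cat(sprintf("  var: subject %.4g, observer %.4g, residual %.4g; grand mean %.4g\n",
              x$var_subject, x$var_observer, x$var_residual, x$grand_mean))
  invisible(x)
}

# Graybill-Wang modified-large-sample CI for V = c1*MSB + c2*MSE
mls_interval <- function(ms, n, level) {
  alpha <- 1 - level
  c1 <- 1 / n; c2 <- 1 - 1 / n
  V <- c1 * ms$msb + c2 * ms$mse
  g1 <- 1 - ms$df_b / stats::qchisq(1 - alpha / 2, ms$df_b)
  g2 <- 1 - ms$df_e / stats::qchisq(1 - alpha / 2, ms$df_e)
  h1 <- ms$df_b / stats::qchisq(alpha / 2, ms$df_b) - 1
  h2 <- ms$df_e / stats::qchisq(alpha / 2, ms$df_e) - 1
  lo <- V - sqrt(g1^2 * c1^2 * ms$msb^2 + g2^2 * c2^2 * ms$mse^2)
  hi <- V + sqrt(h1^2 * c1^2 * ms$msb^2 + h2^2 * c2^2 * ms$mse^2)
  c(max(lo, 0), hi)
}

#' Limits of agreement with the mean (LOAM)
#'
#' Under the additive two-way model, an observer's deviation from the
#' per-subject observer mean has variance `(1 - 1/m) * (var_observer +
#' var_residual)`; the LOAM half-width is `z * sqrt` of that, with `z` the
#' standard-normal quantile for the chosen level. The default 95% CI is a
#' Graybill-Wang modified-large-sample interval on the variance sum
#' (balanced designs); a parametric bootstrap is available and is used
#' automatically for unbalanced tables.
#'
#' @param table Long-format measurement table, or a [fit_two_way()] result.
#' @param level Agreement level (default 0.95).
#' @param ci_method `"mls"` (default, balanced designs) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates (bootstrap path).
#' @param seed Seed for the bootstrap path.
#' @inheritParams fit_two_way
#' @return Object of class `loam_fit`: `loam` (half-width, report as
#'   +-loam), `ci_low`, `ci_high`, the variance components, `level`, `n`,
#'   `m`, and the methods used.
#' @export
loam <- function(table, level = 0.95, ci_method = c("mls", "bootstrap"),
                 n_boot = 200, seed = 1L,
                 subject = "stone_id", observer = "observer_id",
                 value = "d_largest_mm") {
  ci_method <- match.arg(ci_method)
  fit <- if (inherits(table, "two_way_fit")) table else
    fit_two_way(table, subject, observer, value)
  z <- stats::qnorm((1 + level) / 2)
  fac <- 1 - 1 / fit$m
  v_sum <- fit$var_observer + fit$var_residual
  point <- z * sqrt(fac * v_sum)
  if (fit$method == "degenerate" || v_sum == 0) {
    ci <- c(0, 0)
    ci_method_used <- "degenerate"
  } else if (ci_method == "mls" && fit$method == "anova") {
    vb <- mls_interval(fit$ms, fit$n, level)
    ci <- z * sqrt(fac * vb)
    ci_method_used <- "mls"
  } else {
    ci <- loam_bootstrap_ci(fit, level, z, fac, n_boot, seed)
    ci_method_used <- "bootstrap"
  }
  points <- if (is.data.frame(table)) {
    tryCatch(suppressWarnings(bland_altman_points(table, subject, observer, value)),
             error = function(e) NULL)
  }
  structure(list(loam = point, ci_low = ci[1], ci_high = ci[2],
                 var_subject = fit$var_subject, var_observer = fit$var_observer,
                 var_residual = fit$var_residual, grand_mean = fit$grand_mean,
                 level = level, n = fit$n, m = fit$m,
                 method = fit$method, ci_method = ci_method_used,
                 points = points),
            class = "loam_fit")
}

loam_bootstrap_ci <- function(fit, level, z, fac, n_boot, seed) {
  alpha <- 1 - level
  sims <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
    tab <- simulate_two_way(fit$n, fit$m, fit$var_subject, fit$var_observer,
                            fit$var_residual, grand_mean = fit$grand_mean,
                            seed = sample.int(2^30, 1))
    f <- suppressWarnings(fit_two_way(tab))
    f$var_observer + f$var_residual
  }, numeric(1)))
  q <- stats::quantile(sims, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  # percentile interval recentred on the estimate (basic bootstrap)
  v_sum <- fit$var_observer + fit$var_residual
  lo <- max(2 * v_sum - q[2], 0)
  hi <- max(2 * v_sum - q[1], 0)
  z * sqrt(fac * c(lo, hi))
}

#' @export
print.loam_fit <- function(x, ...) {
  cat(sprintf("<loam_fit> LOAM +-%.3g mm (%.0f%% CI %.3g-%.3g), n=%d, m=%d [%s/%s]\n",
              x$loam, 100 * x$level, x$ci_low, x$ci_high, x$n, x$m,
              x$method, x$ci_method))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.loam_fit <- function(x, ...) {
  tibble::tibble(
    term = c("loam", "var_subject", "var_observer", "var_residual"),
    estimate = c(x$loam, x$var_subject, x$var_observer, x$var_residual),
    conf.low = c(x$ci_low, NA, NA, NA),
    conf.high = c(x$ci_high, NA, NA, NA)
  )
}

#' @export
glance.loam_fit <- function(x, ...) {
  tibble::tibble(loam = x$loam, ci_low = x$ci_low, ci_high = x$ci_high,
                 level = x$level, n = x$n, m = x$m,
                 method = x$method, ci_method = x$ci_method)
}

#' Multi-observer Bland-Altman plot data
#'
#' One point per measurement: the per-subject all-observer mean on the
#' horizontal axis, the observer's deviation from it on the vertical.
#' Per-subject deviations sum to zero by construction. Subjects with a
#' single observer carry no agreement information and are excluded with a
#' warning.
#'
#' @inheritParams fit_two_way
#' @return Tibble with `subject`, `observer`, `subject_mean`, `deviation`.
#' @export
bland_altman_points <- function(table, subject = "stone_id",
                                observer = "observer_id",
                                value = "d_largest_mm") {
  df <- tibble::as_tibble(table)[, c(subject, observer, value)]
  names(df) <- c("subject", "observer", "value")
  counts <- dplyr::count(df, .data$subject)
  single <- counts$subject[counts$n < 2]
  if (length(single) > 0) {
    warning("excluding ", length(single),
            " subject(s) with a single observer", call. = FALSE)
    df <- df[!df$subject %in% single, ]
  }
  df |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(subject_mean = mean(.data$value),
                  deviation = .data$value - .data$subject_mean) |>
    dplyr::ungroup() |>
    dplyr::select("subject", "observer", "subject_mean", "deviation")
}

#' LOAM per window setting
#'
#' Analyzes each window setting of a long study table as a separate
#' agreement table (mirroring per-window reporting of interreader
#' variability).
#'
#' @param study_table Output of [simulate_study()] (or any long table with
#'   a `window` column plus the agreement columns).
#' @param ... Passed to [loam()].
#' @return Tibble with one row per window: `window`, `loam`, `ci_low`,
#'   `ci_high`, `n`, `m`, and a `fit` list column of `loam_fit` objects.
#' @export
loam_by_window <- function(study_table, ...) {
  study_table |>
    dplyr::group_by(.data$window) |>
    dplyr::group_modify(function(d, key) {
      f <- loam(d, ...)
      g <- glance(f)
      g$fit <- list(f)
      g
    }) |>
    dplyr::ungroup()
}

#' Simulate a balanced two-way measurement table
#'
#' Draws `y_ij = mu + a_i + b_j + e_ij` with independent normal effects.
#' Used for estimator validation (bias and CI coverage of [loam()]).
#'
#' @param n,m Numbers of subjects and observers.
#' @param var_subject,var_observer,var_residual True variance components.
#' @param grand_mean True grand mean.
#' @param seed Seed.
#' @return Long tibble with `stone_id`, `observer_id`, `d_largest_mm`.
#' @export
simulate_two_way <- function(n, m, var_subject, var_observer, var_residual,
                             grand_mean = 5, seed = 1L) {
  y <- withr::with_seed(seed, {
    outer(stats::rnorm(n, 0, sqrt(var_subject)),
          stats::rnorm(m, 0, sqrt(var_observer)), "+") +
      matrix(stats::rnorm(n * m, 0, sqrt(var_residual)), n, m) + grand_mean
  })
  tibble::tibble(
    stone_id = rep(sprintf("s%03d", seq_len(n)), times = m),
    observer_id = rep(sprintf("o%d", seq_len(m)), each = n),
    d_largest_mm = as.vector(y)
  )
}
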