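#' Study configuration
#'
#' Bundles every tunable of the end-to-end simulated study: cohort
#' distribution parameters, observer panel, window settings, slab
#' thickness, seeds, and the agreement CI method. A config round-trips
#' losslessly through YAML ([write_study_config()] / [read_study_config()]).
#'
#' @param n_stones Cohort size.
#' @param seed Master seed for the whole study.
#' @param observers List of [observer_profile()]s.
#' @param window_modes Window settings to measure in.
#' @param slab_thickness MPR slab thickness (mm).
#' @param exclude_bone_observer If `TRUE` (default), the last observer's
#'   bone-window measurements are excluded, emulating a study arm lost to
#'   a technical error; the bone window is then analyzed with one fewer
#'   observer.
#' @param ci_method CI method for [loam()].
#' @param level Agreement level.
#' @param cohort_args Extra arguments passed to [make_cohort()].
#' @param grid Size grid (mm) for prediction curves.
#' @return List of class `study_config`.
#' @export
study_config <- function(n_stones = 60, seed = 1L,
                         observers = default_observers(),
                         window_modes = c("bone", "soft_tissue",
                                          "half_value_mean", "half_value_max"),
                         slab_thickness = 3,
                         exclude_bone_observer = TRUE,
                         ci_method = "mls", level = 0.95,
                         cohort_args = list(),
                         grid = seq(2, 12, by = 0.1)) {
  structure(list(n_stones = n_stones, seed = as.integer(seed),
                 observers = observers, window_modes = window_modes,
                 slab_thickness = slab_thickness,
                 exclude_bone_observer = exclude_bone_observer,
                 ci_method = ci_method, level = level,
                 cohort_args = cohort_args, grid = grid),
            class = "study_config")
}

#' Serialize / restore a study configuration
#'
#' @param config A [study_config()].
#' @param path YAML file path.
#' @return `read_study_config()` returns a [study_config()];
#'   `write_study_config()` returns `path` invisibly.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  x$observers <- lapply(x$observers, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$observers <- lapply(x$observers, function(o)
    observer_profile(o$observer_id, o$edge_fraction, o$caliper_sd,
                     o$roi_center_sd, o$policy_type, o$seed))
  do.call(study_config, x)
}

# FNV-1a hash of a character scalar; cheap text checksum for manifests
fnv1a <- function(txt) {
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

table_checksum <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  fnv1a(paste(unlist(lapply(df, as.character)), collapse = ","))
}

#' Run the end-to-end demonstration study
#'
#' Generates a synthetic stone cohort, simulates a multi-observer
#' measurement study across the four window settings, computes per-window
#' LOAM with CIs, multi-observer Bland-Altman points, and per-observer
#' logistic passage-prediction curves. Deterministic given the config: the
#' returned manifest records versions, seeds and table checksums, and
#' rerunning the same config reproduces identical checksums.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, writes `cohort.csv`,
#'   `study.csv`, `loam.csv`, `bland_altman.csv`, `curves.csv` and
#'   `manifest.json` there.
#' @return List of class `stone_study`: `cohort`, `study` (long
#'   measurement table), `loam` (per-window tibble), `ba_points`,
#'   `curves` (from [curve_family()]), `manifest`, `config`.
#' @export
run_demo <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  cohort <- do.call(make_cohort,
                    c(list(n = config$n_stones,
                           seed = mix_seed(config$seed, "cohort")),
                      config$cohort_args))
  exclude <- NULL
  if (isTRUE(config$exclude_bone_observer) && "bone" %in% config$window_modes) {
    last_obs <- config$observers[[length(config$observers)]]$observer_id
    exclude <- tibble::tibble(observer_id = last_obs, window = "bone")
  }
  study <- simulate_study(cohort, config$observers, config$window_modes,
                          master_seed = mix_seed(config$seed, "study"),
                          slab_thickness = config$slab_thickness,
                          exclude = exclude)
  loam_tbl <- loam_by_window(study, level = config$level,
                             ci_method = config$ci_method)
  ba <- study |>
    dplyr::group_by(.data$window) |>
    dplyr::group_modify(function(d, key) bland_altman_points(d)) |>
    dplyr::ungroup()
  curves <- curve_family(study, grid = config$grid)
  manifest <- list(
    package_version = as.character(utils::packageVersion("stonewindow")),
    r_version = R.version.string,
    seed = config$seed,
    n_stones = config$n_stones,
    observers = lapply(config$observers, unclass),
    window_modes = config$window_modes,
    checksums = list(cohort = table_checksum(cohort[, c("stone_id", "true_diameter_mm",
                                                        "stone_hu", "passed")]),
                     study = table_checksum(study))
  )
  out <- structure(list(cohort = cohort, study = study, loam = loam_tbl,
                        ba_points = ba, curves = curves,
                        manifest = manifest, config = config),
                   class = "stone_study")
  if (!is.null(out_dir)) write_study_artifacts(out, out_dir)
  out
}

write_study_artifacts <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$cohort[, c("stone_id", "true_diameter_mm", "stone_hu", "passed")],
                   file.path(out_dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(x$study, file.path(out_dir, "study.csv"), row.names = FALSE)
  utils::write.csv(x$loam[, c("window", "loam", "ci_low", "ci_high", "n", "m")],
                   file.path(out_dir, "loam.csv"), row.names = FALSE)
  utils::write.csv(x$ba_points, file.path(out_dir, "bland_altman.csv"),
                   row.names = FALSE)
  utils::write.csv(x$curves$curves, file.path(out_dir, "curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(x$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.stone_study <- function(x, ...) {
  cat(sprintf("<stone_study> %d stones x %d observers x %d windows (%d rows)\n",
              nrow(x$cohort), length(x$config$observers),
              length(x$config$window_modes), nrow(x$study)))
  lt <- x$loam
  for (i in seq_len(nrow(lt))) {
    cat(sprintf("  LOAM %-16s +-%.2f mm (%.0f%% CI %.2f-%.2f)\n",
                lt$window[i], lt$loam[i], 100 * x$config$level,
                lt$ci_low[i], lt$ci_high[i]))
  }
  invisible(x)
}

#' Read / write long measurement tables
#'
#' Fixed CSV dialect: comma separator, `.` decimal, UTF-8, mandatory
#' header.
#'
#' @param table Data frame to write.
#' @param path CSV path.
#' @return `read_table_csv()` returns a tibble; `write_table_csv()`
#'   returns `path` invisibly.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
}
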