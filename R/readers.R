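#' Simulated observer profile
#'
#' Mechanistic stand-in for a human reader. Fixed traits: where within the
#' displayed contrast the observer perceives the stone border in
#' nonzero-width windows (`edge_fraction`, via the perception policy), plus
#' per-measurement caliper jitter and histogram-circle placement jitter.
#' Half-value modes ignore `edge_fraction` (their threshold is
#' algorithmic).
#'
#' @param observer_id Identifier.
#' @param edge_fraction In `[0, 1]`; passed to [perception_policy()].
#' @param caliper_sd SD (mm) of per-plane caliper placement noise.
#' @param roi_center_sd SD (mm) of histogram-circle placement jitter.
#' @param policy_type Perception policy type (see [perception_policy()]).
#' @param seed Per-observer seed component.
#' @return An object of class `observer_profile`.
#' @export
observer_profile <- function(observer_id, edge_fraction = 0.5,
                             caliper_sd = 0.1, roi_center_sd = 0.3,
                             policy_type = "contrast", seed = 1L) {
  assert_that(edge_fraction >= 0 && edge_fraction <= 1,
              "`edge_fraction` must be in [0, 1]")
  assert_that(caliper_sd >= 0 && roi_center_sd >= 0,
              "noise SDs must be >= 0")
  structure(list(observer_id = as.character(observer_id),
                 edge_fraction = edge_fraction,
                 caliper_sd = caliper_sd, roi_center_sd = roi_center_sd,
                 policy_type = policy_type, seed = as.integer(seed)),
            class = "observer_profile")
}

#' Default panel of five simulated observers
#'
#' Five observers with heterogeneous perceived-edge fractions and modest
#' placement noise. The trait values are calibration choices (tuned so the
#' simulated study reproduces the clinically observed ordering of
#' interreader variability across window settings); they are not measured
#' human parameters.
#'
#' @param caliper_sd,roi_center_sd Shared noise SDs (mm).
#' @return List of [observer_profile()]s.
#' @export
default_observers <- function(caliper_sd = 0.1, roi_center_sd = 0.3) {
  ef <- c(0.30, 0.40, 0.50, 0.60, 0.70)
  lapply(seq_along(ef), function(i)
    observer_profile(paste0("obs_", i), edge_fraction = ef[i],
                     caliper_sd = caliper_sd, roi_center_sd = roi_center_sd,
                     seed = 1000L + i))
}

#' Simulate one observer's reading of a stone
#'
#' Applies the observer's perception policy (nonzero-width windows only),
#' perturbs the histogram-circle center by `N(0, roi_center_sd^2)` in each
#' in-plane direction, and adds `N(0, caliper_sd^2)` caliper noise to each
#' per-plane diameter (truncated at 0) before taking the largest. With all
#' noise SDs zero and a half-value mode this reduces exactly to
#' [half_value_max_semiauto()] / [measure_stone()].
#'
#' @inheritParams measure_stone
#' @param profile An [observer_profile()].
#' @param rng_seed Integer seed for this reading's noise draws.
#' @return One-row measurement tibble (see [measure_stone()]).
#' @export
simulate_reading <- function(vol, seed_point, window_mode, profile,
                             rng_seed = 1L, slab_thickness = 3,
                             background_hu = 0, stone_id = "stone") {
  prep <- prepare_planes(vol, seed_point, slab_thickness)
  simulate_reading_prepared(prep, window_mode, profile, rng_seed,
                            background_hu = background_hu, stone_id = stone_id)
}

simulate_reading_prepared <- function(prep, window_mode, profile, rng_seed,
                                      background_hu = 0, stone_id = "stone") {
  stopifnot(inherits(profile, "observer_profile"))
  noise <- withr::with_seed(rng_seed, list(
    roi = stats::rnorm(2, 0, profile$roi_center_sd),
    caliper = stats::rnorm(3, 0, profile$caliper_sd)
  ))
  pol <- perception_policy(profile$policy_type, profile$edge_fraction)
  measure_prepared(prep, window_mode, policy = pol,
                   background_hu = background_hu,
                   roi_offset = noise$roi, caliper_noise = noise$caliper,
                   stone_id = stone_id, observer_id = profile$observer_id)
}

#' Simulate a multi-observer measurement study
#'
#' Renders each cohort phantom once, reuses its slab selection, and has
#' every observer measure every stone in every window setting. Randomness
#' flows through named substreams derived from `master_seed`, the stone
#' id, the observer's seed and the window, so permuting observers or
#' windows leaves each cell's value unchanged and the study is
#' reproducible bit-exactly from its manifest.
#'
#' @param cohort Tibble from [make_cohort()] (or any tibble with
#'   `stone_id`, `spec`, `passed` columns).
#' @param observers List of [observer_profile()]s (`>= 2`).
#' @param window_modes Character vector of window modes.
#' @param master_seed Master seed.
#' @param slab_thickness MPR slab thickness in mm.
#' @param exclude Optional tibble with `observer_id` and `window` columns;
#'   matching cells are dropped (emulates an observer's excluded window).
#' @param supersample Phantom rendering subgrid factor.
#' @return Long tibble, one row per stone x observer x window, with the
#'   measurement columns of [measure_stone()] plus `passed`.
#' @export
simulate_study <- function(cohort, observers = default_observers(),
                           window_modes = c("bone", "soft_tissue",
                                            "half_value_mean", "half_value_max"),
                           master_seed = 1L, slab_thickness = 3,
                           exclude = NULL, supersample = 3L) {
  assert_that(nrow(cohort) >= 2, "need at least 2 stones")
  assert_that(length(observers) >= 2, "need at least 2 observers")
  rows <- vector("list", nrow(cohort) * length(observers) * length(window_modes))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    spec <- cohort$spec[[i]]
    ph <- render_phantom(spec, supersample = supersample)
    seed_vox <- pmax(1L, pmin(dim(ph$volume$voxels),
                              as.integer(round(spec$center / spec$voxel_spacing)) + 1L))
    prep <- prepare_planes(ph$volume, seed_vox, slab_thickness)
    for (obs in observers) {
      for (wm in window_modes) {
        cell_seed <- mix_seed(master_seed, cohort$stone_id[i], obs$seed, wm)
        m <- simulate_reading_prepared(prep, wm, obs, cell_seed,
                                       stone_id = cohort$stone_id[i])
        m$passed <- cohort$passed[i]
        k <- k + 1L
        rows[[k]] <- m
      }
    }
  }
  out <- dplyr::bind_rows(rows[seq_len(k)])
  if (!is.null(exclude)) {
    out <- dplyr::anti_join(out, exclude, by = c("observer_id", "window"))
  }
  out
}
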