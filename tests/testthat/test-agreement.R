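test_that("a constant table yields zero components and zero LOAM", {
  tab <- tibble::tibble(stone_id = rep(sprintf("s%d", 1:4), 3),
                        observer_id = rep(c("a", "b", "c"), each = 4),
                        d_largest_mm = 5)
  fit <- fit_two_way(tab)
  expect_equal(c(fit$var_subject, fit$var_observer, fit$var_residual), c(0, 0, 0))
  expect_equal(fit$grand_mean, 5)
  lf <- loam(tab)
  expect_equal(lf$loam, 0)
  expect_equal(c(lf$ci_low, lf$ci_high), c(0, 0))
})

test_that("design preconditions are enforced", {
  tab <- tibble::tibble(stone_id = c("s1", "s1"), observer_id = c("a", "b"),
                        d_largest_mm = c(4, 5))
  expect_error(fit_two_way(tab), ">= 2 subjects")
  dup <- tibble::tibble(stone_id = c("s1", "s1", "s2", "s2"),
                        observer_id = c("a", "a", "a", "b"),
                        d_largest_mm = 1:4)
  expect_error(fit_two_way(dup), "at most once")
})

test_that("balanced ANOVA recovers known variance components", {
  truth <- c(va = 2.25, vb = 0.04, ve = 0.02)
  reps <- 120
  est <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    tab <- simulate_two_way(60, 5, truth["va"], truth["vb"], truth["ve"],
                            seed = 4000 + r)
    f <- suppressWarnings(fit_two_way(tab))
    est[r, ] <- c(f$var_subject, f$var_observer, f$var_residual)
  }
  mc_se <- apply(est, 2, sd) / sqrt(reps)
  expect_lt(abs(mean(est[, 1]) - truth["va"]), 3 * mc_se[1])
  expect_lt(abs(mean(est[, 2]) - truth["vb"]), 3 * mc_se[2])
  expect_lt(abs(mean(est[, 3]) - truth["ve"]), 3 * mc_se[3])
})

test_that("REML path agrees with ANOVA on balanced data", {
  # on a balanced table with interior estimates the two estimators coincide
  for (s in c(17, 18, 19)) {
    tab <- simulate_two_way(40, 4, 2, 0.05, 0.03, seed = s)
    bal <- fit_two_way(tab, method = "anova")
    reml <- fit_two_way(tab, method = "reml")
    expect_equal(reml$var_subject, bal$var_subject, tolerance = 1e-4)
    expect_equal(reml$var_observer, bal$var_observer, tolerance = 1e-3)
    expect_equal(reml$var_residual, bal$var_residual, tolerance = 1e-4)
    expect_equal(reml$grand_mean, bal$grand_mean, tolerance = 1e-6)
  }
  expect_error(fit_two_way(simulate_two_way(5, 3, 1, 0.1, 0.1)[-1, ],
                           method = "anova"), "balanced")
})

test_that("loam follows the (1 - 1/m) algebra and large-m limit", {
  fit <- structure(list(var_subject = 4, var_observer = 0.05,
                        var_residual = 0.03, grand_mean = 5, n = 100, m = 5,
                        method = "anova",
                        ms = list(msb = 100 * 0.05 + 0.03, mse = 0.03,
                                  df_b = 4, df_e = 396)),
                   class = "two_way_fit")
  lf <- loam(fit)
  expect_equal(lf$loam, qnorm(0.975) * sqrt((1 - 1 / 5) * 0.08))
  big <- fit; big$m <- 10000
  big$ms$df_b <- 9999; big$ms$df_e <- 99 * 9999
  expect_equal(loam(big)$loam, 1.96 * sqrt(0.08), tolerance = 1e-3)
})

test_that("loam point estimates center on the truth and CIs cover it", {
  m <- 5; n <- 124
  v_true <- 0.04 / (qnorm(0.975)^2 * (1 - 1 / m))
  loam_true <- qnorm(0.975) * sqrt((1 - 1 / m) * v_true)
  expect_equal(loam_true, 0.2)
  reps <- 200
  est <- numeric(reps); cover <- logical(reps)
  for (r in seq_len(reps)) {
    tab <- simulate_two_way(n, m, 3.24, v_true / 2, v_true / 2, seed = 9000 + r)
    lf <- suppressWarnings(loam(tab))
    est[r] <- lf$loam
    cover[r] <- lf$ci_low <= loam_true && loam_true <= lf$ci_high
    expect_true(lf$ci_low <= lf$loam && lf$loam <= lf$ci_high)
  }
  expect_lt(abs(mean(est) - loam_true), 3 * sd(est) / sqrt(reps))
  expect_gt(mean(cover), 0.90)
})

test_that("loam is scale-equivariant and shift/permutation invariant", {
  tab <- simulate_two_way(30, 4, 1.5, 0.06, 0.04, seed = 55)
  base <- suppressWarnings(loam(tab))
  scaled <- tab; scaled$d_largest_mm <- 3.7 * scaled$d_largest_mm
  lf_s <- suppressWarnings(loam(scaled))
  expect_equal(lf_s$loam, 3.7 * base$loam)
  expect_equal(lf_s$ci_low, 3.7 * base$ci_low)
  expect_equal(lf_s$ci_high, 3.7 * base$ci_high)
  shifted <- tab; shifted$d_largest_mm <- shifted$d_largest_mm + 11
  lf_t <- suppressWarnings(loam(shifted))
  expect_equal(lf_t$loam, base$loam)
  expect_equal(lf_t$grand_mean, base$grand_mean + 11)
  # relabel subjects and observers
  perm <- tab
  perm$stone_id <- paste0("x", perm$stone_id)
  perm$observer_id <- chartr("1234", "4321", perm$observer_id)
  lf_p <- suppressWarnings(loam(perm))
  expect_equal(lf_p$loam, base$loam)
  expect_equal(c(lf_p$ci_low, lf_p$ci_high), c(base$ci_low, base$ci_high))
})

test_that("bootstrap CI path works on unbalanced tables", {
  tab <- simulate_two_way(25, 4, 1.5, 0.06, 0.04, seed = 31)
  tab <- tab[-c(3, 40), ] # unbalance
  lf <- suppressWarnings(loam(tab, n_boot = 60, seed = 2))
  expect_equal(lf$method, "reml")
  expect_equal(lf$ci_method, "bootstrap")
  expect_true(lf$ci_low <= lf$loam & lf$loam <= lf$ci_high)
})

test_that("Bland-Altman deviations center to zero per subject", {
  tab <- tibble::tibble(stone_id = c("s1", "s1", "s2", "s2", "s2"),
                        observer_id = c("a", "b", "a", "b", "c"),
                        d_largest_mm = c(4, 6, 3, 5, 7))
  pts <- bland_altman_points(tab)
  expect_equal(pts$deviation[pts$subject == "s1"], c(-1, 1))
  expect_equal(pts$subject_mean[pts$subject == "s1"], c(5, 5))
  sums <- tapply(pts$deviation, pts$subject, sum)
  expect_equal(as.numeric(sums), c(0, 0))
  # single-observer subjects are excluded with a warning
  tab2 <- dplyr::bind_rows(tab, tibble::tibble(stone_id = "s3",
                                               observer_id = "a",
                                               d_largest_mm = 9))
  expect_warning(pts2 <- bland_altman_points(tab2), "single observer")
  expect_false("s3" %in% pts2$subject)
})

test_that("the SD of deviations is consistent with loam on large tables", {
  tab <- simulate_two_way(800, 5, 1, 0.05, 0.05, seed = 77)
  lf <- suppressWarnings(loam(tab))
  pts <- bland_altman_points(tab)
  expect_equal(sd(pts$deviation), lf$loam / qnorm(0.975), tolerance = 0.05)
})

test_that("tidy and glance methods expose the fit", {
  tab <- simulate_two_way(20, 3, 1, 0.05, 0.05, seed = 3)
  lf <- suppressWarnings(loam(tab))
  td <- tidy(lf)
  expect_true(all(c("term", "estimate", "conf.low") %in% names(td)))
  expect_equal(td$estimate[td$term == "loam"], lf$loam)
  gl <- glance(lf)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, 20)
})
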