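test_that("generators are pure functions of parameters and seed", {
  expect_identical(simulate_facs_cohort(200, seed = 1),
                   simulate_facs_cohort(200, seed = 1))
  expect_identical(simulate_ihc_cohort(50, seed = 2),
                   simulate_ihc_cohort(50, seed = 2))
  expect_identical(simulate_trajectories(5, seed = 3),
                   simulate_trajectories(5, seed = 3))
  expect_identical(simulate_invasion_stack(100, seed = 4),
                   simulate_invasion_stack(100, seed = 4))
  expect_identical(simulate_survival_cohort(50, seed = 5),
                   simulate_survival_cohort(50, seed = 5))
  s1 <- simulate_tissue_sections(misalignment = 1, seed = 6)
  s2 <- simulate_tissue_sections(misalignment = 1, seed = 6)
  expect_identical(s1, s2)
  # and the caller's RNG stream is not disturbed
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(simulate_facs_cohort(10, seed = 9)); b <- runif(1)
  expect_identical(a, b)
})

test_that("zero-noise draws land exactly in their learned threshold band", {
  ref <- simulate_reference_cells(4000, level_sd = 1e-9, seed = 11)
  th <- learn_thresholds(ref, markers = caf_panel("FACS"))
  for (m in caf_panel("FACS")) {
    lev <- discretize_level(ref[[m]], m, th)
    expect_identical(lev, ref[[paste0("level_", m)]], label = m)
  }
})

test_that("facs cohort respects profiles and input validation", {
  cells <- simulate_facs_cohort(1000, proportions = c(1, 0, 0, 0), seed = 12)
  expect_true(all(cells$true_subset == "CAF-S1"))
  expect_true(all(unlist(cells[caf_panel("FACS")]) > 0))
  expect_error(simulate_facs_cohort(100, proportions = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(simulate_facs_cohort(0), "positive")
  expect_error(simulate_facs_cohort(10, level_means = c(2, 2, 6, 8)),
               "increasing")
})

test_that("ihc cohort emits H-scores in range with true labels", {
  ihc <- simulate_ihc_cohort(150, enrichment_mix = c(1, 0, 0, 0), seed = 13)
  expect_true(all(ihc$true_enrichment == "CAF-S1"))
  hs <- unlist(ihc[caf_panel("IHC")])
  expect_true(all(hs >= 0 & hs <= 400))
  expect_error(simulate_ihc_cohort(-5), "positive")
})

test_that("tissue sections carry ground truth and exact landmark pairs", {
  sec <- simulate_tissue_sections(misalignment = 0, seed = 14)
  expect_equal(dim(sec$truth), c(20, 20))
  expect_setequal(names(sec$images),
                  c("FAP", "CD29", "SMA", "FSP1", "EPCAM"))
  # identity misalignment: landmarks coincide, transform recovers identity
  lm <- sec$landmarks$FAP
  expect_equal(lm$x_ref, lm$x_mov)
  fit <- fit_landmark_transform(lm, "affine")
  expect_equal(fit$matrix, diag(3), tolerance = 1e-10)
  expect_lt(fit$residual, 1e-9)
  # all-epithelium layout labels every tile epithelium
  lay <- demo_section_layout(6)
  lay$tiles[] <- "epithelium"
  sec2 <- simulate_tissue_sections(lay, misalignment = 0, seed = 15)
  expect_true(all(sec2$truth == "epithelium"))
  expect_error(simulate_tissue_sections(px_per_um = 0.3, seed = 1),
               "whole number")
})

test_that("trajectory persistence endpoints behave as designed", {
  straight <- simulate_trajectories(5, speed = 10, persistence_param = 1,
                                    dt = 1, duration = 10, seed = 16)
  m <- track_metrics_table(straight)
  expect_equal(m$persistence, rep(1, 5), tolerance = 1e-12)
  expect_equal(m$velocity, rep(10, 5), tolerance = 1e-12)
  # isotropic walk: mean persistence decays with duration toward the
  # random-walk expectation
  ps <- sapply(c(6, 24, 96), function(T) {
    tr <- simulate_trajectories(60, speed = 10, persistence_param = 0,
                                dt = 1, duration = T, seed = 17)
    mean(track_metrics_table(tr)$persistence)
  })
  expect_true(all(diff(ps) < 0))
  # Monte-Carlo reference for an isotropic unit-step walk of 24 steps
  set.seed(18)
  mc <- replicate(400, {
    th <- runif(24, 0, 2 * pi)
    sqrt(sum(cos(th))^2 + sum(sin(th))^2) / 24
  })
  expect_equal(ps[2], mean(mc), tolerance = 0.15)
  expect_error(simulate_trajectories(5, dt = 0), "dt")
  expect_error(simulate_trajectories(5, persistence_param = 2), "persistence")
})

test_that("invasion stack z-law covers degenerate and tail cases", {
  z0 <- simulate_invasion_stack(100, z_law = list(bulk_mean = 0, tail_mass = 0),
                                seed = 19)
  expect_true(all(z0$z == 0))
  st <- simulate_invasion_stack(2000, seed = 20)
  expect_true(all(st$z >= 0 & st$z <= 200))
  expect_error(simulate_invasion_stack(0), "n_cells")
})

test_that("survival cohort honours censoring and effect specification", {
  sv <- simulate_survival_cohort(300, censor_rate = 0, seed = 21)
  expect_true(all(sv$event == 1))
  expect_true(all(sv$time > 0))
  expect_error(simulate_survival_cohort(10, baseline_rate = Inf), "finite")
  expect_error(simulate_survival_cohort(10, strata_effects = c(bogus = 1)),
               "unknown")
  # imposed hazard doubles the event rate for the high-stromal group
  sv2 <- simulate_survival_cohort(4000, c(stromal_high = log(2)),
                                  censor_rate = 0, seed = 22)
  rate_ratio <- mean(sv2$time[sv2$stromal_percent <= 30]) /
    mean(sv2$time[sv2$stromal_percent > 30])
  expect_equal(rate_ratio, 2, tolerance = 0.15)
})

test_that("forward elasticity operator is linear and scales inversely with E", {
  tr <- gaussian_traction_dipole(32, 2)
  tr2 <- vector_field(2 * tr$vx, 2 * tr$vy, tr$spacing, tr$E, tr$nu)
  u <- tfm_forward(tr); u2 <- tfm_forward(tr2)
  expect_equal(u2$vx, 2 * u$vx, tolerance = 1e-12)
  expect_equal(u2$vy, 2 * u$vy, tolerance = 1e-12)
  trE <- vector_field(tr$vx, tr$vy, tr$spacing, 2 * tr$E, tr$nu)
  uE <- tfm_forward(trE)
  expect_equal(uE$vx, u$vx / 2, tolerance = 1e-12)
  # zero traction -> zero displacement
  z <- vector_field(matrix(0, 16, 16), matrix(0, 16, 16), 1)
  expect_true(all(tfm_forward(z)$vx == 0))
  expect_error(vector_field(matrix(0, 4, 4), matrix(0, 4, 4), 1, nu = 0.7),
               "Poisson")
})
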