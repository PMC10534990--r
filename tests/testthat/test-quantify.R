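test_that("sphere volumes reproduce bead and droplet compartments", {
  expect_equal(sphere_volume(117.5), 0.849, tolerance = 1e-3)
  expect_equal(sphere_volume(94.8), 0.446, tolerance = 1e-3)
  expect_equal(sphere_volume(124.07), 1.000, tolerance = 1e-4)
  expect_error(sphere_volume(0), "diameter")
})

test_that("modality selection distinguishes one and two populations", {
  # identical intensities: trivially unimodal
  tr0 <- select_modality(rep(100, 50))
  expect_equal(tr0$modality, 1L)

  # well separated mixture: bimodal with a clean threshold
  x <- with_seed_test(42, c(rnorm(1500, 100, 10), rnorm(1500, 1000, 50)))
  tr <- select_modality(x)
  expect_equal(tr$modality, 2L)
  expect_lt(tr$BIC_2, tr$BIC_1)
  expect_gt(tr$threshold, 130)
  expect_lt(tr$threshold, 850)
  truth <- rep(c(FALSE, TRUE), each = 1500)
  expect_lt(mean((x > tr$threshold) != truth), 0.005)

  # a single Gaussian stays unimodal across seeds
  for (s in 1:20) {
    x1 <- with_seed_test(s, rnorm(3000, 100, 10))
    expect_equal(select_modality(x1)$modality, 1L)
  }

  # too few beads: indeterminate, not an error
  expect_true(select_modality(c(1, 2, 3))$indeterminate)
})

test_that("modality call agrees with an independent mixture implementation", {
  library(mclust)
  x <- with_seed_test(8, c(rnorm(800, 2000, 600), rnorm(1200, 8000, 1400)))
  tr <- select_modality(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(tr$modality, 2L)
  expect_equal(sort(tr$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  # BIC-based preference matches mclust's (sign conventions differ)
  mc1 <- mclust::Mclust(x, G = 1, modelNames = "V", verbose = FALSE)
  expect_equal(unname(tr$BIC_2 < tr$BIC_1),
               unname(as.numeric(mc$bic) > as.numeric(mc1$bic)))
})

test_that("KDE threshold sits at the density minimum between the modes", {
  x <- with_seed_test(10, c(rnorm(2000, 0, 1), rnorm(2000, 10, 1)))
  tr <- select_modality(x)
  expect_equal(tr$modality, 2L)
  expect_lt(abs(tr$threshold - 5), 0.2)
  expect_error(find_threshold(x, list(modality = 1)), "bimodal")
})

test_that("poisson lambda follows -ln(N_neg/N) with range flags", {
  lam <- poisson_lambda(1000, 1000)
  expect_equal(as.numeric(lam), 0)
  expect_equal(attr(lam, "flags"), "all_negative")
  expect_equal(as.numeric(poisson_lambda(500, 1000)), log(2))
  expect_equal(as.numeric(poisson_lambda(3000, 3300)), log(1.1))
  above <- poisson_lambda(0, 500)
  expect_true(is.na(above))
  expect_equal(attr(above, "flags"), "all_positive")
  expect_equal(attr(above, "lambda_lower"), log(500))
  expect_error(poisson_lambda(11, 10), "N_neg")
})

test_that("bead-count quantification needs no compartment volume", {
  d <- study_design()
  expect_equal(concentration_beads(0, d), 0)
  expect_equal(concentration_beads(log(2), d), 3916, tolerance = 1e-4)
  # linear in lambda and N_B, inverse in V_S
  expect_equal(concentration_beads(2 * log(2), d),
               2 * concentration_beads(log(2), d))
  d2 <- study_design(N_B = 2 * 90400)
  expect_equal(concentration_beads(1, d2), 2 * concentration_beads(1, d))
  d3 <- study_design(V_S = 32)
  expect_equal(concentration_beads(1, d3), concentration_beads(1, d) / 2)
  expect_error(study_design(V_S = 0), "positive")
})

test_that("volume-based quantification matches the droplet formula", {
  d <- study_design(V_C = 0.849, D = 5)
  expect_equal(concentration_volume(10000, 20000, d), 4082, tolerance = 1e-4)
  expect_equal(concentration_volume(500, 500, d), 0)
  d1 <- study_design(V_C = 1, D = 1)
  expect_equal(concentration_volume(round(1000 / exp(1)), 1000, d1), 1000,
               tolerance = 1e-3)
})

test_that("bead and volume modes agree when beads exactly tile the sample", {
  # every bead has volume V_C and N_B beads make up V_S = N_B * V_C
  V_C <- 0.446
  N_B <- 5000
  d <- study_design(N_B = N_B, V_S = N_B * V_C * 1e-3, V_C = V_C, D = 1)
  for (frac in c(0.9, 0.5, 0.2)) {
    N_neg <- round(frac * 2000)
    lam <- as.numeric(poisson_lambda(N_neg, 2000))
    expect_equal(concentration_beads(lam, d),
                 concentration_volume(N_neg, 2000, d), tolerance = 1e-12)
  }
})

test_that("detection statistics reproduce the low-concentration limit", {
  d <- study_design()
  ds <- detection_stats(3.18, d, beads_analyzed = 3300)
  expect_equal(ds$expected_targets, 1.9, tolerance = 0.03)
  expect_equal(ds$detection_rate, 0.85, tolerance = 0.01)
  ds2 <- detection_stats(1 / 16, d, beads_analyzed = 90400)
  expect_equal(ds2$expected_targets, 1)
  expect_equal(ds2$detection_rate, 1 - exp(-1))
  expect_error(detection_stats(1, d, beads_analyzed = 1e6), "N_B")
})

test_that("lambda estimation recovers the truth within dPCR sampling error", {
  N <- 5000
  for (lam in c(0.1, 0.7, 2)) {
    errs <- vapply(1:20, function(s) {
      counts <- draw_target_counts(N, lam, seed = 1000 + s)
      as.numeric(poisson_lambda(sum(counts == 0), N)) - lam
    }, numeric(1))
    tol <- 3 * sqrt((exp(lam) - 1) / N)
    expect_lt(max(abs(errs)), tol * 1.5)     # individual draws
    expect_lt(abs(mean(errs)), tol / sqrt(20) * 3)  # no bias
  }
})

test_that("well quantification integrates threshold and Poisson steps", {
  img <- image_spec()
  sim <- simulate_well_intensities(3300, 0.6931, img, seed = 5)
  q <- quantify_well(sim$intensity, positive_control = 5000)
  expect_equal(q$N, 3300)
  # classification against the generating truth: within the <= 0.5%
  # misclassification the intensity modes allow
  expect_lt(abs(q$N_neg - sum(!sim$positive)), 0.005 * q$N)
  expect_equal(q$lambda, -log(q$N_neg / q$N), tolerance = 1e-12)
  expect_equal(q$concentration, q$lambda * 90400 / 16)

  # all-negative well resolved by the positive control
  neg <- with_seed_test(6, rnorm(2000, img$negative_intensity, img$negative_sd))
  qn <- quantify_well(neg, positive_control = 5000)
  expect_equal(qn$lambda, 0)
  expect_true("all_negative" %in% qn$flags)

  # all-positive well is above range, no finite estimate
  pos <- with_seed_test(6, rnorm(2000, img$positive_intensity, img$positive_sd))
  qp <- quantify_well(pos, positive_control = 5000)
  expect_true("above_range" %in% qp$flags)
  expect_true(is.na(qp$concentration))

  # fixed external threshold bypasses the mixture step
  qt <- quantify_well(sim$intensity, threshold = 5000)
  expect_equal(qt$N_neg, sum(sim$intensity <= 5000))

  # Wilson interval brackets the estimate
  qc <- quantify_well(sim$intensity, positive_control = 5000, ci = TRUE)
  expect_lt(qc$lambda_ci[1], qc$lambda)
  expect_gt(qc$lambda_ci[2], qc$lambda)
})

test_that("replicate runs support per-replicate and pooled estimation", {
  img <- image_spec()
  sets <- lapply(1:4, function(s)
    simulate_well_intensities(1000, 0.5, img, seed = 50 + s)$intensity)
  pr <- quantify_run(sets, mode = "per_replicate", positive_control = 5000)
  expect_equal(nrow(pr), 4)
  pooled <- quantify_run(sets, mode = "pooled", positive_control = 5000)
  expect_equal(pooled$N, 4000)
  expect_equal(sum(pr$N_neg), pooled$N_neg, tolerance = 2)
})
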