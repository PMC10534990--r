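test_that("isotherm evaluates the Langmuir form with its limits", {
  expect_equal(langmuir_isotherm(0.0011, 1.1, 0.0011), 0.55)  # half saturation
  expect_equal(langmuir_isotherm(1e9, 1.1, 0.0011), 1.1, tolerance = 1e-8)
  expect_equal(langmuir_isotherm(0.0099, 1.1, 0.0011), 0.99)
  expect_equal(langmuir_isotherm(0, 1.1, 0), 1.1)  # saturation convention
  expect_error(langmuir_isotherm(-1, 1, 1), ">= 0")
})

test_that("kinetics trajectory starts at zero, rises, and saturates", {
  expect_equal(langmuir_kinetics(0, 0.21, 100, 50), 0)
  t <- seq(0, 300, 1)
  # capacity-limited (C0 > b_max) and supply-limited (C0 < b_max) regimes
  for (pars in list(c(b = 40, C = 50), c(b = 150, C = 50))) {
    bt <- langmuir_kinetics(t, 0.21, pars["b"], pars["C"])
    expect_equal(bt[1], 0)
    expect_true(all(diff(bt) >= -1e-12))
    expect_lte(max(bt), min(pars["b"], pars["C"]) + 1e-9)
    expect_equal(bt[length(bt)], min(pars["b"], pars["C"]), tolerance = 1e-6)
  }
  # degenerate C0 = b_max: logistic limit
  expect_equal(langmuir_kinetics(10, 0.5, 50, 50), 50 * 5 / 6, tolerance = 1e-6)
  expect_error(langmuir_kinetics(-1, 0.2, 1, 1), "t must")
  expect_error(langmuir_kinetics(1, -0.2, 1, 1), "parameters")

  # the study's conditions: binding essentially complete by 10 minutes
  b_max <- 13900 * 1.1 / 100
  bt600 <- langmuir_kinetics(600, 0.21, b_max, 50)
  expect_gt(bt600 / min(b_max, 50), 0.99)
})

test_that("noiseless fits recover generating parameters to 3 significant figures", {
  iso <- simulate_isotherm_assay(1.1, 1.1)
  f <- fit_isotherm(iso, ci = "none")
  est <- setNames(f$estimates$estimate, f$estimates$parameter)
  expect_equal(unname(est["q_max"]), 1.1, tolerance = 5e-4)
  expect_equal(unname(est["K_D"]), 1.1, tolerance = 5e-4)

  kin <- simulate_kinetics_assay(q_max = 1.1, K_D = 1.1, k_a = 0.21, C0 = 50,
                                 n_beads = 13900, volume = 100,
                                 times = seq(0, 120, 5))
  kd <- data.frame(t = kin$time_s, bound = kin$bound)
  b_max <- attr(kin, "params")$b_max
  fk <- fit_kinetics(kd, C0 = 50, b_max = b_max, ci = "none")
  expect_equal(fk$estimates$estimate[1], 0.21, tolerance = 5e-4)
  # co-estimating b_max still recovers the rate
  fk2 <- fit_kinetics(kd, C0 = 50, ci = "none")
  est2 <- setNames(fk2$estimates$estimate, fk2$estimates$parameter)
  expect_equal(unname(est2["k_a"]), 0.21, tolerance = 5e-3)

  expect_error(fit_isotherm(data.frame(free = c(1, 2), bound = c(1, 2))),
               "distinct")
  expect_error(fit_kinetics(data.frame(t = 1:3, bound = 1:3), C0 = 1),
               "time points")
})

test_that("kinetics fit is order-invariant and honest on flat data", {
  kin <- simulate_kinetics_assay(q_max = 1.1, K_D = 1.1, k_a = 0.21, C0 = 50,
                                 n_beads = 13900, volume = 100,
                                 times = seq(0, 120, 5), noise_sd = 0.5,
                                 seed = 3)
  kd <- data.frame(t = kin$time_s, bound = kin$bound)
  f1 <- fit_kinetics(kd, C0 = 50, b_max = 152.9, ci = "none")
  shuffled <- kd[with_seed_test(4, sample(nrow(kd))), ]
  f2 <- fit_kinetics(shuffled, C0 = 50, b_max = 152.9, ci = "none")
  expect_equal(f1$estimates$estimate, f2$estimates$estimate)

  flat <- data.frame(t = seq(0, 100, 10), bound = 0)
  ff <- fit_kinetics(flat, C0 = 50, b_max = 100)
  expect_equal(ff$estimates$estimate[1], 0)
  expect_true(isTRUE(ff$degenerate))
})

test_that("isotherm optimum matches a brute-force grid search", {
  iso <- simulate_isotherm_assay(1.1, 1.1, rel_noise = 0.05, seed = 9)
  f <- fit_isotherm(iso, ci = "none")
  grid <- expand.grid(q_max = seq(0.5, 2, length.out = 60),
                      K_D = seq(0.1, 4, length.out = 60))
  rss <- mapply(function(q, k)
    sum((iso$bound - langmuir_isotherm(iso$free, q, k))^2),
    grid$q_max, grid$K_D)
  best <- grid[which.min(rss), ]
  expect_lte(f$rss, min(rss) + 1e-12)
  est <- setNames(f$estimates$estimate, f$estimates$parameter)
  expect_lt(abs(est["q_max"] - best$q_max), 1.5 / 59 + 1e-9)
  expect_lt(abs(est["K_D"] - best$K_D), 3.9 / 59 + 1e-9)
})

test_that("confidence intervals cover the generating parameters", {
  # asymptotic intervals, 100 simulated assays at 5% noise
  hits <- 0L
  n_ok <- 0L
  for (s in 1:100) {
    iso <- simulate_isotherm_assay(1.1, 1.1, rel_noise = 0.05, seed = 200 + s)
    f <- tryCatch(fit_isotherm(iso, ci = "asymptotic"),
                  error = function(e) NULL)
    if (is.null(f)) next
    e <- f$estimates
    n_ok <- n_ok + 1L
    if (e$lower[1] <= 1.1 && 1.1 <= e$upper[1]) hits <- hits + 1L
  }
  expect_gte(n_ok, 95)
  expect_gte(hits / n_ok, 0.85)
  expect_lte(hits / n_ok, 1.0)

  # bootstrap interval brackets the estimate and stays ordered
  iso <- simulate_isotherm_assay(1.1, 1.1, rel_noise = 0.05, seed = 77)
  fb <- fit_isotherm(iso, ci = "bootstrap", nboot = 200, seed = 1)
  e <- fb$estimates
  expect_true(all(e$lower <= e$estimate & e$estimate <= e$upper))
})

test_that("capture fraction solves the conservation equation exactly", {
  input <- 0.0172 * 90400
  cf <- capture_fraction(1.1, 1.1, 90400, input, 200)
  free <- attr(cf, "free")
  # mass conservation to 1e-8 relative
  bound_mass <- 90400 * langmuir_isotherm(free, 1.1, 1.1)
  expect_lt(abs(free * 200 + bound_mass - input) / input, 1e-8)
  expect_gte(cf, 0.99)

  # limits
  expect_equal(as.numeric(capture_fraction(1.1, 0, 90400, 100, 200)), 1,
               tolerance = 1e-9)
  expect_equal(as.numeric(capture_fraction(1.1, 1.1, 0, 100, 200)), 0)

  # monotone: increasing in beads and capacity, decreasing in K_D and volume
  base <- as.numeric(capture_fraction(1.1, 1.1, 50000, 1000, 200))
  expect_gt(as.numeric(capture_fraction(1.1, 1.1, 55000, 1000, 200)), base)
  expect_gt(as.numeric(capture_fraction(1.21, 1.1, 50000, 1000, 200)), base)
  expect_lt(as.numeric(capture_fraction(1.1, 1.65, 50000, 1000, 200)), base)
  expect_lt(as.numeric(capture_fraction(1.1, 1.1, 50000, 1000, 260)), base)
})

test_that("capacity density and absorbance conversions are exact", {
  expect_equal(capacity_density(1.1, 0.446), 2.5, tolerance = 0.02)
  expect_equal(capacity_density(1, 1), 1)
  expect_equal(capacity_density(0.5, 0.446), 1.12, tolerance = 1e-2)
  expect_equal(absorbance_to_conc(c(0, 1, 2.2)), c(0, 50, 110))
})
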