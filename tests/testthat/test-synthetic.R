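test_that("target counts are Poisson draws with the requested mean", {
  expect_identical(draw_target_counts(1000, 0, seed = 1), rep(0L, 1000))
  expect_error(draw_target_counts(10, -1), "lam")

  # fraction of zero-target beads matches the closed-form Poisson mass
  counts <- draw_target_counts(1e5, 1.0, seed = 42)
  p0 <- mean(counts == 0)
  tol <- 3 * sqrt(exp(-1) * (1 - exp(-1)) / 1e5)
  expect_lt(abs(p0 - exp(-1)), tol)

  # the low-concentration condition: 3.18 cp/uL in 16 uL over 90,400 beads
  # puts ~51 targets on the beads
  counts <- draw_target_counts(90400, 0.000563, seed = 42)
  expect_lt(abs(sum(counts > 0) - 3.18 * 16), 3 * sqrt(3.18 * 16))

  # reproducibility
  expect_identical(draw_target_counts(500, 0.5, seed = 9),
                   draw_target_counts(500, 0.5, seed = 9))
})

test_that("bead placement is non-overlapping and reaches monolayer density", {
  radii <- rep(5, 200)
  pos <- with_seed_test(3, beadpcr:::place_beads(200, radii, 110))
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  expect_gte(min(d), 10)                     # no overlap
  expect_lte(max(sqrt(pos$x^2 + pos$y^2)), 105)  # inside the well
  # the study geometry: 3,300 beads of 94.8 um in a 7 mm well is feasible
  pos2 <- with_seed_test(4, beadpcr:::place_beads(3300, rep(47.4, 3300), 3500))
  expect_equal(nrow(pos2), 3300)
  # an impossible request names the achieved count
  expect_error(with_seed_test(5, beadpcr:::place_beads(500, rep(5, 500), 30)),
               "infeasible packing")
})

test_that("rendered wells match their ground truth", {
  # blank image: background only
  ren0 <- render_well_image(bead_population(0), small_img(), seed = 1)
  expect_equal(nrow(ren0$truth), 0)
  expect_true(all(ren0$marker == 500))

  # noiseless render: centre pixel of each bead is its representative
  # intensity above background
  ren <- render_well_image(small_pop(), small_img(), lam = 0, seed = 7)
  expect_equal(nrow(ren$truth), 50)
  for (i in seq_len(10)) {
    centre <- ren$marker[round(ren$truth$y_px[i]) + 1,
                         round(ren$truth$x_px[i]) + 1]
    expect_lt(abs(centre - (ren$truth$marker_intensity[i] + 500)) /
                ren$truth$marker_intensity[i], 0.02)
  }

  # integrated intensity above background equals the sum of the projected
  # sphere integrals A * (2/3) pi R^2 (larger beads keep discretisation
  # error below the 0.5% contract)
  pop <- bead_population(20, 94.8, 0)
  img <- image_spec(width = 400, height = 400, pixel_size = 4.74, noise_sd = 0)
  ren2 <- render_well_image(pop, img, seed = 11)
  total <- sum(ren2$marker - 500)
  expected <- sum(2 / 3 * pi * ren2$truth$radius_px^2 *
                    ren2$truth$marker_intensity)
  expect_lt(abs(total - expected) / expected, 0.005)

  # positivity in truth is targets >= 1 and totals are consistent
  ren3 <- render_well_image(small_pop(), small_img(), lam = 0.8, seed = 3)
  expect_identical(ren3$truth$positive, ren3$truth$targets >= 1L)
  expect_equal(ren3$manifest$n_positive, sum(ren3$truth$positive))
  expect_equal(ren3$manifest$n_targets_total, sum(ren3$truth$targets))

  # bit-reproducible for fixed (spec, seed)
  ren4 <- render_well_image(small_pop(), small_img(), lam = 0.8, seed = 3)
  expect_identical(ren3$marker, ren4$marker)
  expect_identical(ren3$truth, ren4$truth)
})

test_that("positive fraction converges to 1 - exp(-lambda)", {
  lam <- 0.7
  sim <- simulate_well_intensities(1e5, lam, seed = 42)
  p <- mean(sim$positive)
  expected <- 1 - exp(-lam)
  expect_lt(abs(p - expected), 3 * sqrt(expected * (1 - expected) / 1e5))
})

test_that("kinetics assay obeys the initial condition and mass balance", {
  times <- seq(0, 600, 30)
  sim <- simulate_kinetics_assay(q_max = 1.1, K_D = 1.1, k_a = 0.21, C0 = 50,
                                 n_beads = 13900, volume = 100,
                                 times = times)
  expect_equal(sim$bound[1], 0)
  expect_equal(sim$supernatant[1], 50)
  expect_true(all(diff(sim$bound) >= 0))
  # capacity >> input: the supernatant drains to the model asymptote
  b_max <- attr(sim, "params")$b_max
  expect_gt(b_max, 50)
  expect_lt(sim$supernatant[length(times)], 0.01 * 50)
  # absorbance readout: 1 AU = 50 ng/uL
  sim_a <- simulate_kinetics_assay(q_max = 1.1, K_D = 1.1, k_a = 0.21,
                                   C0 = 50, n_beads = 13900, volume = 100,
                                   times = times, absorbance = TRUE)
  expect_equal(sim_a$a260, sim_a$supernatant / 50)
  expect_error(simulate_kinetics_assay(1, 1, 0.2, 50, 100, 10, times,
                                       noise_sd = -1), "noise_sd")
})

test_that("isotherm assay reproduces the equilibrium mass balance", {
  iso <- simulate_isotherm_assay(1.1, 1.1)
  # bound amounts never exceed per-bead share of the input
  expect_true(all(iso$bound <= iso$input * 100 / 13900 + 1e-9))
  # each row satisfies free*V + n*bound = input*V
  lhs <- iso$free * 100 + 13900 * iso$bound
  expect_equal(lhs, iso$input * 100, tolerance = 1e-8)
})

test_that("paired measurements carry the injected bias", {
  d0 <- simulate_paired_measurements(c(10, 100, 1000), sd_x = 0, sd_y = 0)
  expect_equal(d0$method_x, d0$truth)
  expect_equal(d0$method_y, d0$truth)
  d1 <- simulate_paired_measurements(c(10, 100, 1000), bias = 0.06,
                                     sd_x = 0, sd_y = 0)
  expect_equal(log10(d1$method_y) - log10(d1$method_x), rep(0.06, 3))
  expect_error(simulate_paired_measurements(c(1, -1, 2)), "true_concs")
})

test_that("well images survive a TIFF write/read round trip", {
  ren <- render_well_image(small_pop(10), small_img(noise_sd = 10), seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_well_image(ren, dir, "w1")
  expect_true(all(file.exists(paths)))
  back <- read_well_image(paths[["marker"]])
  expect_equal(dim(back), dim(ren$marker))
  expect_lt(max(abs(back - ren$marker)), 1)  # 16-bit quantisation only
  truth <- utils::read.csv(paths[["truth"]])
  expect_equal(nrow(truth), 10)
})
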