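small_cfg <- function(seed = 5, ...) {
  synthetic_config(time = time_grid(100, 300, 20),
                   wavenumbers = seq(1250, 1780, 25), seed = seed, ...)
}

test_that("generation is bit-identical under a fixed seed", {
  g1 <- generate_flash_series(small_cfg())
  g2 <- generate_flash_series(small_cfg())
  expect_identical(flash_cube(g1$dataset), flash_cube(g2$dataset))
  g3 <- generate_flash_series(small_cfg(seed = 6))
  expect_false(identical(flash_cube(g1$dataset), flash_cube(g3$dataset)))
  # ground truth ships with the data
  expect_s3_class(g1$truth$weights, "transition_weights")
  expect_named(g1$truth$models, c("S0->S1", "S1->S2", "S2->S3", "S3->S0"))
  expect_equal(g1$truth$noise_sigma, 5e-6)
  # stochastic output without a seed is refused
  expect_error(synthetic_config(noise_sigma = 1e-6, seed = NULL,
                                time = time_grid(100, 50, 5),
                                wavenumbers = c(1400, 1500)), "seed")
})

test_that("the no-miss noise-free limit reproduces pure transitions", {
  cfg <- small_cfg(kok = kok_params(miss = 0, double_hit = 0),
                   noise_sigma = 0, acceptor = NULL, heat_artifact = NULL)
  g <- generate_flash_series(cfg)
  cube <- flash_cube(g$dataset)
  tt <- times(cfg$time); post <- tt >= 0
  # flash 3 is exactly the S3->S0 model evaluation
  expect_equal(cube[3, post, ],
               evaluate_model(g$truth$models[["S3->S0"]], tt[post]),
               tolerance = 1e-14)
  # pre-flash samples are zero without noise
  expect_equal(max(abs(cube[, !post, ])), 0)
})

test_that("generated noise passes moment-based normality checks", {
  cfg <- synthetic_config(time = time_grid(50, 400, 100),
                          wavenumbers = seq(1200, 1800, 20),
                          noise_sigma = 5e-6, seed = 3)
  g <- generate_flash_series(cfg)
  # pre-flash cells contain pure noise
  z <- as.vector(flash_cube(g$dataset)[, 1:100, ]) / 5e-6
  expect_gt(length(z), 2e4)
  expect_lt(abs(mean(z)), 0.02)
  expect_equal(sd(z), 1, tolerance = 0.02)
  expect_lt(abs(mean(z^3)), 0.05)           # skewness
  expect_lt(abs(mean(z^4) - 3), 0.1)        # excess kurtosis
})

test_that("the arrhenius series generator matches its stated law", {
  d0 <- generate_arrhenius_series(E_act_meV = 310, noise_cv = 0)
  expect_equal(arrhenius_fit(d0)$E_act_meV, 310, tolerance = 1e-10)
  # E = 0 gives a flat series
  dflat <- generate_arrhenius_series(E_act_meV = 0, noise_cv = 0)
  expect_equal(dflat$tau_ox_ms, rep(2.5, nrow(dflat)))
  # lognormal noise has unit mean and the requested cv
  set.seed(1)
  dn <- generate_arrhenius_series(noise_cv = 0.05, n_replicates = 4000,
                                  temperatures_K = 293.15, seed = 2)
  expect_equal(mean(dn$tau_ox_ms), 2.5, tolerance = 0.005)
  expect_equal(sd(dn$tau_ox_ms) / mean(dn$tau_ox_ms), 0.05, tolerance = 0.05)
  expect_error(generate_arrhenius_series(noise_cv = 0.05, seed = NULL),
               "seed")
})

test_that("polarography generation adds reproducible noise to the truth", {
  m <- polarography_model(yields = c(0, 1), n_grid = 40, domain_um = 100,
                          dt_us = 500, flash_spacing_ms = 200,
                          record_post_ms = 150, record_pre_ms = 5)
  g0 <- generate_polarography(m, noise_sigma = 0)
  expect_equal(g0$transients$current,
               simulate_transients(m)$current)
  g1 <- generate_polarography(m, noise_sigma = 1e-3, seed = 4)
  g2 <- generate_polarography(m, noise_sigma = 1e-3, seed = 4)
  expect_identical(g1$transients$current, g2$transients$current)
  expect_equal(g1$truth$tau_ox_ms, 2.5)
  # zero yields + noise-free stays zero
  mz <- polarography_model(yields = 0, n_grid = 40, domain_um = 100,
                           dt_us = 500, flash_spacing_ms = 200,
                           record_post_ms = 150)
  expect_equal(max(abs(generate_polarography(mz)$transients$current)), 0)
})

test_that("the third-flash fixture is sized and labelled as stated", {
  g <- generate_third_flash(n_wavenumbers = 20, dt_us = 60, t_max_ms = 30,
                            noise_frac = 0.1, seed = 9)
  expect_equal(dim(g$data), c(length(seq(0, 30e3, 60)), 20))
  expect_equal(g$truth$taus_us, c(340, 2500, 3100))
  clean <- evaluate_model(g$truth$model, g$times_us)
  expect_equal(g$noise_sigma, 0.1 * max(abs(clean)))
  # noise realisation is seed-stable
  g2 <- generate_third_flash(n_wavenumbers = 20, dt_us = 60, t_max_ms = 30,
                             noise_frac = 0.1, seed = 9)
  expect_identical(g$data, g2$data)
})

test_that("config validation rejects inconsistent kinetic blocks", {
  bad <- default_kinetics()
  bad[["S3->S0"]]$bands <- bad[["S3->S0"]]$bands[1]
  expect_error(synthetic_config(kinetics = bad, noise_sigma = 0,
                                time = time_grid(100, 50, 5),
                                wavenumbers = c(1400, 1500)),
               "one band set per time constant")
  expect_error(band(1500, -2, 1e-5), "positive")
})
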