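small_model <- function(...) {
  polarography_model(yields = c(0, 0, 1, 0.4), n_grid = 60, domain_um = 150,
                     dt_us = 500, tau_ox_ms = 2.5, flash_spacing_ms = 300,
                     record_post_ms = 250, record_pre_ms = 10, ...)
}

test_that("zero yields give identically zero transients", {
  m <- polarography_model(yields = c(0, 0, 0), n_grid = 40, domain_um = 100,
                          dt_us = 500, flash_spacing_ms = 100,
                          record_post_ms = 70, record_pre_ms = 5)
  tr <- simulate_transients(m)
  expect_equal(max(abs(tr$flux_raw)), 0)
  expect_equal(max(abs(tr$current)), 0)
})

test_that("with reflecting boundaries total O2 is conserved", {
  m <- polarography_model(yields = 1, n_grid = 80, domain_um = 100,
                          dt_us = 500, flash_spacing_ms = 100,
                          record_post_ms = 70, electrode = "reflecting")
  tr <- simulate_transients(m)
  # 100 ms >> tau_ox: all of the unit yield has been delivered and must
  # still be in the domain (spec tolerance 0.1%; the solver is exact)
  expect_equal(attr(tr, "final_mass"), 1, tolerance = 1e-3)
  expect_equal(attr(tr, "final_mass"), 1, tolerance = 1e-9)
  # mass is non-decreasing (production only, no sink)
  expect_true(all(diff(attr(tr, "trace")$mass) > -1e-15))
})

test_that("time-integrated electrode flux accounts for all O2 produced", {
  m <- polarography_model(yields = 1, n_grid = 100, domain_um = 50,
                          dt_us = 250, flash_spacing_ms = 30000,
                          record_post_ms = 480)
  # 30 s >> 100 * L^2/D-ish drainage time for a 50 um domain
  f <- attr(simulate_transients(m, 1), "trace")$flux_raw
  integral <- (sum(f) - f[length(f)] / 2) * 250e-6      # trapezoid, f(0) = 0
  expect_equal(integral, 1, tolerance = 0.01)
})

test_that("the high-pass filter has the analytic single-pole behaviour", {
  # step response decays towards zero with the filter time constant
  y <- apply_highpass(rep(1, 400), dt_ms = 1, filter_tau_ms = 100)
  a <- 100 / 101
  expect_equal(y, a^(1:400), tolerance = 1e-12)
  expect_lt(y[400], y[1] * exp(-3.9))

  expect_equal(apply_highpass(rep(0, 50), 1), rep(0, 50))

  # sinusoid gains match |H| = wt/sqrt(1+(wt)^2) (1% at wt = 100, 2% at wt = 1)
  for (wt in c(1, 100)) {
    tau <- 100; om <- wt / tau; dt <- 0.05
    t <- seq(0, 40 * 2 * pi / om, by = dt)
    y <- apply_highpass(sin(om * t), dt, tau)
    gain <- max(y[t > 10 * 2 * pi / om])
    expect_equal(gain, wt / sqrt(1 + wt^2),
                 tolerance = if (wt == 100) 0.01 else 0.02)
  }
  expect_error(apply_highpass(1:5, dt_ms = -1), "positive")
})

test_that("the raw signal is exactly linear in the yields", {
  m1 <- small_model()
  m2 <- small_model(); m2$yields <- 2 * m2$yields
  t1 <- simulate_transients(m1)
  t2 <- simulate_transients(m2)
  expect_equal(t2$flux_raw, 2 * t1$flux_raw, tolerance = 1e-12)
  expect_equal(t2$current, 2 * t1$current, tolerance = 1e-12)
})

test_that("DC is rejected while the pre-filter flux carries the O2 budget", {
  m <- polarography_model(yields = 1, n_grid = 80, domain_um = 100,
                          dt_us = 500, flash_spacing_ms = 5000,
                          record_post_ms = 480)
  tc <- attr(simulate_transients(m, 1), "trace")
  expect_lt(abs(sum(tc$current)) / sum(abs(tc$flux_raw)), 0.005)
})

test_that("a finite-rate (Robin) electrode draws less current than absorbing", {
  ma <- small_model()
  mr <- small_model(electrode = "robin", robin_rate_m_s = 2e-5)
  mr2 <- small_model(electrode = "robin", robin_rate_m_s = 2e-4)
  fa <- max(simulate_transients(ma)$flux_raw)
  fr <- max(simulate_transients(mr)$flux_raw)
  fr2 <- max(simulate_transients(mr2)$flux_raw)
  expect_lt(fr, fa)
  expect_lt(fr, fr2)      # faster surface reduction -> closer to absorbing
  expect_lt(fr2, fa * 1.001)
})

test_that("tau_ox is recovered from simulated transients", {
  tmpl <- small_model()
  obs <- simulate_transients(tmpl)
  away <- small_model(); away$tau_ox_ms <- 6    # start far from the truth
  f <- fit_tau_ox(obs, away)
  expect_equal(f$tau_ox_ms, 2.5, tolerance = 0.01)   # noise-free, <= 1%
  expect_equal(f$scale, 1, tolerance = 1e-3)

  # identifiability: the objective grows away from the optimum on both sides
  expect_gt(f$objective(1.2), f$objective(2.5) + 1e-8)
  expect_gt(f$objective(5.5), f$objective(2.5) + 1e-8)

  # 5% additive noise: within 10%
  peak <- max(abs(obs$current))
  gp <- generate_polarography(tmpl, noise_sigma = 0.05 * peak, seed = 7)
  f5 <- fit_tau_ox(gp$transients, away)
  expect_equal(f5$tau_ox_ms, 2.5, tolerance = 0.1)
  expect_equal(glance(f5)$tau_ox_ms, f5$tau_ox_ms)
})

test_that("model validation catches inconsistent geometry and protocols", {
  expect_error(polarography_model(layer_um = 600, domain_um = 500), "layer")
  expect_error(polarography_model(D_m2_s = 0), "positive")
  expect_error(polarography_model(yields = c(1, -0.1)), "nonnegative")
  expect_error(polarography_model(record_pre_ms = 500, record_post_ms = 500,
                                  flash_spacing_ms = 900), "window")
  m <- small_model(); m$dt_us <- 170     # spacing not a multiple of dt
  expect_error(simulate_transients(m, 1), "multiple")
})
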