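test_that("the rise model evaluates to its closed form", {
  m <- exp_model(340, matrix(1), 0, 1500)
  expect_equal(evaluate_model(m, 0)[1, 1], 0)            # 1 - e^0
  expect_equal(evaluate_model(m, 340)[1, 1], 1 - exp(-1))
  expect_equal(evaluate_model(m, 1e9)[1, 1], 1, tolerance = 1e-12)

  m2 <- toy_model()
  expect_equal(evaluate_model(m2, 0)[1, ], m2$offsets)   # t = 0 -> B
  expect_equal(evaluate_model(m2, 1e9)[1, ],             # asymptote
               rowSums(m2$amplitudes) + m2$offsets, tolerance = 1e-10)
  expect_error(evaluate_model(m2, c(-5, 10)), "times >= 0")
  expect_error(exp_model(c(2500, 340), matrix(0, 2, 2), c(0, 0),
                         c(1400, 1500)), "ascending")
})

test_that("simulate-then-fit recovers any separated-tau model exactly", {
  # property: noise-free data from models with tau ratios >= 3 are recovered
  # to <= 0.1% in tau and <= 1e-6 relative in the DAS
  for (seed in 1:3) {
    set.seed(seed)
    t1 <- exp(runif(1, log(50), log(500)))
    taus <- c(t1, t1 * exp(runif(1, log(3), log(12))))
    truth <- toy_model(taus_us = taus, seed = seed)
    tt <- seq(0, 25 * max(taus), length.out = 1500)
    Y <- evaluate_model(truth, tt)
    fit <- global_fit(Y, tt, truth$wavenumbers,
                      init_taus_us = taus * c(1.8, 0.55))
    expect_equal(fit$taus_us, taus, tolerance = 1e-3)
    expect_lt(max(abs(fit$amplitudes - truth$amplitudes)) /
                max(abs(truth$amplitudes)), 1e-6)
    expect_lt(max(abs(fit$offsets - truth$offsets)) /
                max(abs(truth$amplitudes)), 1e-6)
  }
})

test_that("flat traces yield zero amplitudes and the constant offset", {
  tt <- seq(0, 2e4, by = 100)
  Y <- matrix(3.3e-5, length(tt), 4)
  fit <- suppressWarnings(global_fit(Y, tt, 1:4, init_taus_us = 500))
  expect_equal(max(abs(fit$amplitudes)), 0, tolerance = 1e-12)
  expect_equal(fit$offsets, rep(3.3e-5, 4))
})

test_that("variable projection is self-consistent at the optimum", {
  truth <- toy_model()
  tt <- seq(0, 4e4, by = 60)
  set.seed(4)
  Y <- evaluate_model(truth, tt) + matrix(rnorm(length(tt) * 12, sd = 3e-6),
                                          length(tt))
  fit <- global_fit(Y, tt, truth$wavenumbers, init_taus_us = c(200, 4000))
  # re-solving the linear subproblem at the returned taus reproduces the
  # amplitudes
  keep <- tt >= fit$fit_start_us
  Phi <- cbind(1 - exp(-outer(tt[keep], 1 / fit$taus_us)), 1)
  C <- qr.solve(Phi, Y[keep, ])
  expect_equal(unname(t(C[1:2, ])), unname(fit$amplitudes), tolerance = 1e-10)
  expect_equal(unname(C[3, ]), fit$offsets, tolerance = 1e-10)
  # residual bookkeeping
  expect_equal(fit$residual_norm^2, sum((Y[keep, ] - Phi %*% C)^2),
               tolerance = 1e-8)
})

test_that("more components never fit worse, and invariances hold", {
  truth <- toy_model()
  tt <- seq(0, 4e4, by = 80)
  set.seed(8)
  Y <- evaluate_model(truth, tt) + matrix(rnorm(length(tt) * 12, sd = 4e-6),
                                          length(tt))
  wn <- truth$wavenumbers
  rss <- vapply(list(900, c(200, 4000), c(100, 900, 8000)), function(it)
    suppressWarnings(glance(global_fit(Y, tt, wn, init_taus_us = it,
                                       multi_start = 4, seed = 2)))$rss, 1)
  expect_true(all(diff(rss) <= 1e-12))

  fit2 <- global_fit(Y, tt, wn, init_taus_us = c(200, 4000))
  # wavenumber permutation leaves taus unchanged, permutes DAS
  perm <- sample(length(wn))
  fitp <- global_fit(Y[, perm], tt, wn[perm], init_taus_us = c(200, 4000))
  expect_equal(fitp$taus_us, fit2$taus_us, tolerance = 1e-6)
  expect_equal(fitp$amplitudes[order(perm), ], fit2$amplitudes,
               tolerance = 1e-6)
  # uniform rescaling scales DAS, not taus
  fits <- global_fit(10 * Y, tt, wn, init_taus_us = c(200, 4000))
  expect_equal(fits$taus_us, fit2$taus_us, tolerance = 1e-6)
  expect_equal(fits$amplitudes, 10 * fit2$amplitudes, tolerance = 1e-6)
})

test_that("tau estimates are consistent as noise shrinks", {
  truth <- toy_model()
  tt <- seq(0, 4e4, by = 60)
  clean <- evaluate_model(truth, tt)
  peak <- max(abs(clean))
  err <- vapply(c(0.1, 0.01, 0.001), function(fr) {
    set.seed(21)
    Y <- clean + matrix(rnorm(length(clean), sd = fr * peak), nrow(clean))
    fit <- global_fit(Y, tt, truth$wavenumbers, init_taus_us = c(200, 4000))
    max(abs(fit$taus_us / truth$taus_us - 1))
  }, 1)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-3)
})

test_that("fixed kinetic components are held while their amplitudes float", {
  wn <- seq(1300, 1700, length.out = 15)
  A <- cbind(bands_to_spectrum(wn, band(1400, 30, 5e-5)),
             bands_to_spectrum(wn, band(1600, 25, -4e-5)),
             bands_to_spectrum(wn, band(1500, 20, 3e-5)))
  truth <- exp_model(c(340, 2500, 3100), A, rep(0, 15), wn)
  tt <- seq(0, 8e4, by = 60)
  Y <- evaluate_model(truth, tt)
  fit <- global_fit(Y, tt, wn, init_taus_us = c(150, 1200),
                    fixed_taus_us = 3100)
  expect_equal(fit$fixed, c(FALSE, FALSE, TRUE))
  expect_equal(fit$taus_us[3], 3100)
  expect_equal(fit$taus_us[1:2], c(340, 2500), tolerance = 1e-4)
  expect_equal(fit$amplitudes, A, tolerance = 1e-5)
})

test_that("DAS access, labels and sign convention behave", {
  truth <- toy_model()
  tt <- seq(0, 4e4, by = 80)
  Y <- evaluate_model(truth, tt)
  fit <- global_fit(Y, tt, truth$wavenumbers, init_taus_us = c(250, 3500),
                    labels = c("t_H+", "t_O2"))
  expect_equal(extract_das(fit, "t_O2")$value, truth$amplitudes[, 2],
               tolerance = 1e-5)
  expect_equal(extract_das(fit, 2500)$value, truth$amplitudes[, 2],
               tolerance = 1e-5)   # lookup by tau value
  expect_error(extract_das(fit, "t_slow"), "t_H\\+, t_O2")
  # positive amplitude contributes positively to the final spectrum
  i <- which.max(truth$amplitudes[, 2])
  f_inf <- predict(fit, 1e9)[1, i]
  f_0 <- predict(fit, 0)[1, i]
  expect_gt(f_inf - f_0, 0)
  # pure single-exponential DAS equals its generating spectrum
  m1 <- exp_model(500, truth$amplitudes[, 1, drop = FALSE], truth$offsets,
                  truth$wavenumbers)
  f1 <- global_fit(evaluate_model(m1, tt), tt, truth$wavenumbers,
                   init_taus_us = 900)
  expect_equal(extract_das(f1, 1)$value, truth$amplitudes[, 1],
               tolerance = 1e-6)
  # tidy/glance shapes
  td <- tidy(fit)
  expect_equal(nrow(td), 12 * 3)   # 2 components + offset rows
  expect_true(all(c("component", "wavenumber", "tau_us", "amplitude")
                  %in% names(td)))
  expect_equal(glance(fit)$n_components, 2)
})

test_that("steady-state window averaging matches the model asymptote", {
  # constant signal
  tt <- seq(0, 1.05e6, by = 1000)                 # to 1.05 s, 1 ms sampling
  Yc <- matrix(7e-5, length(tt), 3)
  ss <- steady_state_spectrum(Yc, tt, c(1400, 1500, 1600))
  expect_equal(ss$value, rep(7e-5, 3))

  # all taus <= 25 ms: window mean equals sum(A) + B essentially exactly
  truth <- toy_model(taus_us = c(340, 25000))
  Y <- evaluate_model(truth, tt)
  ss2 <- steady_state_spectrum(Y, tt, truth$wavenumbers)
  expect_equal(ss2$value, rowSums(truth$amplitudes) + truth$offsets,
               tolerance = 1e-5)
  expect_error(steady_state_spectrum(Y[tt < 2e5, ], tt[tt < 2e5],
                                     truth$wavenumbers), "window")
})

test_that("a short record relative to the slowest component warns", {
  tt <- seq(0, 5e4, by = 100)
  truth <- toy_model()
  Y <- evaluate_model(truth, tt)
  expect_warning(global_fit(Y, tt, truth$wavenumbers,
                            init_taus_us = c(300, 25000)), "10x")
})
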