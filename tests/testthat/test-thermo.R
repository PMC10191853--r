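# independent closed-form constants for oracle checks (CODATA, eV-based)
.kB_eV <- 8.617333262e-5
.h_eVs <- 4.135667696e-15

test_that("arrhenius regression recovers a noise-free activation energy", {
  d <- generate_arrhenius_series(E_act_meV = 310, noise_cv = 0)
  f <- arrhenius_fit(d)
  expect_equal(f$E_act_meV, 310, tolerance = 1e-10)
  # prefactor closes the loop: k(T) = A exp(-E/kBT) reproduces 1/tau
  kBT <- 8.617333262e-2 * d$temperature_K
  k_pred <- f$prefactor_per_s * exp(-f$E_act_meV / kBT)
  expect_equal(k_pred, 1e3 / d$tau_ox_ms, tolerance = 1e-8)
  expect_equal(glance(f)$E_act_kcal_mol, 310 / 43.3641, tolerance = 1e-10)
})

test_that("two temperatures interpolate exactly with an undefined CI", {
  d <- generate_arrhenius_series(E_act_meV = 250, noise_cv = 0,
                                 temperatures_K = c(283, 303))
  expect_warning(f <- arrhenius_fit(d), "CI undefined")
  expect_equal(f$E_act_meV, 250, tolerance = 1e-10)
  expect_true(is.na(f$E_act_sigma_meV))
  expect_error(arrhenius_fit(data.frame(temperature_K = 293,
                                        tau_ox_ms = 2.5)), "2 distinct")
})

test_that("the 1-sigma slope CI covers the truth at its nominal rate", {
  # Monte-Carlo coverage oracle: 5% lognormal noise, n = 3, 7 temperatures;
  # the fitted slope should lie within its own 1-sigma CI of 310 meV in at
  # least 2/3 of 100 seed replicates
  covered <- vapply(1:100, function(s) {
    f <- arrhenius_fit(generate_arrhenius_series(noise_cv = 0.05, seed = s))
    abs(f$E_act_meV - 310) <= f$E_act_sigma_meV
  }, TRUE)
  expect_gte(sum(covered), 67)
})

test_that("eyring decomposition matches the independent closed form", {
  a <- eyring_decompose(tau_ms = 2.5, T0_K = 293.15, E_act_meV = 310)
  kBT_meV <- .kB_eV * 293.15 * 1e3
  dG_oracle <- kBT_meV * log((.kB_eV * 293.15 / .h_eVs) / (1 / 2.5e-3))
  expect_equal(a$deltaG_meV, dG_oracle, tolerance = 1e-12)
  expect_equal(round(a$deltaG_meV), 592)

  # reconstructing k from (dG, T) inverts the decomposition exactly
  k_back <- (.kB_eV * 293.15 / .h_eVs) * exp(-a$deltaG_meV / kBT_meV)
  expect_equal(k_back, 400, tolerance = 1e-12)
  expect_equal(enthalpic_limit_tau(a$deltaG_meV, 293.15), 2.5e-3,
               tolerance = 1e-12)

  # conventions: condensed H = E - kBT; identity H = E
  expect_equal(a$H_act_meV, 310 - kBT_meV)
  ai <- eyring_decompose(2.5, 293.15, 310, convention = "identity")
  expect_equal(ai$H_act_meV, 310)
  expect_equal(a$TS_act_meV, a$H_act_meV - a$deltaG_meV)
  expect_lt(a$TS_act_meV, 0)   # entropic slowdown

  # uncertainty propagation: same relative error as E_act
  au <- eyring_decompose(2.5, 293.15, 310, E_act_sigma_meV = 9.3)
  expect_equal(au$H_act_sigma_meV / abs(au$H_act_meV), 9.3 / 310)
  expect_equal(au$TS_act_sigma_meV / abs(au$TS_act_meV), 9.3 / 310)
  expect_equal(au$H_act_sigma_abs_meV, 9.3)

  expect_error(eyring_decompose(1e-12, 293.15, 310), "nonphysical")
})

test_that("kcal/mol and meV anchor values agree within printed rounding", {
  expect_equal(kcal_mol_to_mev(7.1), 310, tolerance = 0.01)
  expect_equal(mev_to_kcal_mol(310), 7.1, tolerance = 0.01)
  expect_equal(mev_to_kcal_mol(kcal_mol_to_mev(2.2)), 2.2)
  expect_equal(kcal_mol_to_mev(6.5), 285, tolerance = 0.02)
})

test_that("a purely enthalpic 310 meV barrier implies sub-microsecond kinetics", {
  tau <- enthalpic_limit_tau(310, 293.15)
  expect_lt(tau, 1e-6)
  # prefactor limit at zero barrier: h / (kB T)
  expect_equal(enthalpic_limit_tau(0, 293.15),
               .h_eVs / (.kB_eV * 293.15), tolerance = 1e-12)
  # monotone in dG, antitone in T
  gs <- seq(100, 600, 50)
  expect_true(all(diff(vapply(gs, enthalpic_limit_tau, 1, T_K = 293.15)) > 0))
  Ts <- seq(273, 320, 5)
  expect_true(all(diff(vapply(Ts, function(T)
    enthalpic_limit_tau(310, T), 1)) < 0))
})

test_that("entropic slowdown is a Boltzmann factor", {
  expect_gt(entropic_slowdown(285, 293.15), 1e4)
  expect_equal(entropic_slowdown(0, 293.15), 1)
  kBT <- .kB_eV * 293.15 * 1e3
  expect_equal(entropic_slowdown(kBT, 293.15), exp(1))
  # multiplicativity at fixed temperature
  expect_equal(entropic_slowdown(150 + 135, 293.15),
               entropic_slowdown(150, 293.15) * entropic_slowdown(135, 293.15))
})

test_that("arrhenius + eyring recovers the generating enthalpy of activation", {
  # world generated from the exact Eyring form (H, S constant); the
  # condensed-phase convention H = E_act - kBT inverts it up to the small
  # curvature of ln(kBT/h) across the temperature window
  kB <- 8.617333262e-2; h <- 4.135667696e-12
  H <- 300; S <- -0.97                       # meV, meV/K
  Ts <- seq(278, 308, 5)
  tau_ms <- h / (kB * Ts) * exp((H - Ts * S) / (kB * Ts)) * 1e3
  fa <- suppressWarnings(
    arrhenius_fit(tibble::tibble(temperature_K = Ts, tau_ox_ms = tau_ms)))
  dec <- eyring_decompose(tau_ms[4], Ts[4], fa$E_act_meV,
                          convention = "condensed")
  expect_equal(dec$H_act_meV, H, tolerance = 2e-3)
  expect_equal(dec$TS_act_meV, Ts[4] * S, tolerance = 2e-3)
  expect_equal(dec$slowdown, exp(abs(Ts[4] * S) / (kB * Ts[4])),
               tolerance = 0.05)
})
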