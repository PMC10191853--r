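#' Arrhenius regression of oxygen-evolution time constants
#'
#' Fits the unweighted ordinary least-squares regression line of
#' `ln(tau_ox)` versus `1/(kB*T)`, whose slope is the activation energy
#' E_act (meV). Replicate time constants at one temperature are averaged on
#' the log scale before the regression (per-temperature mean of ln tau),
#' without weighting by standard deviations. The intercept yields the
#' Arrhenius pre-exponential factor A (s^-1) via `k = A exp(-E_act/kB T)`,
#' `k = 1/tau`. The quoted uncertainty is the 1-sigma confidence interval of
#' the slope.
#'
#' @param data data frame with columns `temperature_K` and `tau_ox_ms`
#'   (replicates as repeated rows per temperature).
#' @return An `arrhenius_fit` object: `E_act_meV`, `E_act_sigma_meV` (NA with
#'   a flag when only two temperatures are available), `prefactor_per_s`,
#'   `lm` (the underlying fit), `n_temperatures`; see [tidy()] / [glance()].
#' @examples
#' d <- generate_arrhenius_series(E_act_meV = 310, seed = 1, noise_cv = 0)
#' arrhenius_fit(d)$E_act_meV
#' @export
arrhenius_fit <- function(data) {
  if (!all(c("temperature_K", "tau_ox_ms") %in% names(data)))
    abort("`data` needs columns `temperature_K` and `tau_ox_ms`.")
  if (any(data$tau_ox_ms <= 0)) abort("all time constants must be positive.")
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(data), .data$temperature_K),
    mean_ln_tau_s = mean(log(.data$tau_ox_ms / 1e3)),
    n = dplyr::n(), .groups = "drop")
  nT <- nrow(agg)
  if (nT < 2) abort("need at least 2 distinct temperatures.")
  x <- 1 / kbt_mev(agg$temperature_K)      # (kB T)^-1 in 1/meV
  fit <- lm(mean_ln_tau_s ~ x, data = data.frame(x = x,
                                                 mean_ln_tau_s = agg$mean_ln_tau_s))
  slope <- unname(coef(fit)[2])            # meV
  intercept <- unname(coef(fit)[1])        # ln tau at infinite T => A = exp(-b)
  sigma <- if (nT >= 3) suppressWarnings(sqrt(vcov(fit)[2, 2])) else NA_real_
  if (nT == 2)
    warn("only two temperatures: exact interpolation, slope CI undefined.")
  structure(list(
    E_act_meV = slope,
    E_act_sigma_meV = sigma,
    prefactor_per_s = exp(-intercept),
    lm = fit,
    data = agg,
    n_temperatures = nT
  ), class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> E_act = %.4g meV (%.3g kcal/mol)",
              x$E_act_meV, mev_to_kcal_mol(x$E_act_meV)))
  if (is.finite(x$E_act_sigma_meV))
    cat(sprintf(" +/- %.2g meV (1 sigma)", x$E_act_sigma_meV))
  cat(sprintf("\n  pre-exponential A = %.4g s^-1, %d temperatures\n",
              x$prefactor_per_s, x$n_temperatures))
  invisible(x)
}

#' @describeIn arrhenius_fit tidy method: slope/intercept table in meV units.
#' @param x an `arrhenius_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.arrhenius_fit <- function(x, ...) {
  tibble::tibble(
    term = c("E_act_meV", "ln_prefactor"),
    estimate = c(x$E_act_meV, -unname(coef(x$lm)[1])),
    std.error = c(x$E_act_sigma_meV,
                  if (x$n_temperatures >= 3)
                    suppressWarnings(sqrt(vcov(x$lm)[1, 1])) else NA_real_)
  )
}

#' @describeIn arrhenius_fit glance method: one-row summary.
#' @exportS3Method generics::glance
glance.arrhenius_fit <- function(x, ...) {
  tibble::tibble(E_act_meV = x$E_act_meV,
                 E_act_kcal_mol = mev_to_kcal_mol(x$E_act_meV),
                 E_act_sigma_meV = x$E_act_sigma_meV,
                 prefactor_per_s = x$prefactor_per_s,
                 n_temperatures = x$n_temperatures,
                 r.squared = suppressWarnings(summary(x$lm))$r.squared)
}

#' @describeIn arrhenius_fit autoplot: the Arrhenius plot with the
#'   regression line (ln tau_ox versus 1/kB*T).
#' @param object an `arrhenius_fit`.
#' @exportS3Method ggplot2::autoplot
autoplot.arrhenius_fit <- function(object, ...) {
  d <- tibble::tibble(x = 1 / kbt_mev(object$data$temperature_K),
                      y = object$data$mean_ln_tau_s)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dotted", colour = "black") +
    ggplot2::labs(x = expression(1 / (k[B] * T) ~ (meV^-1)),
                  y = expression(ln ~ tau[ox] ~ (s))) +
    ggplot2::theme_minimal()
}

#' Eyring transition-state decomposition of a rate constant
#'
#' Decomposes a measured rate `k = 1/tau` at temperature `T` into activation
#' terms using `k = kappa * (kB T / h) * exp(-dG/kB T)` with transmission
#' coefficient `kappa` (fixed 1 by default): the free energy of activation
#' `dG = kB T ln(kappa kB T / (h k))`, the enthalpy of activation `H_act`
#' from the Arrhenius `E_act`, and the entropic term `T * S_act = H_act - dG`
#' (negative when entropy slows the reaction). Two `H_act` conventions are
#' exposed: `"condensed"` (unimolecular condensed phase,
#' `H_act = E_act - kB T`, the default) and `"identity"` (`H_act = E_act`).
#'
#' @param tau_ms time constant (ms) at temperature `T0_K`.
#' @param T0_K reference temperature in kelvin (default 293.15).
#' @param E_act_meV Arrhenius activation energy (meV).
#' @param E_act_sigma_meV optional 1-sigma uncertainty of `E_act`; propagated
#'   to `H_act` and `T0 * S_act` as the same *relative* uncertainty, with the
#'   equal-absolute alternative also reported.
#' @param kappa transmission coefficient (default 1).
#' @param convention `"condensed"` or `"identity"` (see above).
#' @return An `activation_fit` with `deltaG_meV`, `H_act_meV`,
#'   `TS_act_meV` (= H - dG, negative for entropic slowdown),
#'   `S_act_meV_per_K`, `slowdown` (= exp(|TS|/kB T)), `entropic_meV`
#'   (= |dG - H_act|), `entropic_alt_meV` (= |dG - E_act|), uncertainties
#'   `H_act_sigma_meV`, `TS_act_sigma_meV` (relative-uncertainty convention)
#'   and `*_sigma_abs_meV` (equal-absolute alternative).
#' @examples
#' a <- eyring_decompose(tau_ms = 2.5, T0_K = 293.15, E_act_meV = 310)
#' a$deltaG_meV   # ~592 meV
#' a$slowdown     # > 10000
#' @export
eyring_decompose <- function(tau_ms, T0_K = 293.15, E_act_meV,
                             E_act_sigma_meV = NA_real_, kappa = 1,
                             convention = c("condensed", "identity")) {
  convention <- match.arg(convention)
  if (tau_ms <= 0 || T0_K <= 0) abort("`tau_ms` and `T0_K` must be positive.")
  kBT <- kbt_mev(T0_K)
  nu <- kappa * kBT / phys_constants$h_meV_s   # attempt frequency, s^-1
  k <- 1 / (tau_ms / 1e3)                      # s^-1
  if (k >= nu)
    abort(sprintf("nonphysical rate: k = %.3g s^-1 >= kappa*kB*T/h = %.3g s^-1.",
                  k, nu))
  dG <- kBT * log(nu / k)
  H <- switch(convention, condensed = E_act_meV - kBT, identity = E_act_meV)
  TS <- H - dG
  rel <- if (is.finite(E_act_sigma_meV)) E_act_sigma_meV / abs(E_act_meV) else NA_real_
  structure(list(
    tau_ms = tau_ms, T0_K = T0_K, kappa = kappa, convention = convention,
    E_act_meV = E_act_meV, E_act_sigma_meV = E_act_sigma_meV,
    deltaG_meV = dG,
    H_act_meV = H,
    TS_act_meV = TS,
    S_act_meV_per_K = TS / T0_K,
    entropic_meV = abs(dG - H),
    entropic_alt_meV = abs(dG - E_act_meV),
    slowdown = exp(abs(TS) / kBT),
    H_act_sigma_meV = rel * abs(H),
    TS_act_sigma_meV = rel * abs(TS),
    H_act_sigma_abs_meV = E_act_sigma_meV,
    TS_act_sigma_abs_meV = E_act_sigma_meV
  ), class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  cat(sprintf("<activation_fit> tau = %g ms at T0 = %g K (%s convention)\n",
              x$tau_ms, x$T0_K, x$convention))
  cat(sprintf("  dG  = %.4g meV\n  H   = %.4g meV\n  T0*S = %.4g meV (slowdown %.3g)\n",
              x$deltaG_meV, x$H_act_meV, x$TS_act_meV, x$slowdown))
  invisible(x)
}

#' @describeIn eyring_decompose glance method: one-row summary table.
#' @param x an `activation_fit`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.activation_fit <- function(x, ...) {
  tibble::tibble(T0_K = x$T0_K, convention = x$convention,
                 E_act_meV = x$E_act_meV, deltaG_meV = x$deltaG_meV,
                 H_act_meV = x$H_act_meV, TS_act_meV = x$TS_act_meV,
                 entropic_meV = x$entropic_meV, slowdown = x$slowdown,
                 H_act_sigma_meV = x$H_act_sigma_meV,
                 TS_act_sigma_meV = x$TS_act_sigma_meV)
}

#' Reconstruct the rate/time constant implied by a free energy of activation
#'
#' Inverts the Eyring relation: `tau = h / (kappa kB T) * exp(dG / kB T)`.
#' With a purely enthalpic barrier equal to the measured 310 meV activation
#' energy this gives tau well below 1 us — four orders of magnitude faster
#' than the observed millisecond kinetics, which is the entropic-slowdown
#' argument.
#'
#' @param deltaG_meV free energy of activation (meV).
#' @param T_K temperature (K).
#' @param kappa transmission coefficient.
#' @return Time constant in seconds.
#' @examples
#' enthalpic_limit_tau(310, 293.15) * 1e6   # microseconds, << 1
#' @export
enthalpic_limit_tau <- function(deltaG_meV, T_K = 293.15, kappa = 1) {
  if (T_K <= 0 || kappa <= 0) abort("`T_K` and `kappa` must be positive.")
  kBT <- kbt_mev(T_K)
  phys_constants$h_meV_s / (kappa * kBT) * exp(deltaG_meV / kBT)
}

#' Boltzmann slowdown factor of an entropic activation contribution
#'
#' `exp(entropic_meV / kB T)`: the factor by which an unfavourable activation
#' entropy slows the rate relative to a purely enthalpic barrier.
#'
#' @param entropic_meV entropic contribution |T*S_act| to the activation free
#'   energy (meV).
#' @param T_K temperature (K).
#' @return Dimensionless factor.
#' @examples
#' entropic_slowdown(285, 293.15)   # exceeds 10000
#' @export
entropic_slowdown <- function(entropic_meV, T_K = 293.15) {
  if (T_K <= 0) abort("`T_K` must be positive.")
  exp(entropic_meV / kbt_mev(T_K))
}
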