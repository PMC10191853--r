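#' Shared-time-constant multiexponential model
#'
#' The kinetic model of flash-induced absorbance changes:
#' `F_nu(t) = sum_i A_nu_i * (1 - exp(-t / tau_i)) + B_nu`,
#' with time constants `tau_i` shared by all wavenumbers, per-wavenumber
#' amplitudes `A_nu_i` (the decay-associated spectra, DAS) and offsets
#' `B_nu` collecting all changes faster than the time resolution. The rise
#' form is used exactly; decays are represented by negative amplitudes, so a
#' positive `A_nu_i` contributes positively to the final steady-state
#' spectrum `sum_i A_nu_i + B_nu`.
#'
#' @param taus_us time constants in microseconds, positive and strictly
#'   ascending.
#' @param amplitudes matrix `A` (n_wavenumbers x n_components) in delta-OD.
#' @param offsets per-wavenumber offsets `B` (delta-OD).
#' @param wavenumbers wavenumber axis (cm^-1).
#' @param fit_start_us time after the flash where fitting begins (us).
#' @return An `exp_model` object.
#' @examples
#' m <- exp_model(c(340, 2500), matrix(c(1, -1, 2, 1), 2), c(0, 0),
#'                c(1400, 1700))
#' evaluate_model(m, c(0, 340, 1e7))
#' @export
exp_model <- function(taus_us, amplitudes, offsets, wavenumbers,
                      fit_start_us = 9) {
  taus_us <- as.numeric(taus_us)
  if (any(taus_us <= 0)) abort("time constants must be positive.")
  if (is.unsorted(taus_us, strictly = TRUE))
    abort("time constants must be strictly ascending.")
  amplitudes <- as.matrix(amplitudes)
  if (ncol(amplitudes) != length(taus_us))
    abort("amplitude matrix must have one column per time constant.")
  if (nrow(amplitudes) != length(offsets) ||
      nrow(amplitudes) != length(wavenumbers))
    abort("amplitudes, offsets and wavenumbers disagree in length.")
  structure(list(taus_us = taus_us, amplitudes = amplitudes,
                 offsets = as.numeric(offsets),
                 wavenumbers = as.numeric(wavenumbers),
                 fit_start_us = fit_start_us),
            class = "exp_model")
}

#' @param model an `exp_model`.
#' @param times_us nonnegative times (us) at which to evaluate.
#' @rdname exp_model
#' @return `evaluate_model()`: a time x wavenumber matrix of delta-OD.
#' @export
evaluate_model <- function(model, times_us) {
  stopifnot(inherits(model, "exp_model"))
  if (any(times_us < 0)) abort("model evaluation requires times >= 0.")
  Phi <- 1 - exp(-outer(times_us, 1 / model$taus_us))
  Phi %*% t(model$amplitudes) +
    matrix(model$offsets, length(times_us), length(model$offsets),
           byrow = TRUE)
}

# rise-function design matrix: [1 - exp(-t/tau_1), ..., 1] (n_t x (k+1))
varpro_design <- function(t_us, taus_us) {
  cbind(1 - exp(-outer(t_us, 1 / taus_us)), 1)
}

#' Global multiexponential fit producing decay-associated spectra
#'
#' Simultaneous least-squares fit of all wavenumber transients with one
#' shared set of time constants, by variable projection: the nonlinear search
#' runs over log time constants only, while amplitudes and offsets are solved
#' exactly as a linear subproblem at every evaluation. Samples before
#' `fit_start_us` after the flash (default 9 us) are excluded from the
#' objective.
#'
#' @param data time x wavenumber matrix of absorbance changes (OD), or the
#'   list returned by [transition_data()].
#' @param times_us time axis (us, 0 at flash); ignored when `data` carries
#'   its own grid.
#' @param wavenumbers wavenumber axis; ignored when `data` carries its own.
#' @param init_taus_us initial values for the free time constants (us);
#'   their number sets the free component count.
#' @param fixed_taus_us optional time constants held fixed during the fit
#'   (their amplitudes remain free linear parameters) — e.g. an acceptor-side
#'   component whose time constant is known from another transition's
#'   analysis.
#' @param fit_start_us start of the fitted window (us after flash).
#' @param multi_start number of additional log-spaced random starts (0 = use
#'   only `init_taus_us`); best residual wins.
#' @param seed RNG seed for the multi-start draws (required if
#'   `multi_start > 0`).
#' @param labels optional character vector naming each component (ascending
#'   tau order), e.g. `c("t_H+", "t_O2")`.
#' @param max_iter maximum optimiser iterations.
#' @return A `das_fit` object with elements `taus_us` (ascending),
#'   `amplitudes` (wavenumber x component DAS matrix), `offsets`,
#'   `wavenumbers`, `residual_norm`, `residuals_by_wavenumber`,
#'   `convergence`, `n_eval`; see [tidy.das_fit()], [glance.das_fit()],
#'   [extract_das()], [autoplot.das_fit()].
#' @examples
#' t <- seq(0, 2e4, by = 50)
#' truth <- exp_model(c(340, 2500), cbind(c(1, 2), c(-1, 1)) * 1e-4,
#'                    c(0, 0), c(1400, 1700))
#' y <- evaluate_model(truth, t)
#' fit <- global_fit(y, t, c(1400, 1700), init_taus_us = c(200, 4000))
#' fit$taus_us
#' @export
global_fit <- function(data, times_us = NULL, wavenumbers = NULL,
                       init_taus_us, fixed_taus_us = NULL, fit_start_us = 9,
                       multi_start = 0, seed = NULL, labels = NULL,
                       max_iter = 2000) {
  if (is.list(data) && !is.data.frame(data) && !is.matrix(data)) {
    times_us <- times(data$time)
    wavenumbers <- as.numeric(data$wavenumbers)
    data <- data$data
  }
  data <- as.matrix(data)
  if (length(times_us) != nrow(data))
    abort("`times_us` length must equal nrow(data).")
  if (is.null(wavenumbers)) wavenumbers <- seq_len(ncol(data))
  if (length(wavenumbers) != ncol(data))
    abort("`wavenumbers` length must equal ncol(data).")
  k <- length(init_taus_us)
  k_fix <- length(fixed_taus_us)
  if (k < 1) abort("need at least one free component.")
  if (any(c(init_taus_us, fixed_taus_us) <= 0))
    abort("initial and fixed time constants must be positive.")

  keep <- times_us >= fit_start_us
  if (sum(keep) < k + k_fix + 2)
    abort("too few samples at or after `fit_start_us` to fit the model.")
  t_fit <- times_us[keep]
  Y <- data[keep, , drop = FALSE]
  t_span <- max(t_fit)
  if (t_span < 10 * max(init_taus_us))
    warn(sprintf(paste0("data span %.3g us covers less than 10x the largest ",
                        "initial time constant (%.3g us); slow components ",
                        "may be poorly determined."), t_span,
                 max(init_taus_us)))

  rss_of <- function(log_tau) {
    tau <- c(exp(log_tau), fixed_taus_us)
    Phi <- varpro_design(t_fit, tau)
    C <- tryCatch(qr.solve(Phi, Y), error = function(e) NULL)
    if (is.null(C)) return(.Machine$double.xmax)
    sum((Y - Phi %*% C)^2)
  }

  starts <- list(log(init_taus_us))
  if (multi_start > 0) {
    if (is.null(seed)) abort("`seed` is required when multi_start > 0.")
    rng <- local({ set.seed(seed); lapply(seq_len(multi_start), function(i)
      sort(stats::runif(k, log(max(fit_start_us, t_fit[2] - t_fit[1])),
                        log(t_span))))
    })
    starts <- c(starts, rng)
  }

  best <- NULL
  n_eval <- 0L
  for (s in starts) {
    if (k == 1) {
      opt <- optim(s, rss_of, method = "Brent",
                   lower = s - log(1e4), upper = s + log(1e4),
                   control = list(maxit = max_iter))
      n_eval <- n_eval + opt$counts[1]
    } else {
      # Nelder-Mead, restarted at its own solution until no improvement:
      # guards against premature simplex collapse on flat valleys
      opt <- optim(s, rss_of, method = "Nelder-Mead",
                   control = list(maxit = max_iter, reltol = 1e-14))
      n_eval <- n_eval + opt$counts[1]
      repeat {
        re <- optim(opt$par, rss_of, method = "Nelder-Mead",
                    control = list(maxit = max_iter, reltol = 1e-14))
        n_eval <- n_eval + re$counts[1]
        improved <- re$value < opt$value * (1 - 1e-12)
        opt <- re
        if (!improved) break
      }
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (best$convergence != 0)
    warn(sprintf("optimiser did not fully converge (code %d); returning best fit found (rss = %.4g).",
                 best$convergence, best$value))

  tau_all <- c(exp(best$par), fixed_taus_us)
  is_fixed <- c(rep(FALSE, k), rep(TRUE, k_fix))
  ord <- order(tau_all)
  tau_hat <- tau_all[ord]
  is_fixed <- is_fixed[ord]
  kk <- k + k_fix
  if (kk > 1 && any(diff(tau_hat) / tau_hat[-kk] < 0.05))
    warn("degenerate components: some fitted time constants differ by < 5%.")
  Phi <- varpro_design(t_fit, tau_hat)
  C <- qr.solve(Phi, Y)                      # (kk+1) x n_wn
  R <- Y - Phi %*% C
  A <- t(C[seq_len(kk), , drop = FALSE])     # n_wn x kk, already tau-ordered
  if (!is.null(labels) && length(labels) != kk)
    abort("`labels` must have one entry per component (free and fixed).")
  structure(list(
    taus_us = tau_hat,
    fixed = is_fixed,
    amplitudes = A,
    offsets = as.numeric(C[kk + 1, ]),
    wavenumbers = as.numeric(wavenumbers),
    fit_start_us = fit_start_us,
    labels = labels,
    residual_norm = sqrt(sum(R^2)),
    residuals_by_wavenumber = sqrt(colSums(R^2)),
    n_obs = length(Y), n_times = nrow(Y),
    convergence = best$convergence, n_eval = as.integer(n_eval),
    init_taus_us = init_taus_us
  ), class = "das_fit")
}

#' @export
print.das_fit <- function(x, ...) {
  lab <- if (is.null(x$labels)) rep("", length(x$taus_us)) else
    paste0(" (", x$labels, ")")
  cat("<das_fit> global multiexponential fit\n")
  cat(sprintf("  %d components over %d wavenumbers, %d time samples (from %g us)\n",
              length(x$taus_us), length(x$wavenumbers), x$n_times,
              x$fit_start_us))
  for (i in seq_along(x$taus_us))
    cat(sprintf("  tau_%d = %.4g us%s\n", i, x$taus_us[i], lab[i]))
  cat(sprintf("  residual norm %.4g OD\n", x$residual_norm))
  invisible(x)
}

#' Turn a das_fit into its model object or evaluate it
#'
#' @param object,... a `das_fit`; `newdata` times in us.
#' @param newdata times (us) to evaluate at; defaults to an error if missing.
#' @return `as_exp_model()` the equivalent [exp_model()]; `predict()` a
#'   time x wavenumber matrix.
#' @export
as_exp_model <- function(object) {
  stopifnot(inherits(object, "das_fit"))
  exp_model(object$taus_us, object$amplitudes, object$offsets,
            object$wavenumbers, object$fit_start_us)
}

#' @rdname as_exp_model
#' @export
predict.das_fit <- function(object, newdata, ...) {
  evaluate_model(as_exp_model(object), newdata)
}

#' Extract one decay-associated spectrum
#'
#' @param fit a `das_fit`.
#' @param component component index (ascending-tau order), a component label
#'   (if the fit was labelled), or a time constant in us (nearest component
#'   on the log scale, required to lie within 20%).
#' @return A [spectrum_tbl()] of the `A_nu_i` column.
#' @export
extract_das <- function(fit, component) {
  stopifnot(inherits(fit, "das_fit"))
  k <- length(fit$taus_us)
  idx <- NULL
  if (is.character(component)) {
    if (is.null(fit$labels))
      abort("fit has no component labels; use an index.")
    idx <- match(component, fit$labels)
    if (is.na(idx))
      abort(sprintf("unknown component label '%s'; available: %s.",
                    component, paste(fit$labels, collapse = ", ")))
  } else if (component >= 1 && component <= k && component == round(component)) {
    idx <- as.integer(component)
  } else {
    d <- abs(log(fit$taus_us / component))
    idx <- which.min(d)
    if (d[idx] > log(1.2))
      abort(sprintf("no component with tau within 20%% of %g us; taus: %s.",
                    component, paste(signif(fit$taus_us, 4), collapse = ", ")))
  }
  spectrum_tbl(fit$wavenumbers, fit$amplitudes[, idx])
}

#' Offset spectrum of a das_fit
#'
#' The `B_nu` spectrum of all flash-induced changes faster than the time
#' resolution.
#'
#' @param fit a `das_fit`.
#' @return A [spectrum_tbl()].
#' @export
offset_spectrum <- function(fit) {
  stopifnot(inherits(fit, "das_fit"))
  spectrum_tbl(fit$wavenumbers, fit$offsets)
}

#' @describeIn global_fit tidy method: one row per (wavenumber, component)
#'   with the DAS amplitude; the offset appears as component `"offset"`.
#' @param x a `das_fit`.
#' @exportS3Method generics::tidy
tidy.das_fit <- function(x, ...) {
  k <- length(x$taus_us)
  comp <- if (is.null(x$labels)) paste0("tau_", seq_len(k)) else x$labels
  das <- tidyr::expand_grid(component = factor(comp, levels = c(comp, "offset")),
                            wavenumber = x$wavenumbers)
  das$tau_us <- rep(x$taus_us, each = length(x$wavenumbers))
  # column-major vectorisation = wavenumber fastest within component,
  # matching expand_grid order above
  das$amplitude <- as.vector(x$amplitudes)
  off <- tibble::tibble(component = factor("offset", levels = levels(das$component)),
                        wavenumber = x$wavenumbers, tau_us = NA_real_,
                        amplitude = x$offsets)
  dplyr::bind_rows(tibble::as_tibble(das), off)
}

#' @describeIn global_fit glance method: one-row fit summary.
#' @exportS3Method generics::glance
glance.das_fit <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$taus_us),
    n_obs = x$n_obs,
    residual_norm = x$residual_norm,
    rss = x$residual_norm^2,
    convergence = x$convergence,
    n_eval = x$n_eval
  )
}

#' Plot decay-associated spectra
#'
#' @param object a `das_fit`.
#' @param include_offset also draw the offset spectrum `B_nu`.
#' @param ... unused.
#' @return A ggplot: DAS amplitude (micro-OD) versus wavenumber, one colour
#'   per kinetic component, wavenumber axis reversed as conventional for IR.
#' @exportS3Method ggplot2::autoplot
autoplot.das_fit <- function(object, include_offset = FALSE, ...) {
  td <- tidy(object)
  if (!include_offset) td <- td[td$component != "offset", ]
  ggplot2::ggplot(td, ggplot2::aes(.data$wavenumber, .data$amplitude * 1e6,
                                   colour = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)),
                  y = expression(Delta * A ~ (mu * OD)),
                  colour = "component") +
    ggplot2::theme_minimal()
}

#' Steady-state difference spectrum by late-window averaging
#'
#' Averages each wavenumber's transient over a late time window (default
#' 300 ms to 1 s after the flash), the conventional estimate of the stable
#' flash-induced difference spectrum. For the rise model this converges to
#' `sum_i A_nu_i + B_nu`.
#'
#' @param data time x wavenumber matrix, [transition_data()] list, or a
#'   [flash_series()] (then `flash` selects which flash).
#' @param times_us time axis when `data` is a bare matrix.
#' @param wavenumbers wavenumber axis when `data` is a bare matrix.
#' @param window_start_ms,window_end_ms averaging window (ms after flash).
#' @param flash flash number when `data` is a flash series.
#' @return A [spectrum_tbl()].
#' @export
steady_state_spectrum <- function(data, times_us = NULL, wavenumbers = NULL,
                                  window_start_ms = 300, window_end_ms = 1000,
                                  flash = 1) {
  if (inherits(data, "flash_series")) {
    cube <- flash_cube(data)
    times_us <- times(attr(data, "time"))
    wavenumbers <- as.numeric(attr(data, "wavenumbers"))
    data <- cube[flash, , ]
  } else if (is.list(data) && !is.data.frame(data) && !is.matrix(data)) {
    times_us <- times(data$time)
    wavenumbers <- as.numeric(data$wavenumbers)
    data <- data$data
  }
  data <- as.matrix(data)
  sel <- times_us >= window_start_ms * 1e3 & times_us <= window_end_ms * 1e3
  if (!any(sel))
    abort(sprintf("no samples in the %g-%g ms window (data end at %g ms).",
                  window_start_ms, window_end_ms, max(times_us) / 1e3))
  if (is.null(wavenumbers)) wavenumbers <- seq_len(ncol(data))
  spectrum_tbl(wavenumbers, colMeans(data[sel, , drop = FALSE]))
}
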