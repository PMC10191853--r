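#' Kok-cycle flash-advance parameters
#'
#' Parameters of the standard Kok model of S-state advancement of the
#' oxygen-evolving complex: on each saturating flash a centre advances one
#' S-state with probability `1 - miss - double_hit`, stays put with the miss
#' probability (alpha), or advances twice with the double-hit probability
#' (beta). Dark-adapted photosystems start synchronised in the dark-stable
#' S1 state, the default initial population.
#'
#' @param miss scalar miss probability alpha in `[0, 1]`.
#' @param double_hit double-hit probability beta; `miss + double_hit <= 1`.
#' @param initial_populations probabilities over (S0, S1, S2, S3), summing
#'   to 1; default pure S1.
#' @param per_state_miss optional 4-vector of per-state miss probabilities
#'   overriding the scalar `miss` (indexed by current state S0..S3).
#' @return A `kok_params` object.
#' @examples
#' kok_params(miss = 0.1)
#' @export
kok_params <- function(miss = 0.1, double_hit = 0,
                       initial_populations = c(0, 1, 0, 0),
                       per_state_miss = NULL) {
  if (!is.null(per_state_miss)) {
    if (length(per_state_miss) != 4 || any(per_state_miss < 0))
      abort("`per_state_miss` must be a nonnegative 4-vector.")
  }
  alpha <- per_state_miss %||% rep(miss, 4)
  if (miss < 0 || double_hit < 0 || any(alpha + double_hit > 1))
    abort("need 0 <= miss, double_hit and miss + double_hit <= 1 (each state).")
  p0 <- as.numeric(initial_populations)
  if (length(p0) != 4 || any(p0 < 0) || abs(sum(p0) - 1) > 1e-12)
    abort("`initial_populations` must be 4 nonnegative values summing to 1.")
  structure(list(miss = miss, double_hit = double_hit,
                 alpha = alpha, initial_populations = p0),
            class = "kok_params")
}

#' @export
print.kok_params <- function(x, ...) {
  cat(sprintf("<kok_params> miss = %s, double hit = %g, start = (%s)\n",
              paste(signif(x$alpha, 3), collapse = "/"), x$double_hit,
              paste(signif(x$initial_populations, 3), collapse = ", ")))
  invisible(x)
}

s_state_names <- c("S0", "S1", "S2", "S3")
transition_names <- c("S0->S1", "S1->S2", "S2->S3", "S3->S0")

#' Single-flash S-state advancement matrix
#'
#' Column-stochastic 4x4 matrix M with `M[i, j] = P(S_j -> S_i)` on one flash:
#' stay with the miss probability, advance one state (cyclic, S3 wraps to S0)
#' with `1 - miss - double_hit`, advance two with `double_hit`.
#'
#' @param params a [kok_params()].
#' @return 4x4 numeric matrix, columns = input states S0..S3.
#' @examples
#' kok_transition_matrix(kok_params(miss = 0))  # cyclic permutation
#' @export
kok_transition_matrix <- function(params) {
  stopifnot(inherits(params, "kok_params"))
  M <- matrix(0, 4, 4, dimnames = list(s_state_names, s_state_names))
  b <- params$double_hit
  for (j in 1:4) {
    a <- params$alpha[j]
    M[j, j] <- M[j, j] + a
    M[(j %% 4) + 1, j] <- M[(j %% 4) + 1, j] + 1 - a - b
    M[((j + 1) %% 4) + 1, j] <- M[((j + 1) %% 4) + 1, j] + b
  }
  M
}

#' Propagate S-state populations across a flash train
#'
#' @param params a [kok_params()].
#' @param n_flashes number of flashes applied (>= 0).
#' @return Tibble with columns `flash` (0 = dark-adapted, before any flash)
#'   and `S0`..`S3`; row `flash = k` holds the populations after `k` flashes.
#' @examples
#' kok_propagate(kok_params(miss = 0.1), 4)
#' @export
kok_propagate <- function(params, n_flashes) {
  stopifnot(inherits(params, "kok_params"))
  n_flashes <- as.integer(n_flashes)
  if (n_flashes < 0) abort("`n_flashes` must be >= 0.")
  M <- kok_transition_matrix(params)
  P <- matrix(NA_real_, n_flashes + 1, 4,
              dimnames = list(NULL, s_state_names))
  P[1, ] <- params$initial_populations
  for (k in seq_len(n_flashes)) P[k + 1, ] <- M %*% P[k, ]
  dplyr::bind_cols(tibble::tibble(flash = 0:n_flashes),
                   tibble::as_tibble(P))
}

#' Expected per-flash S-state transition weights
#'
#' For each flash n and transition j in (S0->S1, S1->S2, S2->S3, S3->S0),
#' the expected fraction of centres executing that transition on flash n.
#' A double hit executes two consecutive transitions and both legs are
#' credited: `W[n, j] = p[j] * (1 - alpha) + p[j-1] * beta`, with p the
#' populations before flash n. These weights are the design matrix of the
#' flash-to-transition deconvolution.
#'
#' @inheritParams kok_propagate
#' @return Tibble of class `transition_weights`: columns `flash` (1-based)
#'   and the four transitions. `weights_matrix()` extracts the bare matrix.
#' @examples
#' kok_transition_weights(kok_params(miss = 0.1), 4)
#' @export
kok_transition_weights <- function(params, n_flashes) {
  n_flashes <- as.integer(n_flashes)
  if (n_flashes < 1) abort("`n_flashes` must be >= 1.")
  pops <- kok_propagate(params, n_flashes)
  P <- as.matrix(pops[, s_state_names])
  b <- params$double_hit
  W <- matrix(0, n_flashes, 4, dimnames = list(NULL, transition_names))
  for (n in seq_len(n_flashes)) {
    p <- P[n, ]  # populations before flash n
    for (j in 1:4) {
      jm1 <- ((j - 2) %% 4) + 1
      W[n, j] <- p[j] * (1 - params$alpha[j]) + p[jm1] * b
    }
  }
  structure(dplyr::bind_cols(tibble::tibble(flash = seq_len(n_flashes)),
                             tibble::as_tibble(W)),
            class = c("transition_weights", class(tibble::tibble())))
}

#' @param w a `transition_weights` tibble.
#' @rdname kok_transition_weights
#' @export
weights_matrix <- function(w) {
  m <- as.matrix(w[, transition_names])
  rownames(m) <- NULL
  m
}

#' Flash-pattern of oxygen yields
#'
#' O2 is released on the S3->S0 transition, so the expected O2 yield of flash
#' n is its S3->S0 transition weight: a damped period-four oscillation with
#' maxima on flashes 3, 7, 11, ... for dark-adapted (S1) samples.
#'
#' @inheritParams kok_propagate
#' @param normalize divide yields by their long-run (steady-state) mean
#'   `(1 - miss + double_hit) / 4`.
#' @return Tibble with columns `flash`, `yield`.
#' @examples
#' o2_yield_pattern(kok_params(miss = 0.1), 12)
#' @export
o2_yield_pattern <- function(params, n_flashes, normalize = FALSE) {
  w <- kok_transition_weights(params, n_flashes)
  y <- w[["S3->S0"]]
  if (normalize) {
    ss <- (1 - mean(params$alpha) + params$double_hit) / 4
    y <- y / ss
  }
  tibble::tibble(flash = w$flash, yield = y)
}

#' Deconvolve a flash series into pure S-state-transition datasets
#'
#' Solves, for every (time, wavenumber) cell independently but through one
#' shared pseudo-inverse, the ordinary least-squares problem
#' `data[n] ~ sum_j W[n, j] * transition_j`, turning flash-indexed spectra
#' into time-resolved difference spectra of the four S-state transitions.
#' Exact recovery when the data were mixed from the same weights.
#'
#' @param fs a [flash_series()] with at least 4 flashes.
#' @param weights a [kok_transition_weights()] result (or bare n x 4 matrix)
#'   with one row per flash in `fs`.
#' @param max_condition largest acceptable condition number of the weight
#'   matrix before the deconvolution is refused.
#' @return A tibble of class `transition_series` with columns `transition`,
#'   `time_us`, `wavenumber`, `dod`; attributes carry the axes, the weight
#'   matrix, its condition number and the residual norm.
#' @examples
#' p <- kok_params(miss = 0.08)
#' tg <- time_grid(6, 30, 3); wg <- wavenumber_grid(c(1400, 1544, 1700))
#' arr <- array(rnorm(10 * 30 * 3, sd = 1e-5), dim = c(10, 30, 3))
#' fs <- flash_series(arr, tg, wg)
#' ts <- deconvolve_transitions(fs, kok_transition_weights(p, 10))
#' @export
deconvolve_transitions <- function(fs, weights, max_condition = 1e8) {
  stopifnot(inherits(fs, "flash_series"))
  W <- if (is.matrix(weights)) weights else weights_matrix(weights)
  nf <- attr(fs, "n_flashes")
  if (nf < 4) abort("deconvolution needs at least 4 flashes.")
  if (nrow(W) != nf)
    abort(sprintf("weight matrix has %d rows but dataset has %d flashes.",
                  nrow(W), nf))
  sv <- svd(W)$d
  if (sv[4] <= 0 || sv[1] / sv[4] > max_condition)
    abort(paste0(
      "weight matrix is rank-deficient or too ill-conditioned (condition ",
      sprintf("%.3g", if (sv[4] > 0) sv[1] / sv[4] else Inf),
      "); deconvolution would amplify noise — reconsider the Kok ",
      "parameters (miss/double-hit/initial populations)."))
  cube <- flash_cube(fs)
  dm <- dim(cube)
  D <- matrix(cube, nrow = nf)           # flashes x (time*wavenumber)
  X <- qr.solve(W, D)                    # 4 x (time*wavenumber)
  resid_norm <- sqrt(sum((D - W %*% X)^2))
  tg <- attr(fs, "time"); wg <- attr(fs, "wavenumbers")
  tb <- tidyr::expand_grid(
    transition = factor(transition_names, levels = transition_names),
    time_us = times(tg), wavenumber = as.numeric(wg))
  tb$dod <- as.vector(aperm(array(X, dim = c(4, dm[2], dm[3])), c(3, 2, 1)))
  structure(tibble::as_tibble(tb),
            time = tg, wavenumbers = wg, weights = W,
            condition = sv[1] / sv[4], residual_norm = resid_norm,
            class = c("transition_series", class(tibble::tibble())))
}

#' Extract one transition's time x wavenumber data matrix
#'
#' @param ts a `transition_series` from [deconvolve_transitions()].
#' @param transition one of `"S0->S1"`, `"S1->S2"`, `"S2->S3"`, `"S3->S0"`.
#' @return List with `data` (time x wavenumber matrix), `time` and
#'   `wavenumbers` grids.
#' @export
transition_data <- function(ts, transition) {
  stopifnot(inherits(ts, "transition_series"))
  transition <- match.arg(transition, transition_names)
  tg <- attr(ts, "time"); wg <- attr(ts, "wavenumbers")
  sub <- ts[ts$transition == transition, ]
  m <- matrix(sub$dod, nrow = tg$n_samples, byrow = TRUE)
  list(data = m, time = tg, wavenumbers = wg)
}
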