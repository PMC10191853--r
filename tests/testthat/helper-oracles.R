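# Exhaustive outcome-tree oracle for the Kok flash chain: walks every
# (stay / single advance / double advance)^n path, accumulating state
# populations after each flash and per-flash transition weights (both legs
# of a double hit credited). Independent of the matrix implementation.
kok_enumerate <- function(params, n_flashes) {
  pops <- matrix(0, n_flashes + 1, 4)
  W <- matrix(0, n_flashes, 4)
  beta <- params$double_hit
  recurse <- function(state, flash, p) {   # state 0-based (S0..S3)
    pops[flash + 1, state + 1] <<- pops[flash + 1, state + 1] + p
    if (flash == n_flashes || p == 0) return(invisible())
    a <- params$alpha[state + 1]
    one <- 1 - a - beta
    recurse(state, flash + 1, p * a)
    # single advance executes transition index state+1
    W[flash + 1, state + 1] <<- W[flash + 1, state + 1] + p * one
    recurse((state + 1) %% 4, flash + 1, p * one)
    # double hit executes two consecutive transitions
    W[flash + 1, state + 1] <<- W[flash + 1, state + 1] + p * beta
    W[flash + 1, ((state + 1) %% 4) + 1] <<-
      W[flash + 1, ((state + 1) %% 4) + 1] + p * beta
    recurse((state + 2) %% 4, flash + 1, p * beta)
  }
  for (s0 in 0:3) recurse(s0, 0L, params$initial_populations[s0 + 1])
  list(populations = pops, weights = W)
}

# small two-component rise model on a short wavenumber grid
toy_model <- function(taus_us = c(340, 2500), n_wn = 12, seed = 1,
                      offset = TRUE) {
  set.seed(seed)
  wn <- seq(1300, 1740, length.out = n_wn)
  A <- sapply(seq_along(taus_us), function(i)
    bands_to_spectrum(wn, band(1350 + 150 * i + 20 * i^2, 40, 6e-5 * (-1)^i)) +
      bands_to_spectrum(wn, band(1600 - 90 * i, 25, 4e-5)))
  B <- if (offset) bands_to_spectrum(wn, band(1500, 60, 1.2e-5)) else rep(0, n_wn)
  exp_model(taus_us, A, B, wn)
}
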