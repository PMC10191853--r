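#' Sampling grid of a flash-triggered time axis
#'
#' Time is measured in microseconds with zero at the laser flash; pre-flash
#' samples carry negative times. The instrument default is one analogue-to-
#' digital conversion every 6 us, 6 ms before and 130 ms after each flash.
#'
#' @param dt_us sampling interval in microseconds (> 0).
#' @param n_samples total number of samples per flash.
#' @param pre_flash_samples number of samples recorded before the flash;
#'   the flash instant (time 0) is sample `pre_flash_samples + 1`.
#' @return A `time_grid` object; `times()` returns the derived axis (us).
#' @examples
#' tg <- time_grid(dt_us = 6, n_samples = 100, pre_flash_samples = 10)
#' head(times(tg))
#' @export
time_grid <- function(dt_us, n_samples, pre_flash_samples = 0) {
  if (!is.numeric(dt_us) || length(dt_us) != 1 || dt_us <= 0)
    abort("`dt_us` must be a single positive number.")
  n_samples <- as.integer(n_samples)
  pre_flash_samples <- as.integer(pre_flash_samples)
  if (n_samples < 1) abort("`n_samples` must be >= 1.")
  if (pre_flash_samples < 0 || pre_flash_samples >= n_samples)
    abort("`pre_flash_samples` must be in [0, n_samples).")
  structure(
    list(dt_us = dt_us, n_samples = n_samples,
         pre_flash_samples = pre_flash_samples,
         t0_index = pre_flash_samples + 1L),
    class = "time_grid"
  )
}

#' @param x a `time_grid`.
#' @rdname time_grid
#' @export
times <- function(x) {
  stopifnot(inherits(x, "time_grid"))
  (seq_len(x$n_samples) - x$t0_index) * x$dt_us
}

#' @export
print.time_grid <- function(x, ...) {
  tt <- times(x)
  cat(sprintf("<time_grid> %d samples, dt = %g us, t in [%g, %g] us (0 at flash)\n",
              x$n_samples, x$dt_us, min(tt), max(tt)))
  invisible(x)
}

#' Ordered wavenumber axis
#'
#' Wavenumbers are stored ascending; readers normalise descending input and
#' reorder the data accordingly. Values must lie within the declared
#' instrument range (default mid-IR, 400 to 4000 cm^-1).
#'
#' @param values numeric wavenumbers (cm^-1), strictly monotone.
#' @param range declared instrument range, length-2 numeric.
#' @return Numeric vector of class `wavenumber_grid`, sorted ascending, with
#'   a `descending_input` attribute recording whether input was reversed.
#' @examples
#' wavenumber_grid(c(1800, 1500, 1200))  # normalised to ascending
#' @export
wavenumber_grid <- function(values, range = c(400, 4000)) {
  values <- as.numeric(values)
  if (length(values) < 1) abort("wavenumber grid must be non-empty.")
  if (anyNA(values)) abort("wavenumber grid contains NA.")
  d <- diff(values)
  desc <- FALSE
  if (length(values) > 1) {
    if (all(d > 0)) {
      # already ascending
    } else if (all(d < 0)) {
      values <- rev(values)
      desc <- TRUE
    } else {
      abort("wavenumber grid must be strictly monotone.")
    }
  }
  if (any(values < range[1] | values > range[2]))
    abort(sprintf("wavenumbers outside declared instrument range [%g, %g] cm^-1.",
                  range[1], range[2]))
  structure(values, class = "wavenumber_grid", descending_input = desc,
            range = range)
}

#' Flash-series spectro-kinetic dataset
#'
#' The pipeline's central container: absorbance changes (OD) indexed by flash
#' number, time after flash (us) and wavenumber (cm^-1), held as a long tibble
#' with one row per (flash, time, wavenumber) cell plus grid metadata in
#' attributes. `flash_series()` builds one from a 3D array
#' (flash x time x wavenumber); `flash_cube()` recovers that array.
#'
#' @param data 3D numeric array, dimensions flash x time x wavenumber.
#' @param time a [time_grid()].
#' @param wavenumbers a [wavenumber_grid()] (or numeric coerced to one).
#' @param flash_spacing_ms spacing between consecutive flashes (ms).
#' @param metadata free-form named list.
#' @return A tibble of class `flash_series` with columns `flash`, `time_us`,
#'   `wavenumber`, `dod`.
#' @examples
#' tg <- time_grid(6, 20, 2)
#' wg <- wavenumber_grid(c(1400, 1500, 1600))
#' arr <- array(rnorm(4 * 20 * 3), dim = c(4, 20, 3))
#' fs <- flash_series(arr, tg, wg)
#' dim(flash_cube(fs))
#' @export
flash_series <- function(data, time, wavenumbers, flash_spacing_ms = 700,
                         metadata = list()) {
  if (!is.array(data) || length(dim(data)) != 3)
    abort("`data` must be a 3D array (flash x time x wavenumber).")
  if (!inherits(wavenumbers, "wavenumber_grid"))
    wavenumbers <- wavenumber_grid(wavenumbers)
  dm <- dim(data)
  if (dm[1] < 1) abort("dataset must contain at least one flash.")
  if (dm[2] != time$n_samples)
    abort(sprintf("time axis mismatch: array has %d samples, grid %d.",
                  dm[2], time$n_samples))
  if (dm[3] != length(wavenumbers))
    abort(sprintf("wavenumber axis mismatch: array has %d, grid %d.",
                  dm[3], length(wavenumbers)))
  bad <- which(!is.finite(data))
  if (length(bad))
    abort(sprintf("dataset contains %d non-finite cells (first indices: %s).",
                  length(bad), paste(head(bad, 5), collapse = ", ")))
  tt <- times(time)
  wn <- as.numeric(wavenumbers)
  tb <- tidyr::expand_grid(flash = seq_len(dm[1]), time_us = tt,
                           wavenumber = wn)
  # aperm puts wavenumber fastest, then time, then flash — matching
  # expand_grid's iteration order above
  tb$dod <- as.vector(aperm(data, c(3, 2, 1)))
  new_flash_series(tb, time, wavenumbers, flash_spacing_ms, metadata)
}

new_flash_series <- function(tb, time, wavenumbers, flash_spacing_ms,
                             metadata) {
  structure(
    tibble::as_tibble(tb),
    time = time, wavenumbers = wavenumbers,
    n_flashes = max(tb$flash), flash_spacing_ms = flash_spacing_ms,
    metadata = metadata,
    class = c("flash_series", class(tibble::tibble()))
  )
}

#' @param fs a `flash_series`.
#' @rdname flash_series
#' @export
flash_cube <- function(fs) {
  stopifnot(inherits(fs, "flash_series"))
  tg <- attr(fs, "time"); wg <- attr(fs, "wavenumbers")
  nf <- attr(fs, "n_flashes")
  arr <- aperm(array(fs$dod, dim = c(length(wg), tg$n_samples, nf)),
               c(3, 2, 1))
  dimnames(arr) <- list(NULL, NULL, NULL)
  arr
}

#' @rdname flash_series
#' @export
n_flashes <- function(fs) attr(fs, "n_flashes")

#' Per-wavenumber spectrum container
#'
#' A spectrum is a tibble with columns `wavenumber` (cm^-1) and `value`
#' (OD or delta-OD). Arithmetic between spectra requires identical grids.
#'
#' @param wavenumber numeric wavenumbers (cm^-1).
#' @param value per-wavenumber amplitudes.
#' @return A tibble of class `spectrum_tbl`.
#' @examples
#' spectrum_tbl(c(1400, 1500), c(1e-5, -2e-5))
#' @export
spectrum_tbl <- function(wavenumber, value) {
  if (length(wavenumber) != length(value))
    abort("`wavenumber` and `value` must have equal length.")
  structure(tibble::tibble(wavenumber = as.numeric(wavenumber),
                           value = as.numeric(value)),
            class = c("spectrum_tbl", class(tibble::tibble())))
}

check_same_grid <- function(a, b, what = "spectra") {
  if (nrow(a) != nrow(b) || any(abs(a$wavenumber - b$wavenumber) > 1e-9))
    abort(sprintf("%s are not on identical wavenumber grids.", what))
  invisible(TRUE)
}
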