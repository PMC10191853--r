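#' Acceptor-side correction of an oxygen-evolution DAS
#'
#' The millisecond DAS of the S3->S0 transition is a sum of the
#' oxygen-evolution step and a minor quinone (acceptor-side) contribution.
#' Because the two-electron acceptor-side chemistry oscillates with flash
#' parity, the same millisecond contribution appears in the S1->S2 transition
#' (both on odd flashes for dark-adapted samples), whose 3.1 ms DAS can
#' therefore be subtracted pointwise, without further scaling.
#'
#' @param das_target [spectrum_tbl()] to correct (e.g. the ms DAS of S3->S0).
#' @param das_reference [spectrum_tbl()] on the identical wavenumber grid
#'   (e.g. the 3.1 ms DAS of S1->S2).
#' @return A [spectrum_tbl()] `target - reference`, with a `correction`
#'   attribute recording kind, scaling (fixed at 1) and provenance.
#' @examples
#' a <- spectrum_tbl(c(1400, 1700), c(2e-5, -1e-5))
#' b <- spectrum_tbl(c(1400, 1700), c(5e-6, 5e-6))
#' acceptor_side_correct(a, b)
#' @export
acceptor_side_correct <- function(das_target, das_reference) {
  check_same_grid(das_target, das_reference, "target and reference DAS")
  out <- spectrum_tbl(das_target$wavenumber,
                      das_target$value - das_reference$value)
  attr(out, "correction") <- list(
    kind = "acceptor_side", scaling = 1,
    provenance = "pointwise subtraction of acceptor-side reference DAS, unscaled")
  out
}

#' Remove a flash-synchronised heat-artifact spectrum
#'
#' Subtracts `scale * artifact_spectrum` from every post-flash time sample of
#' each flash: the artifact is modelled as a flash-synchronised,
#' time-independent additive spectrum (the simplest model consistent with a
#' single deposited correction spectrum), with optional per-flash scaling.
#' Pre-flash baseline samples are untouched.
#'
#' @param fs a [flash_series()].
#' @param artifact_spectrum [spectrum_tbl()] on the dataset's wavenumber grid.
#' @param per_flash_scale numeric scale per flash (default 1 for all).
#' @return The corrected [flash_series()].
#' @export
heat_artifact_correct <- function(fs, artifact_spectrum,
                                  per_flash_scale = NULL) {
  stopifnot(inherits(fs, "flash_series"))
  wg <- as.numeric(attr(fs, "wavenumbers"))
  if (length(artifact_spectrum$wavenumber) != length(wg) ||
      any(abs(artifact_spectrum$wavenumber - wg) > 1e-9))
    abort("artifact spectrum is not on the dataset's wavenumber grid.")
  nf <- attr(fs, "n_flashes")
  scale <- per_flash_scale %||% rep(1, nf)
  if (length(scale) != nf || any(!is.finite(scale)))
    abort("`per_flash_scale` must be one finite value per flash.")
  cube <- flash_cube(fs)
  art <- artifact_spectrum$value
  post <- times(attr(fs, "time")) >= 0
  for (n in seq_len(nf))
    cube[n, post, ] <- cube[n, post, ] -
      matrix(scale[n] * art, sum(post), dim(cube)[3], byrow = TRUE)
  out <- flash_series(cube, attr(fs, "time"), attr(fs, "wavenumbers"),
                      attr(fs, "flash_spacing_ms"), attr(fs, "metadata"))
  attr(out, "correction") <- list(kind = "heat_artifact",
                                  per_flash_scale = scale)
  out
}
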