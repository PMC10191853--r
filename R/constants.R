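## Physical constants (CODATA 2018), energies carried in meV throughout.

#' Physical constants used for activation thermodynamics
#'
#' Boltzmann and Planck constants in meV-based units, plus the
#' kcal/mol to meV conversion. All activation energies in this package are
#' carried in meV; `kB_meV * T` is the thermal energy in meV at temperature
#' `T` (kelvin) and `h_meV_s / (kB_meV * T)` (s) is the reciprocal of the
#' transition-state attempt frequency kB*T/h.
#'
#' @format A named list with elements `kB_meV` (meV/K), `h_meV_s` (meV s),
#'   `meV_per_kcal_mol` (meV per kcal/mol).
#' @examples
#' phys_constants$kB_meV * 293.15   # thermal energy at 20 C, ~25.3 meV
#' 7.1 * phys_constants$meV_per_kcal_mol  # ~310 meV
#' @export
phys_constants <- list(
  kB_meV = 8.617333262e-2,
  h_meV_s = 4.135667696e-12,
  meV_per_kcal_mol = 43.3641
)

# thermal energy in meV at temperature T (K)
kbt_mev <- function(T) phys_constants$kB_meV * T

#' Convert between kcal/mol and meV
#'
#' @param x numeric values to convert.
#' @return Converted numeric vector.
#' @examples
#' kcal_mol_to_mev(7.1)  # ~307.9 meV (paper-scale rounding gives 310)
#' @export
kcal_mol_to_mev <- function(x) x * phys_constants$meV_per_kcal_mol

#' @rdname kcal_mol_to_mev
#' @export
mev_to_kcal_mol <- function(x) x / phys_constants$meV_per_kcal_mol
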