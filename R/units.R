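# Internal unit system: length nm, force pN, energy pN nm, friction pN ps/nm,
# viscosity pN ps/nm^2, mechanical time ps, biological (kinetic) time s.
# 1 pN nm = 1e-21 J, so k_B T at 300 K is ~4.14 pN nm and 1 kJ/mol is
# ~1.66 pN nm per molecule.

#' Physical constants used by the unit system
#'
#' @format A named list with elements `kB` (Boltzmann constant, J/K),
#'   `NA_avogadro` (1/mol), `kjmol_pnnm` (pN nm per kJ/mol).
#' @export
unit_constants <- list(
  kB          = 1.380649e-23,   # J/K (exact, SI)
  NA_avogadro = 6.02214076e23,  # 1/mol (exact, SI)
  kjmol_pnnm  = 1e3 / 6.02214076e23 * 1e21  # = 1.66054 pN nm per kJ/mol
)

#' Thermal energy in internal units
#'
#' @param T temperature in kelvin.
#' @return k_B T in pN nm.
#' @examples
#' kB_T(300)  # ~4.14 pN nm
#' @export
kB_T <- function(T = 300) {
  unit_constants$kB * T * 1e21
}

#' Convert molar energies to per-molecule mechanical energies
#'
#' @param x energy in kJ/mol.
#' @return energy in pN nm.
#' @export
kjmol_to_pnnm <- function(x) x * unit_constants$kjmol_pnnm

#' @rdname kjmol_to_pnnm
#' @export
pnnm_to_kjmol <- function(x) x / unit_constants$kjmol_pnnm

#' Convert a molar bimolecular rate constant to a per-pair subcell propensity
#'
#' A bimolecular rate constant k (1/(s M)) acting inside one cubic subcell of
#' side `l_SV` gives a per-reactant-pair propensity c = k / (N_A l_SV^3).
#' The `"rounded"` mode instead multiplies k by 1e-7, the conventional rounded
#' conversion for a 250-nm subcell that reproduces the standard printed
#' propensity tables digit-for-digit (the exact conversion differs by ~6%).
#'
#' @param k_molar rate constant in 1/(s M).
#' @param l_SV subcell side in nm.
#' @param mode `"rounded"` (default) or `"exact"`.
#' @return per-pair propensity in 1/s.
#' @examples
#' convert_bimolecular_rate(1.5e7)                  # 1.5 /s
#' convert_bimolecular_rate(1.5e7, mode = "exact")  # ~1.59 /s
#' @export
convert_bimolecular_rate <- function(k_molar, l_SV = 250,
                                     mode = c("rounded", "exact")) {
  mode <- match.arg(mode)
  if (any(k_molar <= 0) || l_SV <= 0) {
    stop("rate constant and subcell size must be positive")
  }
  if (mode == "rounded") {
    return(k_molar * 1e-7)
  }
  # l_SV^3 in litres: 1 nm^3 = 1e-24 L
  vol_litre <- (l_SV^3) * 1e-24
  k_molar / (unit_constants$NA_avogadro * vol_litre)
}
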