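#' Physical constants and unit conversions
#'
#' All user-facing quantities in pvolr use a fixed unit system: lengths in
#' Angstrom, pressures in GPa, energies in Hartree.  The conversion factors
#' below are derived from CODATA-2018 values of the Hartree energy
#' (4.3597447222071e-18 J) and the Avogadro constant (6.02214076e23 / mol).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{gpa_A3_to_hartree}{energy of 1 GPa * 1 Angstrom^3, in Hartree}
#'   \item{A3_to_cm3_per_mol}{molar volume of 1 Angstrom^3 per molecule, in cm^3/mol}
#'   \item{hartree_to_kj_per_mol}{1 Hartree in kJ/mol}
#'   \item{deg_to_rad, rad_to_deg}{angle conversion factors}
#' }
#' @export
pv_units <- list(
  # 1 GPa * 1 A^3 = 1e9 Pa * 1e-30 m^3 = 1e-21 J
  gpa_A3_to_hartree = 1e-21 / 4.3597447222071e-18,
  # N_A * 1e-24 cm^3
  A3_to_cm3_per_mol = 6.02214076e23 * 1e-24,
  hartree_to_kj_per_mol = 4.3597447222071e-18 * 6.02214076e23 / 1000,
  deg_to_rad = pi / 180,
  rad_to_deg = 180 / pi
)

#' Convert a pressure-volume product to energy
#'
#' Converts \code{P * V} expressed in GPa * Angstrom^3 into Hartree, the
#' energy scale on which electronic-structure backends report \code{E_el},
#' so that the enthalpy \code{H = E_el + P * V} can be summed directly.
#'
#' @param pv numeric vector, pressure-volume products in GPa * Angstrom^3.
#' @return numeric vector of energies in Hartree.
#' @examples
#' convert_pv_energy(82.4477)  # 1 GPa acting on a 82.45 A^3 molecule
#' @export
convert_pv_energy <- function(pv) {
  stopifnot(is.numeric(pv), all(is.finite(pv)))
  pv * pv_units$gpa_A3_to_hartree
}
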