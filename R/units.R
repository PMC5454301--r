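#' Physical constants and unit conversions
#'
#' The engine works in MD "real" units (Angstrom, fs, amu, kcal/mol, K, e);
#' these helpers convert reported quantities to SI at the analysis boundary.
#'
#' @name units
NULL

#' Boltzmann constant in kcal mol^-1 K^-1
#' @export
kB_kcalmol <- 0.0019872041

# amu (A/fs)^2 -> kcal/mol
.mvsq2e <- 2390.0573615334906

# 1 kcal/mol in Joule (per molecule)
.kcalmol2J <- 6.9477e-21

#' Convert a heat flux from internal units to SI
#'
#' @param j_internal flux in kcal mol^-1 A^-2 fs^-1
#' @return flux in W m^-2
#' @export
flux_to_si <- function(j_internal) j_internal * .kcalmol2J / (1e-20 * 1e-15)

#' Thermal conductivity from flux and temperature gradient
#'
#' K = J / |dT/dz|: the ratio of the heat flux to the temperature gradient
#' in the segment it crosses.
#'
#' @param j_si flux in W m^-2
#' @param slope_K_per_A temperature gradient in K A^-1
#' @return conductivity in W m^-1 K^-1
#' @export
conductivity_si <- function(j_si, slope_K_per_A) {
  if (abs(slope_K_per_A) == 0) stop("zero temperature gradient: conductivity undefined")
  j_si / (abs(slope_K_per_A) * 1e10)
}

#' Thermal resistance from a temperature drop and a flux
#'
#' @param delta_T temperature drop in K
#' @param j_si flux in W m^-2
#' @return resistance in m^2 K W^-1
#' @export
resistance_si <- function(delta_T, j_si) delta_T / j_si

#' Convert a conductivity and thickness to a slab resistance (and back)
#'
#' R = d / K with d in Angstrom converted to metres.
#'
#' @param K_si conductivity, W m^-1 K^-1
#' @param thickness_A slab thickness in Angstrom
#' @return resistance in m^2 K W^-1
#' @export
conductivity_to_resistance <- function(K_si, thickness_A) (thickness_A * 1e-10) / K_si

#' @rdname conductivity_to_resistance
#' @param R_si resistance in m^2 K W^-1
#' @export
resistance_to_conductivity <- function(R_si, thickness_A) (thickness_A * 1e-10) / R_si

#' Specific volume of a periodic cell
#'
#' @param volume_A3 cell volume in cubic Angstrom
#' @param mass_amu total mass in amu
#' @return specific volume in cm^3 g^-1
#' @export
specific_volume <- function(volume_A3, mass_amu) {
  # 1 A^3 = 1e-24 cm^3; 1 amu = 1.66053906660e-24 g
  volume_A3 * 1e-24 / (mass_amu * 1.66053906660e-24)
}
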