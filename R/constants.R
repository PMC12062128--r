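# Shared physico-chemical constants: molar masses, elemental formulas and
# carbon fractions of the compounds handled by the physiology calculus and
# the batch simulator.

#' Molar masses of media components and fermentation analytes
#'
#' Named vector of molar masses in g/mol. Ammonium sulfate is listed under
#' `as` (132.14 g/mol, two NH4+ per salt).
#'
#' @format Named numeric vector.
#' @export
MOLAR_MASS <- c(
  glucose  = 180.156,
  xylose   = 150.130,
  eg       = 62.07,   # ethylene glycol C2H6O2
  ga       = 76.05,   # glycolic acid  C2H4O3
  glycerol = 92.094,
  nh4      = 18.039,
  as       = 132.14,  # (NH4)2SO4
  co2      = 44.009,
  o2       = 31.998,
  n        = 14.007,
  c        = 12.011
)

#' Carbon mass fractions of substrates and products
#'
#' Gram carbon per gram compound, from the elemental formulas
#' (glucose C6H12O6, xylose C5H10O5, EG C2H6O2, GA C2H4O3, glycerol C3H8O3).
#'
#' @format Named numeric vector.
#' @export
CARBON_FRACTION <- c(
  glucose  = 6 * 12.011 / 180.156,
  xylose   = 5 * 12.011 / 150.130,
  eg       = 2 * 12.011 / 62.07,
  ga       = 2 * 12.011 / 76.05,
  glycerol = 3 * 12.011 / 92.094
)

#' Carbon atoms per molecule for Cmol bookkeeping
#' @format Named integer vector.
#' @export
CARBON_ATOMS <- c(glucose = 6L, xylose = 5L, eg = 2L, ga = 2L,
                  glycerol = 3L, co2 = 1L)

# Generic yeast biomass CH1.8O0.5N0.2 per Cmol (ash-free).
biomass_elements <- function() c(C = 1, H = 1.8, O = 0.5, N = 0.2)

#' Biomass molar mass per Cmol
#'
#' Gram dry cell weight per Cmol for the CH1.8O0.5N0.2 composition
#' (24.626 g/Cmol). Used to interconvert gram and Cmol biomass yields and to
#' derive the nitrogen content of biomass (11.4% w/w).
#'
#' @param composition element -> count vector over C,H,O,N (per Cmol).
#' @return Molar mass in g per Cmol.
#' @export
biomass_cmol_mass <- function(composition = biomass_elements()) {
  w <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)
  sum(w[names(composition)] * composition)
}

#' Nitrogen mass fraction of biomass
#'
#' @inheritParams biomass_cmol_mass
#' @return g N per g dry cell weight (0.1138 for CH1.8O0.5N0.2).
#' @export
biomass_n_fraction <- function(composition = biomass_elements()) {
  14.007 * composition[["N"]] / biomass_cmol_mass(composition)
}

#' Carbon mass fraction of biomass
#'
#' @inheritParams biomass_cmol_mass
#' @return g C per g dry cell weight.
#' @export
biomass_c_fraction <- function(composition = biomass_elements()) {
  12.011 * composition[["C"]] / biomass_cmol_mass(composition)
}
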