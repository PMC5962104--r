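#' Chemical parameter set
#'
#' Elemental composition, chemical potentials and water content used to
#' convert between energies, masses and wet weights. Defaults are realistic
#' for most animal taxa; the water content of structure may be overridden per
#' phylum or class via `water_frac`.
#'
#' Wet weight is computed as `Ww = d_Vw L^3 + E w_E / mu_E`: wet structure
#' mass plus reserve mass, with wet structure density
#' `d_Vw = d_V / (1 - water_frac)` (g/cm^3).
#'
#' @param d_V dry mass density of structure (g/cm^3).
#' @param water_frac water mass fraction of structure, in `[0, 1)`.
#' @param mu_E,mu_V chemical potentials of reserve and structure (J/mol C).
#' @param w_E,w_V molar weights of reserve and structure (g/mol C).
#' @param n_food,n_reserve,n_structure,n_feces relative elemental frequencies
#'   (H, O, N per C) of the four organic compounds.
#' @return an object of class `deb_chemical` (named list).
#' @export
chemical_params <- function(d_V = 0.1, water_frac = 0.9,
                            mu_E = 550000, mu_V = 500000,
                            w_E = 23.9, w_V = 23.9,
                            n_food = c(H = 1.8, O = 0.5, N = 0.15),
                            n_reserve = c(H = 1.8, O = 0.5, N = 0.15),
                            n_structure = c(H = 1.8, O = 0.5, N = 0.15),
                            n_feces = c(H = 1.8, O = 0.5, N = 0.15)) {
  if (water_frac < 0 || water_frac >= 1) stop("`water_frac` must be in [0, 1)", call. = FALSE)
  for (v in list(d_V, mu_E, mu_V, w_E, w_V)) {
    if (!is.finite(v) || v <= 0) stop("chemical scalars must be positive", call. = FALSE)
  }
  freq <- list(n_food, n_reserve, n_structure, n_feces)
  if (any(unlist(freq) < 0)) stop("elemental frequencies must be non-negative", call. = FALSE)
  structure(
    list(
      d_V = d_V, water_frac = water_frac, d_Vw = d_V / (1 - water_frac),
      mu_E = mu_E, mu_V = mu_V, w_E = w_E, w_V = w_V,
      n_food = n_food, n_reserve = n_reserve,
      n_structure = n_structure, n_feces = n_feces
    ),
    class = "deb_chemical"
  )
}

# growth efficiency predicted from structure's chemistry: energy fixed in
# structure per energy spent building it
kap_G_from_chemistry <- function(p, chem = chemical_params()) {
  chem$mu_V * (chem$d_V / chem$w_V) / p$E_G
}

# wet weight (g) from structural length (cm) and reserve energy (J)
wet_weight <- function(L, E, chem = chemical_params()) {
  chem$d_Vw * L^3 + E * chem$w_E / chem$mu_E
}
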