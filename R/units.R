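#' Molar masses of the tracked species
#'
#' Named vector of molar masses (g/mol) used to convert between the
#' mass-specific rates of the production envelope (g/gDW/h) and the
#' molar fluxes of the metabolic model (mmol/gDW/h).
#'
#' @format Named numeric vector with entries `glucose`, `acetoin`,
#'   `butanediol`.
#' @export
molar_masses <- c(glucose = 180.16, acetoin = 88.11, butanediol = 90.12)

#' Convert mass-specific rates to molar fluxes and back
#'
#' The production-envelope side of the package works in g/gDW/h (what a
#' fermentation scientist fits from concentration curves), the FBA side in
#' mmol/gDW/h (what a stoichiometric matrix balances). Conversion happens
#' only at the module boundary, through these two helpers.
#'
#' @param x rate(s) to convert; g/gDW/h for [g_to_mmol()], mmol/gDW/h for
#'   [mmol_to_g()].
#' @param species one of `"glucose"`, `"acetoin"`, `"butanediol"` (recycled
#'   against `x`).
#' @return converted rate(s); the round trip is an identity to 1e-12
#'   relative.
#' @examples
#' g_to_mmol(-1.5, "glucose")   # glucose uptake, mmol/gDW/h
#' mmol_to_g(g_to_mmol(0.2, "acetoin"), "acetoin")
#' @export
g_to_mmol <- function(x, species) {
  x / molar_mass_of(species) * 1000
}

#' @rdname g_to_mmol
#' @export
mmol_to_g <- function(x, species) {
  x * molar_mass_of(species) / 1000
}

molar_mass_of <- function(species) {
  species <- match.arg(species, names(molar_masses), several.ok = TRUE)
  unname(molar_masses[species])
}
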