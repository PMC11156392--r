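# Gas constant, J / (mol K)
GAS_CONSTANT <- 8.314

#' Odds ratio and nearest-neighbour coupling conversions
#'
#' The binding odds ratio is the relative likelihood of a different-type
#' attachment over a same-type one: `odds = exp(-gamma) / exp(gamma)
#' = exp(-2 * gamma)`, so `gamma = -log(odds) / 2`. Odds of 1 mean no
#' preference (`gamma = 0`); odds above 1 favour alternation (`gamma < 0`).
#'
#' @param odds positive odds ratio.
#' @return `oddsToGamma`: the coupling (dimensionless).
#' @examples
#' oddsToGamma(1.5)  # -0.2027
#' gammaToOdds(-0.2027)
#' @export
oddsToGamma <- function(odds) {
  if (any(!is.finite(odds)) || any(odds <= 0))
    stop("odds ratio must be positive and finite")
  -log(odds) / 2
}

#' @rdname oddsToGamma
#' @param gamma coupling (any real number).
#' @return `gammaToOdds`: the odds ratio (> 0); exact inverse of
#'   `oddsToGamma`.
#' @export
gammaToOdds <- function(gamma) {
  stopifnot(is.numeric(gamma), all(is.finite(gamma)))
  exp(-2 * gamma)
}

#' Standard Gibbs energy of the type-exchange reaction
#'
#' Treating the odds ratio as the equilibrium constant of the reaction that
#' replaces a wildtype molecule at the fibril end with a variant (fibril
#' phases at unit activity), the standard Gibbs energy change is
#' `deltaG = -R * T * log(odds)` with `R = 8.314` J/(mol K). Negative when
#' odds exceed 1: a better fit means a stronger effective bond.
#'
#' @param odds positive odds ratio (may be a vector).
#' @param temperature kelvin, positive. Default physiological 310.15 K.
#' @param units `"J"` (J/mol) or `"kJ"` (kJ/mol, the reporting unit).
#' @return Gibbs energy change in the requested unit.
#' @examples
#' oddsToDeltaG(2, temperature = 310, units = "kJ")  # about -1.79 kJ/mol
#' @export
oddsToDeltaG <- function(odds, temperature = 310.15, units = c("J", "kJ")) {
  if (any(!is.finite(odds)) || any(odds <= 0))
    stop("odds ratio must be positive and finite")
  if (length(temperature) != 1L || !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a single positive value in kelvin")
  units <- match.arg(units)
  dg <- -GAS_CONSTANT * temperature * log(odds)
  if (units == "kJ") dg / 1000 else dg
}

#' @rdname oddsToDeltaG
#' @return `equilibriumRatio`: the equilibrium constant `K_eq` = the
#'   equilibrium aqueous concentration ratio `[wt] / [v]` of the exchange
#'   reaction, equal to the odds ratio.
#' @export
equilibriumRatio <- function(odds) {
  if (any(!is.finite(odds)) || any(odds <= 0))
    stop("odds ratio must be positive and finite")
  odds
}

#' Tabulate the odds-to-energy map
#'
#' One row per odds value with the derived coupling, the equilibrium
#' constant, and the standard Gibbs energy in both J/mol and kJ/mol.
#'
#' @param odds vector of positive odds ratios.
#' @param temperature kelvin.
#' @return a data.frame with columns `odds`, `gamma`, `K_eq`,
#'   `delta_G_J_per_mol`, `delta_G_kJ_per_mol`, `temperature_K`.
#' @examples
#' energyMap(c(1, 1.5, 2, 4))
#' @export
energyMap <- function(odds, temperature = 310.15) {
  dg <- oddsToDeltaG(odds, temperature, units = "J")
  data.frame(
    odds = odds,
    gamma = oddsToGamma(odds),
    K_eq = equilibriumRatio(odds),
    delta_G_J_per_mol = dg,
    delta_G_kJ_per_mol = dg / 1000,
    temperature_K = temperature
  )
}
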