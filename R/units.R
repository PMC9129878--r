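# Physical constants and unit bridges. Internal units are Angstrom, ps,
# kcal/mol, elementary charge; SI appears only at the I/O edges.

#' Physical constants used throughout the package
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal/(mol K).}
#'   \item{coulomb}{Coulomb constant, kcal A/(mol e^2), so that
#'     \eqn{\Phi = k q / (\epsilon r)} gives kcal/(mol e).}
#'   \item{e_C}{Elementary charge in Coulomb.}
#'   \item{avogadro}{Avogadro's number, 1/mol.}
#'   \item{kB_J}{Boltzmann constant, J/K.}
#'   \item{faraday}{Faraday constant, C/mol.}
#'   \item{gas_R}{Molar gas constant, J/(mol K).}
#'   \item{kcalmol_to_V}{Volts per (kcal/mol)/e, the field-to-voltage bridge.}
#' }
#' @export
#' @examples
#' permeon_constants$kB * 298  # thermal energy at 298 K, kcal/mol
permeon_constants <- list(
  kB = 0.001987204259,
  coulomb = 332.0636,
  e_C = 1.602176634e-19,
  avogadro = 6.02214076e23,
  kB_J = 1.380649e-23,
  faraday = 96485.33212,
  gas_R = 8.314462618,
  kcalmol_to_V = 0.0434
)

#' Thermal energy
#'
#' @param temperature temperature in Kelvin.
#' @return \eqn{k_B T} in kcal/mol.
#' @export
#' @examples
#' kBT(298)  # ~0.592 kcal/mol
kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  permeon_constants$kB * temperature
}

# log-sum-exp, guarded against overflow
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
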