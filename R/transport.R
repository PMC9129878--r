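# Conductance from a free-energy profile, field-to-voltage conversion, and
# ohmic current / permeation-rate arithmetic.

#' Single-channel conductance from a potential of mean force
#'
#' One-dimensional diffusion estimate
#' \deqn{\gamma = \frac{q^2 C S}{k_B T}\left[\int_{z_1}^{z_2}
#'   \frac{e^{F(z)/k_BT}}{D(z)}\,dz\right]^{-1}}
#' with trapezoidal integration over the profile bins. The PMF must be
#' anchored to ~0 in the bulk and defined (unmasked) on every bin inside the
#' integration bounds. Mixed molecular/SI units are bridged internally; the
#' result is in pS.
#'
#' @param pmf a `free_energy_profile` (kcal/mol) or any [pore_profile()]
#'   holding free energies.
#' @param q ion charge in elementary charges (default 1).
#' @param concentration bulk ion concentration, mol/L (default 0.1 = 100 mM).
#' @param area cross-sectional area S of the sampled cylinder, Angstrom^2
#'   (default 314, a 10 Angstrom radius).
#' @param diffusion D, m^2/s (default 2e-9, bulk K+); either a scalar (flat
#'   profile) or one value per bin inside the bounds.
#' @param temperature Kelvin.
#' @param bounds integration bounds `c(z1, z2)`, Angstrom. Default: the full
#'   span over which the profile is defined.
#' @return conductance in pS.
#' @export
#' @examples
#' z <- seq(-20, 20, by = 0.5)
#' flat <- pore_profile(z, rep(0, length(z)))
#' conductance_from_pmf(flat, bounds = c(-15, 15))
conductance_from_pmf <- function(pmf, q = 1, concentration = 0.1, area = 314,
                                 diffusion = 2e-9, temperature = 298,
                                 bounds = NULL) {
  stopifnot(inherits(pmf, "pore_profile"), concentration > 0, area > 0,
            all(diffusion > 0), temperature > 0)
  if (is.null(bounds)) {
    ok <- !is.na(pmf$value)
    bounds <- range(pmf$z[ok])
  }
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  sel <- pmf$z >= bounds[1] & pmf$z <= bounds[2]
  if (sum(sel) < 2) stop("fewer than two bins inside the bounds")
  f <- pmf$value[sel]
  if (any(is.na(f)))
    stop("masked (undefined) free-energy bins inside the integration bounds")
  z <- pmf$z[sel]
  d <- rep_len(diffusion, length(z))
  integrand <- exp(f / kBT(temperature)) / d      # s/m^2 per Angstrom of z
  integral <- sum(diff(z) * (integrand[-1] + integrand[-length(z)]) / 2) *
    1e-10                                          # z: Angstrom -> m
  cst <- permeon_constants
  n_density <- concentration * 1000 * cst$avogadro # ions/m^3
  gamma_S <- (q * cst$e_C)^2 * n_density * (area * 1e-20) /
    (cst$kB_J * temperature) / integral
  gamma_S * 1e12
}

#' Transmembrane voltage equivalent to a constant electric field
#'
#' \eqn{\Phi = E_z \times L_z \times 0.0434} V per e^-1 (kcal/mol)^-1,
#' reported in mV. A field of -0.1045 kcal/(mol A e) across a 110.5 A box
#' corresponds to about -500 mV.
#'
#' @param e_z field, kcal/(mol Angstrom e).
#' @param l_z box length along the field, Angstrom.
#' @return potential in mV.
#' @export
#' @examples
#' field_to_voltage(-0.1045, 110.5)  # ~ -501 mV
field_to_voltage <- function(e_z, l_z) {
  stopifnot(l_z > 0)
  e_z * l_z * permeon_constants$kcalmol_to_V * 1000
}

#' Ohmic current and permeation rate from a conductance
#'
#' @param gamma_pS conductance, pS.
#' @param v_mV applied voltage, mV.
#' @return list with `current_pA` (\eqn{I = \gamma V}) and `rate_per_us`
#'   (ions per microsecond, \eqn{I/e}).
#' @export
#' @examples
#' ohmic_current_and_rate(0.23, 500)  # ~0.115 pA, ~0.72 ions/us
ohmic_current_and_rate <- function(gamma_pS, v_mV) {
  i_pA <- gamma_pS * v_mV * 1e-3
  rate <- i_pA * 1e-12 / permeon_constants$e_C * 1e-6
  list(current_pA = i_pA, rate_per_us = rate)
}
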