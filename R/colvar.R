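# Soft-minimum ion-proximity collective variables.

#' Parameters of the soft-minimum proximity variable
#'
#' @param beta smoothing parameter, Angstrom (default 100). Larger values
#'   push the soft minimum closer to the true minimum distance.
#' @param c regularising constant, Angstrom (default 2), which keeps the
#'   exponent finite as an ion crosses the centre.
#' @return list of class `softmin_params`.
#' @export
softmin_params <- function(beta = 100, c = 2) {
  stopifnot(is.numeric(beta), beta > 0, is.numeric(c), c > 0)
  structure(list(beta = beta, c = c), class = "softmin_params")
}

#' Soft-minimum proximity of a set of ions to a virtual centre
#'
#' Computes \deqn{\zeta = \beta / \ln \sum_k \exp\{\beta/(|\Delta Z_k| + C)\} - C}
#' a smooth lower bound on \eqn{\min_k |\Delta Z_k|} that needs no prior
#' choice of which ion permeates. For a single ion it reduces exactly to
#' \eqn{|\Delta Z|}; it converges to the hard minimum as \eqn{\beta \to
#' \infty}. Evaluated via log-sum-exp, so large \eqn{\beta} is safe.
#'
#' @param delta_z axial distances \eqn{\Delta Z_k} of each ion to the centre
#'   (signed or absolute), Angstrom; at least one ion.
#' @param params a [softmin_params()] object.
#' @return \eqn{\zeta} in Angstrom; always in \eqn{(-C, \min_k|\Delta Z_k|]}.
#' @export
#' @examples
#' softmin_proximity(5)            # exactly 5
#' softmin_proximity(c(5, 50))     # slightly below 5
softmin_proximity <- function(delta_z, params = softmin_params()) {
  stopifnot(inherits(params, "softmin_params"))
  if (length(delta_z) == 0L) stop("at least one ion is required")
  if (any(!is.finite(delta_z))) stop("non-finite ion distance")
  cpp_softmin(as.numeric(delta_z), params$beta, params$c)
}

#' Evaluate the collective-variable pair for one frame
#'
#' \eqn{\Delta Z_k} is the Cartesian Z-component of the vector from the
#' reference centre to ion k; one soft-minimum value is returned per centre.
#' The two centres typically flank the channel constriction, about 1 Angstrom
#' apart along the pore axis.
#'
#' @param ion_z Cartesian Z coordinates of all tracked ions, Angstrom.
#' @param center_a_z,center_b_z Z coordinates of centres A and B.
#' @param params a [softmin_params()].
#' @return named numeric vector `c(zeta_a, zeta_b)`.
#' @export
evaluate_cv_pair <- function(ion_z, center_a_z, center_b_z,
                             params = softmin_params()) {
  c(zeta_a = softmin_proximity(ion_z - center_a_z, params),
    zeta_b = softmin_proximity(ion_z - center_b_z, params))
}
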