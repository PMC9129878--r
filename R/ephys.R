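# Patch-clamp analysis: IV extraction from voltage-step sweeps, inhibitor
# background subtraction, reversal potentials, bi-ionic permeability ratios,
# and the hyperbolic dose-response (IC50) fit.

#' Current-voltage relationship from voltage-step sweeps
#'
#' Averages the current samples inside a time window (typically the plateau)
#' for each step voltage.
#'
#' @param sweeps data.frame with columns `voltage` (mV), `time` (ms) and
#'   `current` (pA); one trace per unique voltage.
#' @param window `c(t0, t1)` in ms; must lie within every trace.
#' @return data.frame of class `iv_curve` with `voltage` and `current`,
#'   sorted by voltage; attribute `window`.
#' @export
iv_from_sweeps <- function(sweeps, window) {
  stopifnot(all(c("voltage", "time", "current") %in% names(sweeps)),
            length(window) == 2, window[1] < window[2])
  volts <- sort(unique(sweeps$voltage))
  cur <- vapply(volts, function(v) {
    tr <- sweeps[sweeps$voltage == v, ]
    if (window[1] < min(tr$time) || window[2] > max(tr$time))
      stop("averaging window outside the trace span")
    sel <- tr$time >= window[1] & tr$time <= window[2]
    if (!any(sel)) stop("no samples inside the averaging window")
    mean(tr$current[sel])
  }, numeric(1))
  structure(data.frame(voltage = volts, current = cur),
            window = window, class = c("iv_curve", "data.frame"))
}

#' Background subtraction of an inhibited IV curve
#'
#' Isolates the channel-specific current as control minus inhibited,
#' pointwise on an identical voltage grid.
#'
#' @param iv_control,iv_inhibited `iv_curve` objects on the same voltages.
#' @return an `iv_curve` of the difference.
#' @export
subtract_background <- function(iv_control, iv_inhibited) {
  if (!isTRUE(all.equal(iv_control$voltage, iv_inhibited$voltage)))
    stop("voltage grids differ")
  out <- iv_control
  out$current <- iv_control$current - iv_inhibited$current
  out
}

#' Reversal potential of an IV curve
#'
#' Linear interpolation between the two voltages bracketing the zero
#' crossing. If the curve crosses zero more than once, the crossing nearest
#' 0 mV is used, with a warning.
#'
#' @param iv an `iv_curve`.
#' @return E_rev in mV.
#' @export
reversal_potential <- function(iv) {
  v <- iv$voltage
  i <- iv$current
  if (any(i == 0)) {
    roots <- v[i == 0]
  } else {
    roots <- numeric(0)
  }
  s <- sign(i)
  cross <- which(s[-1] * s[-length(s)] < 0)
  roots <- c(roots, vapply(cross, function(k) {
    v[k] - i[k] * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
  }, numeric(1)))
  if (length(roots) == 0L) stop("IV curve does not cross zero")
  if (length(roots) > 1L) {
    warning("multiple zero crossings; using the one nearest 0 mV")
    roots <- roots[which.min(abs(roots))]
  }
  roots[1]
}

#' Bi-ionic permeability ratio from a reversal potential
#'
#' For monovalent bi-ionic conditions (internal cation X, external cation Y)
#' the zero-current condition gives
#' \deqn{P_{X}/P_{Y} = \frac{[Y]_{out}}{[X]_{in}}
#'   \exp\left(-\frac{E_{rev} F}{R T}\right)}
#' with E_rev the membrane potential (inside relative to outside); a more
#' permeant internal cation gives a negative E_rev and a ratio above 1.
#'
#' @param e_rev_mV reversal potential, mV.
#' @param conc_out external cation concentration, mM.
#' @param conc_in internal cation concentration, mM.
#' @param temperature Kelvin (default 295, room temperature).
#' @return the permeability ratio P_internal / P_external.
#' @export
#' @examples
#' permeability_ratio(-76)  # ~20 (Cs+ over Na+, 150/150 mM)
permeability_ratio <- function(e_rev_mV, conc_out = 150, conc_in = 150,
                               temperature = 295) {
  stopifnot(conc_out > 0, conc_in > 0, temperature > 0)
  rt_f <- permeon_constants$gas_R * temperature / permeon_constants$faraday
  (conc_out / conc_in) * exp(-(e_rev_mV * 1e-3) / rt_f)
}

#' Fit a hyperbolic inhibition dose-response curve
#'
#' Least-squares fit of
#' \deqn{I = I_{min} + (I_{max} - I_{min})\frac{IC_{50}}{IC_{50} + [inh]}}
#' with the constraint IC50 > 0 (Levenberg-Marquardt).
#'
#' @param concentration inhibitor concentrations, mM (>= 4 distinct values
#'   including one at or near zero).
#' @param current normalised currents at each concentration.
#' @return list of class `dose_response`: `i_max`, `i_min`, `ic50` (mM),
#'   `residual_norm`, `fitted` (function of concentration), `fit` (the
#'   underlying nls object).
#' @export
fit_dose_response <- function(concentration, current) {
  stopifnot(length(concentration) == length(current))
  if (length(unique(concentration)) < 4)
    stop("need at least four distinct concentrations")
  if (min(concentration) > 0.05 * max(concentration))
    stop("need a measurement at or near zero inhibitor")
  df <- data.frame(conc = concentration, i = current)
  i_max0 <- max(current)
  i_min0 <- min(current)
  mid <- (i_max0 + i_min0) / 2
  ic50_0 <- concentration[which.min(abs(current - mid))]
  if (ic50_0 <= 0) ic50_0 <- stats::median(concentration[concentration > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      i ~ i_min + (i_max - i_min) * ic50 / (ic50 + conc), data = df,
      start = list(i_max = i_max0, i_min = i_min0, ic50 = ic50_0),
      lower = c(i_max = -Inf, i_min = -Inf, ic50 = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("dose-response fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  if (cf[["i_min"]] > cf[["i_max"]]) {
    tmp <- cf[["i_min"]]; cf[["i_min"]] <- cf[["i_max"]]; cf[["i_max"]] <- tmp
  }
  structure(list(
    i_max = unname(cf[["i_max"]]), i_min = unname(cf[["i_min"]]),
    ic50 = unname(cf[["ic50"]]),
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    fitted = function(conc) cf[["i_min"]] + (cf[["i_max"]] - cf[["i_min"]]) *
      cf[["ic50"]] / (cf[["ic50"]] + conc),
    fit = fit), class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("dose_response: IC50 = %.4g mM, Imax = %.3g, Imin = %.3g\n",
              x$ic50, x$i_max, x$i_min))
  invisible(x)
}
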