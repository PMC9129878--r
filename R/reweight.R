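# Post-hoc reweighting of biased trajectories: snapshot weights from the
# time-averaged bias, occupancy profiles, potentials of mean force, and
# reweighted observable profiles, with the split-half error diagnostic.

#' Statistical weights of trajectory snapshots under a time-averaged bias
#'
#' Each snapshot is assigned to the nearest lattice cell of the effective
#' bias and weighted by \eqn{w_i \propto \exp\{\bar V(\zeta_A,\zeta_B)/k_BT\}},
#' normalised over snapshots. Snapshots sampled where the accumulated bias is
#' large (easily accessible regions) receive large weights; rarely biased
#' regions receive small ones.
#'
#' @param zeta_a,zeta_b per-snapshot collective-variable values, Angstrom.
#'   Values outside the lattice are clamped to its edge with a warning.
#' @param ebias an `effective_bias` (see [time_average_bias()]).
#' @param temperature Kelvin.
#' @return list of class `snapshot_weights`: normalised `weights` (sum to 1),
#'   `temperature`, and the effective sample size `ess`.
#' @export
snapshot_weights <- function(zeta_a, zeta_b, ebias, temperature = 298) {
  stopifnot(inherits(ebias, "effective_bias"),
            length(zeta_a) == length(zeta_b))
  if (length(zeta_a) == 0L) stop("no snapshots")
  g <- ebias$grid
  ia <- round((zeta_a - g$lo) / g$spacing) + 1
  ib <- round((zeta_b - g$lo) / g$spacing) + 1
  n_out <- sum(ia < 1 | ia > g$n | ib < 1 | ib > g$n)
  if (n_out > 0)
    warning(sprintf("%d CV pairs outside the bias lattice were clamped", n_out))
  ia <- pmin(pmax(ia, 1), g$n)
  ib <- pmin(pmax(ib, 1), g$n)
  v <- g$values[cbind(ia, ib)] / kBT(temperature)
  w <- exp(v - logsumexp(v))
  ess <- 1 / sum(w^2)
  if (ess < 10)
    warning(sprintf("effective sample size is only %.2f", ess))
  structure(list(weights = w, temperature = temperature, ess = ess),
            class = "snapshot_weights")
}

#' Ion occupancy profile along the pore axis
#'
#' \deqn{\rho(z_\alpha) = \sum_i \sum_{k \in (\alpha, R_0)} w(X_i)}
#' The inner sum runs over ions whose axial coordinate falls in bin alpha and
#' whose distance to the pore axis does not exceed `r0`; each ion contributes
#' to exactly one bin per snapshot.
#'
#' @param ions data.frame with one row per (snapshot, ion): columns
#'   `snapshot` (1-based index into the weight table), `z` and `r` (Angstrom).
#' @param weights a [snapshot_weights()] object.
#' @param breaks uniform bin boundaries along z, Angstrom.
#' @param r0 axial distance cut-off, Angstrom (default 10).
#' @return a [pore_profile()] of summed snapshot weights per bin.
#' @export
occupancy_profile <- function(ions, weights, breaks, r0 = 10) {
  stopifnot(inherits(weights, "snapshot_weights"),
            all(c("snapshot", "z", "r") %in% names(ions)))
  if (length(breaks) < 2) stop("need at least one bin")
  dz <- diff(breaks)
  if (any(dz <= 0)) stop("zero-width or decreasing bins")
  if (max(abs(dz - dz[1])) > 1e-9) stop("bins must be uniform")
  keep <- ions$r <= r0 & ions$z >= breaks[1] & ions$z < breaks[length(breaks)]
  idx <- findInterval(ions$z[keep], breaks, rightmost.closed = TRUE)
  w <- weights$weights[ions$snapshot[keep]]
  nb <- length(breaks) - 1L
  rho <- rep(0, nb)
  if (length(idx)) {
    agg <- rowsum(w, idx)
    rho[as.integer(rownames(agg))] <- agg[, 1]
  }
  cnt <- tabulate(idx, nbins = nb)
  pore_profile((breaks[-1] + breaks[-length(breaks)]) / 2, rho, cnt,
               quantity = "occupancy", units = "probability", r0 = r0)
}

#' Potential of mean force from an occupancy profile
#'
#' \deqn{F(z_\alpha) = -k_B T \ln \rho(z_\alpha) + C'}
#' with the constant chosen so that the occupancy-weighted mean of F over the
#' anchor (bulk) region is zero. Bins with zero occupancy are masked (`NA`),
#' never zero-filled.
#'
#' @param occupancy a [pore_profile()] from [occupancy_profile()].
#' @param temperature Kelvin.
#' @param anchor two non-negative numbers: the bulk region `|z|` interval
#'   (both sides pooled) over which F is anchored to zero. Default
#'   `c(30, 40)` Angstrom.
#' @return a `free_energy_profile` (also a [pore_profile()], kcal/mol) with
#'   attributes `anchor` and `offset`.
#' @export
pmf_from_occupancy <- function(occupancy, temperature = 298,
                               anchor = c(30, 40)) {
  stopifnot(inherits(occupancy, "pore_profile"), length(anchor) == 2,
            anchor[1] < anchor[2])
  rho <- occupancy$value
  if (all(rho == 0 | is.na(rho))) stop("occupancy is zero everywhere")
  f <- ifelse(rho > 0, -kBT(temperature) * log(rho), NA_real_)
  in_anchor <- abs(occupancy$z) >= anchor[1] & abs(occupancy$z) <= anchor[2] &
    !is.na(f)
  if (!any(in_anchor))
    stop("no occupied bins inside the anchor region")
  offset <- sum(f[in_anchor] * rho[in_anchor]) / sum(rho[in_anchor])
  f <- f - offset
  out <- pore_profile(occupancy$z, f, occupancy$count,
                      quantity = "free_energy", units = "kcal/mol",
                      r0 = attr(occupancy, "r0"))
  attr(out, "anchor") <- anchor
  attr(out, "offset") <- -offset
  attr(out, "temperature") <- temperature
  class(out) <- c("free_energy_profile", class(out))
  out
}

#' Reweighted observable profile along the pore axis
#'
#' \deqn{\bar O(z_\alpha) = \rho(z_\alpha)^{-1} \sum_i \sum_{k \in (\alpha,R_0)}
#'   O_k(X_i)\, w(X_i)}
#' the weighted mean of a per-ion observable (coordination number,
#' electrostatic energy, ...) in each axial bin. Bins with zero occupancy are
#' masked.
#'
#' @param ions as in [occupancy_profile()], plus a column `obs` holding
#'   \eqn{O_k(X_i)} (or pass `obs` separately).
#' @param weights a [snapshot_weights()].
#' @param breaks uniform bin boundaries, Angstrom.
#' @param r0 axial cut-off, Angstrom.
#' @param obs optional observable vector overriding `ions$obs`.
#' @param quantity,units metadata for the returned profile.
#' @return a [pore_profile()] of weighted means per bin.
#' @export
observable_profile <- function(ions, weights, breaks, r0 = 10, obs = NULL,
                               quantity = "observable", units = "") {
  if (is.null(obs)) obs <- ions$obs
  if (is.null(obs)) stop("no observable values supplied")
  if (length(obs) != nrow(ions)) stop("observable length mismatch")
  if (any(is.na(obs))) stop("observable undefined for some ions")
  keep <- ions$r <= r0 & ions$z >= breaks[1] & ions$z < breaks[length(breaks)]
  idx <- findInterval(ions$z[keep], breaks, rightmost.closed = TRUE)
  w <- weights$weights[ions$snapshot[keep]]
  nb <- length(breaks) - 1L
  num <- rep(0, nb)
  den <- rep(0, nb)
  if (length(idx)) {
    aggn <- rowsum(w * obs[keep], idx)
    aggd <- rowsum(w, idx)
    num[as.integer(rownames(aggn))] <- aggn[, 1]
    den[as.integer(rownames(aggd))] <- aggd[, 1]
  }
  val <- ifelse(den > 0, num / den, NA_real_)
  pore_profile((breaks[-1] + breaks[-length(breaks)]) / 2, val, den,
               quantity = quantity, units = units, r0 = r0)
}

#' Split-half convergence diagnostic
#'
#' Recomputes weights (renormalised) and profiles separately on the first and
#' second temporal halves of the data and reports the mean absolute
#' difference over bins defined in both halves. For a converged simulation
#' the two profiles coincide.
#'
#' @param ions per-(snapshot, ion) table with `snapshot`, `z`, `r` and, for an
#'   observable profile, `obs`.
#' @param zeta_a,zeta_b per-snapshot CV values (length = number of snapshots).
#' @param times per-snapshot times, ps.
#' @param ebias the `effective_bias` used for weighting both halves.
#' @param temperature Kelvin.
#' @param breaks,r0 binning as in [occupancy_profile()].
#' @param anchor bulk anchor interval for the PMF (ignored for observables).
#' @param observable if `TRUE`, compare observable profiles of `ions$obs`
#'   instead of free-energy profiles.
#' @return list with `first`, `second` (profiles) and `mean_abs_difference`.
#' @export
split_half_profiles <- function(ions, zeta_a, zeta_b, times, ebias,
                                temperature = 298,
                                breaks = seq(-40, 40, by = 0.5), r0 = 10,
                                anchor = c(30, 40), observable = FALSE) {
  ns <- length(times)
  if (ns < 2) stop("need at least two snapshots to split")
  stopifnot(length(zeta_a) == ns, length(zeta_b) == ns)
  t_mid <- stats::median(times)
  half <- function(sel) {
    map <- cumsum(sel)            # old snapshot index -> new index
    sub <- ions[sel[ions$snapshot], , drop = FALSE]
    sub$snapshot <- map[sub$snapshot]
    w <- snapshot_weights(zeta_a[sel], zeta_b[sel], ebias, temperature)
    if (observable) {
      observable_profile(sub, w, breaks, r0)
    } else {
      pmf_from_occupancy(occupancy_profile(sub, w, breaks, r0),
                         temperature, anchor)
    }
  }
  p1 <- half(times <= t_mid)
  p2 <- half(times > t_mid)
  ok <- !is.na(p1$value) & !is.na(p2$value)
  list(first = p1, second = p2,
       mean_abs_difference = mean(abs(p1$value[ok] - p2$value[ok])))
}
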