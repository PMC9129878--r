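# End-to-end reweighting pipeline for a biased toy-pore run: hills ->
# time-averaged effective bias -> snapshot weights -> occupancy -> PMF.

#' Reweighted free-energy profile from a biased toy-pore simulation
#'
#' Reconstructs the time-averaged effective bias from the hill log over the
#' stationary window, weights the snapshots recorded in that window, bins the
#' ion positions into an occupancy profile and converts it to a potential of
#' mean force anchored in the bulk.
#'
#' @param sim a biased [simulate_toy_pore()] result.
#' @param window averaging window `c(t_start, t_end)` in ps. Default: the
#'   final two thirds of the run (mirroring the practice of averaging once
#'   the bias is approximately stationary).
#' @param breaks axial bin boundaries, Angstrom (default 0.5 A bins across
#'   the box).
#' @param r0 axial distance cut-off for counting ions, Angstrom.
#' @param anchor bulk `|z|` interval where F is anchored to zero.
#' @param n_bias_samples bias snapshots averaged across the window.
#' @return list with `pmf` (a `free_energy_profile`), `occupancy`, `ebias`,
#'   `weights`, and the snapshot selection used.
#' @export
reweighted_pmf <- function(sim, window = NULL,
                           breaks = seq(-40, 40, by = 0.5), r0 = 10,
                           anchor = c(30, 40), n_bias_samples = 25) {
  stopifnot(inherits(sim, "toy_pore_sim"))
  if (is.null(sim$metadynamics))
    stop("simulation was not biased; reweighting needs a hill log")
  t_end <- sim$n_steps * sim$params$dt
  if (is.null(window)) window <- c(t_end / 3, t_end)
  ebias <- effective_bias_from_hills(sim$hills, sim$metadynamics$grid,
                                     window, n_bias_samples)
  s <- sim$snapshots
  sel <- which(s[, "time"] >= window[1] & s[, "time"] <= window[2])
  if (length(sel) == 0L) stop("no snapshots inside the window")
  w <- snapshot_weights(s[sel, "zeta_a"], s[sel, "zeta_b"], ebias,
                        sim$params$temperature)
  ions <- snapshot_ions(sim)
  ions <- ions[ions$snapshot %in% sel, , drop = FALSE]
  ions$snapshot <- match(ions$snapshot, sel)
  occ <- occupancy_profile(ions, w, breaks, r0)
  pmf <- pmf_from_occupancy(occ, sim$params$temperature, anchor)
  list(pmf = pmf, occupancy = occ, ebias = ebias, weights = w,
       window = window, snapshots_used = sel, ions = ions)
}

#' Split-half free-energy comparison for one biased run
#'
#' Splits the analysis window into two temporal halves and computes a fully
#' independent PMF from each: each half gets its own time-averaged effective
#' bias (over that half), its own renormalised snapshot weights and its own
#' bulk anchoring. The mean absolute difference over bins defined in both
#' halves measures the statistical error of the profile.
#'
#' @inheritParams reweighted_pmf
#' @return list with `first`, `second` (free-energy profiles) and
#'   `mean_abs_difference` (kcal/mol).
#' @export
split_half_pmf <- function(sim, window = NULL,
                           breaks = seq(-40, 40, by = 0.5), r0 = 10,
                           anchor = c(30, 40), n_bias_samples = 25) {
  stopifnot(inherits(sim, "toy_pore_sim"))
  t_end <- sim$n_steps * sim$params$dt
  if (is.null(window)) window <- c(t_end / 3, t_end)
  mid <- mean(window)
  p1 <- reweighted_pmf(sim, c(window[1], mid), breaks, r0, anchor,
                       n_bias_samples)$pmf
  p2 <- reweighted_pmf(sim, c(mid, window[2]), breaks, r0, anchor,
                       n_bias_samples)$pmf
  ok <- !is.na(p1$value) & !is.na(p2$value)
  list(first = p1, second = p2,
       mean_abs_difference = mean(abs(p1$value[ok] - p2$value[ok])))
}

#' Split-half convergence against simulation length
#'
#' Runs biased toy-pore simulations of increasing length and reports the
#' split-half mean absolute free-energy difference for each; for a
#' converging protocol this discrepancy decreases with run length. Because
#' one run's split-half value fluctuates, the estimate at each length is
#' averaged over `n_replicas` independent replicas (seeds `seed + 1000 r`).
#'
#' @param params a [toy_pore_params()].
#' @param metadynamics a [toy_metadynamics()].
#' @param lengths vector of per-walker step counts, increasing.
#' @param n_walkers walkers per run.
#' @param n_replicas replicate runs averaged per length.
#' @param seed base seed.
#' @param snap_stride snapshot stride.
#' @return data.frame with `n_steps` and `mean_abs_difference`.
#' @export
split_half_convergence <- function(params, metadynamics,
                                   lengths = c(20000, 80000, 320000),
                                   n_walkers = 8, n_replicas = 3, seed = 1,
                                   snap_stride = 20) {
  stopifnot(all(diff(lengths) > 0), n_replicas >= 1)
  vals <- vapply(lengths, function(L) {
    mean(vapply(seq_len(n_replicas) - 1L, function(r) {
      sim <- simulate_toy_pore(params, L, n_walkers, metadynamics,
                               snap_stride, seed = seed + 1000L * r)
      split_half_pmf(sim)$mean_abs_difference
    }, numeric(1)))
  }, numeric(1))
  data.frame(n_steps = lengths, mean_abs_difference = vals)
}
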