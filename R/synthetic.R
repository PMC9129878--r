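# Synthetic-data generators with known ground truth: the Brownian-dynamics
# toy pore (optionally coupled to metadynamics on the soft-min CV pair),
# hydration-shell fixtures, Gaussian FEP window samples, and patch-clamp
# recordings. Every generator is a pure function of (parameters, seed).

#' Parameters of the Brownian-dynamics toy pore
#'
#' Non-interacting monovalent cations diffuse in a radially confined
#' cylinder (uniform accessible cross-section along z, so the analytic PMF
#' is exactly the imposed axial potential), with reflecting walls at
#' `+/- box_z/2`, a Gaussian axial barrier centred at z = 0, and an optional
#' constant axial field. The default barrier height of 7 kcal/mol matches the
#' scale of the rate-limiting constriction barrier in a narrow K+ channel;
#' the diffusion constant 0.2 A^2/ps is the bulk value for K+ (2e-9 m^2/s).
#'
#' @param n_ions ions per walker (default 8).
#' @param box_z axial extent, Angstrom (reservoirs to +/- 40).
#' @param pore_radius radial confinement radius, Angstrom.
#' @param k_conf confinement stiffness beyond `pore_radius`, kcal/(mol A^2).
#' @param barrier_height Gaussian barrier height U0, kcal/mol.
#' @param barrier_width Gaussian barrier width (sd), Angstrom.
#' @param temperature Kelvin.
#' @param diffusion D, A^2/ps.
#' @param dt timestep, ps. Must satisfy `diffusion * dt < 0.1 *
#'   barrier_width^2` for stability.
#' @param field constant axial field E_z acting on the unit positive charge,
#'   kcal/(mol A e) (0 = equilibrium).
#' @param periodic_z if `TRUE`, wrap z periodically instead of reflecting at
#'   the walls; with a field this sustains a steady-state flux (the
#'   voltage-simulation setup). Default `FALSE`.
#' @return list of class `toy_pore_params`.
#' @export
toy_pore_params <- function(n_ions = 8, box_z = 80, pore_radius = 5,
                            k_conf = 10, barrier_height = 7,
                            barrier_width = 2, temperature = 298,
                            diffusion = 0.2, dt = 0.1, field = 0,
                            periodic_z = FALSE) {
  stopifnot(n_ions >= 1, box_z > 0, pore_radius > 0, k_conf > 0,
            barrier_width > 0, temperature > 0, diffusion > 0, dt > 0)
  if (diffusion * dt >= 0.1 * barrier_width^2)
    stop("unstable timestep: require diffusion * dt << barrier_width^2")
  structure(list(n_ions = n_ions, box_z = box_z, pore_radius = pore_radius,
                 k_conf = k_conf, barrier_height = barrier_height,
                 barrier_width = barrier_width, temperature = temperature,
                 diffusion = diffusion, dt = dt, field = field,
                 periodic_z = periodic_z),
            class = "toy_pore_params")
}

#' Metadynamics settings for the toy pore
#'
#' Hill widths (0.25 Angstrom) and deposition interval (4 ps) follow the
#' standard permeation protocol; the height schedule is the 0.0035 to
#' 0.007 kcal/mol ramp compressed to the toy run length (rise over the first
#' 2 ns, decay complete at 6 ns by default).
#'
#' @param beta,c soft-minimum parameters (see [softmin_params()]).
#' @param sigma hill width in both CV dimensions, Angstrom.
#' @param hill_interval_ps time between hill depositions per walker, ps.
#' @param schedule a [height_schedule()] (times in ns).
#' @param grid a [bias_grid()] for the shared bias.
#' @param center_a_z,center_b_z axial positions of the two CV centres,
#'   1 Angstrom apart flanking the barrier.
#' @return list of class `toy_metadynamics`.
#' @export
toy_metadynamics <- function(beta = 100, c = 2, sigma = 0.25,
                             hill_interval_ps = 4,
                             schedule = height_schedule(t_rise_end = 2,
                                                        t_decay_end = 6),
                             grid = bias_grid(),
                             center_a_z = -0.5, center_b_z = 0.5) {
  stopifnot(sigma > 0, hill_interval_ps > 0,
            inherits(schedule, "height_schedule"),
            inherits(grid, "bias_grid"))
  structure(list(beta = beta, c = c, sigma = sigma,
                 hill_interval_ps = hill_interval_ps, schedule = schedule,
                 grid = grid, center_a_z = center_a_z,
                 center_b_z = center_b_z),
            class = "toy_metadynamics")
}

#' Simulate the toy pore (overdamped Langevin, optional metadynamics)
#'
#' Position update per ion: \eqn{x \leftarrow x + (D/k_BT) F \Delta t +
#' \sqrt{2 D \Delta t}\, \eta}. With `metadynamics` supplied, all walkers
#' deposit Gaussian hills (with boundary images) into one shared bias grid
#' and feel its force through the chain rule of the soft-min CV pair.
#' Deterministic for a fixed seed; walker w uses stream `seed + w`.
#'
#' @param params a [toy_pore_params()].
#' @param n_steps Brownian steps per walker.
#' @param n_walkers number of walkers sharing the bias (default 8).
#' @param metadynamics a [toy_metadynamics()] or `NULL` for unbiased dynamics.
#' @param snap_stride record every `snap_stride`-th step (default 20).
#' @param seed integer seed.
#' @return list of class `toy_pore_sim`: `snapshots` (matrix: time, walker,
#'   zeta_a, zeta_b, then per-ion z and R columns), `hills` (data.frame),
#'   `bias` (final shared [bias_grid()]), plus the inputs.
#' @export
simulate_toy_pore <- function(params, n_steps, n_walkers = 8,
                              metadynamics = NULL, snap_stride = 20,
                              seed = 1) {
  stopifnot(inherits(params, "toy_pore_params"), n_steps >= 1,
            n_walkers >= 1, snap_stride >= 1)
  biased <- !is.null(metadynamics)
  md <- if (biased) metadynamics else toy_metadynamics()
  if (biased) stopifnot(inherits(metadynamics, "toy_metadynamics"))
  hill_every <- max(1L, as.integer(round(md$hill_interval_ps / params$dt)))
  bias_mat <- md$grid$values + 0  # private copy, filled in place
  res <- cpp_simulate_toy_pore(
    params$n_ions, n_walkers, as.integer(n_steps), params$dt,
    params$diffusion, params$temperature, params$box_z,
    isTRUE(params$periodic_z), params$pore_radius,
    params$k_conf, params$barrier_height, params$barrier_width, params$field,
    md$center_a_z, md$center_b_z,
    biased, md$beta, md$c, md$sigma, hill_every,
    md$schedule$h0, md$schedule$h_peak,
    md$schedule$t_rise_end * 1000, md$schedule$t_decay_end * 1000,
    bias_mat, md$grid$lo, md$grid$spacing,
    as.integer(snap_stride), as.integer(seed))
  n_ions <- params$n_ions
  colnames(res$snapshots) <- c("time", "walker", "zeta_a", "zeta_b",
                               paste0("z", seq_len(n_ions)),
                               paste0("r", seq_len(n_ions)))
  hills <- as.data.frame(res$hills)
  names(hills) <- c("time", "zeta_a", "zeta_b", "sigma_a", "sigma_b",
                    "height", "walker")
  grid <- md$grid
  grid$values <- bias_mat
  structure(list(snapshots = res$snapshots, hills = hills, bias = grid,
                 params = params, metadynamics = if (biased) md else NULL,
                 n_steps = n_steps, n_walkers = n_walkers,
                 snap_stride = snap_stride, seed = seed),
            class = "toy_pore_sim")
}

#' @export
print.toy_pore_sim <- function(x, ...) {
  cat(sprintf(
    "toy_pore_sim: %d walkers x %d steps (dt %g ps), %d ions each, %s\n",
    x$n_walkers, x$n_steps, x$params$dt, x$params$n_ions,
    if (is.null(x$metadynamics)) "unbiased" else
      sprintf("%d hills deposited", nrow(x$hills))))
  invisible(x)
}

#' Long-format per-ion table from a toy-pore simulation
#'
#' @param sim a [simulate_toy_pore()] result.
#' @return data.frame with one row per (snapshot, ion): `snapshot` (index
#'   into the snapshot/CV vectors), `time`, `walker`, `ion`, `z`, `r`.
#' @export
snapshot_ions <- function(sim) {
  stopifnot(inherits(sim, "toy_pore_sim"))
  s <- sim$snapshots
  n_ions <- sim$params$n_ions
  ns <- nrow(s)
  data.frame(
    snapshot = rep(seq_len(ns), times = n_ions),
    time = rep(s[, "time"], times = n_ions),
    walker = rep(s[, "walker"], times = n_ions),
    ion = rep(seq_len(n_ions), each = ns),
    z = as.numeric(s[, 4 + seq_len(n_ions)]),
    r = as.numeric(s[, 4 + n_ions + seq_len(n_ions)])
  )
}

#' Analytic ground-truth PMF of the toy pore
#'
#' By construction (uniform accessible cross-section) the free-energy
#' profile is the imposed axial potential plus the field term:
#' \eqn{F(z) = U_0 e^{-z^2/2w^2} - q E_z z}, anchored so that its
#' occupancy-weighted bulk value is ~0 (for zero field this is 0 in the
#' reservoirs automatically; `anchor` applies the same convention as
#' [pmf_from_occupancy()] for comparability).
#'
#' @param params a [toy_pore_params()].
#' @param z axial positions, Angstrom.
#' @param anchor `|z|` interval over which the mean is anchored to zero.
#' @return numeric vector F_true(z), kcal/mol.
#' @export
analytic_toy_pmf <- function(params, z, anchor = c(30, 40)) {
  stopifnot(inherits(params, "toy_pore_params"))
  f <- params$barrier_height * exp(-z^2 / (2 * params$barrier_width^2)) -
    params$field * z
  in_anchor <- abs(z) >= anchor[1] & abs(z) <= anchor[2]
  if (any(in_anchor)) {
    kT <- kBT(params$temperature)
    rho <- exp(-f[in_anchor] / kT)
    f <- f - sum(f[in_anchor] * rho) / sum(rho)
  }
  f
}

#' Hydration fixture: point cloud with a known switching count
#'
#' Places exactly `n_in` oxygens uniformly inside `0.9 * r0` of the ion and
#' `n_out` in the shell `[1.4 * r0, 2 * r0]` (safely outside the switching
#' region), so the smooth switching count equals `n_in` to within 1e-6.
#'
#' @param n_in,n_out inner and outer point counts (>= 0).
#' @param r0 switching radius, Angstrom.
#' @param seed integer seed.
#' @return matrix (n_in + n_out) x 3 of oxygen positions around an ion at
#'   the origin, with attribute `expected` = `n_in`.
#' @export
hydration_fixture <- function(n_in, n_out, r0 = 3.5, seed = 1) {
  stopifnot(n_in >= 0, n_out >= 0, r0 > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shell <- function(n, r_min, r_max) {
    if (n == 0) return(matrix(numeric(0), 0, 3))
    r <- (r_min^3 + (r_max^3 - r_min^3) * runif(n))^(1 / 3)
    u <- rnorm(n); v <- rnorm(n); w <- rnorm(n)
    s <- sqrt(u^2 + v^2 + w^2)
    cbind(r * u / s, r * v / s, r * w / s)
  }
  pts <- rbind(shell(n_in, 0, 0.9 * r0), shell(n_out, 1.4 * r0, 2 * r0))
  attr(pts, "expected") <- n_in
  pts
}

#' Gaussian FEP window samples with closed-form ground truth
#'
#' Per window i, energy differences are drawn from N(mu_i, sigma_i^2); the
#' exponential-average free energy of such a window is exactly
#' \eqn{\mu_i - \sigma_i^2 / 2 k_B T}. The backward leg is generated
#' consistently with the fluctuation theorem: for a Gaussian forward work
#' distribution N(mu, sigma^2), the thermodynamically consistent backward
#' distribution is N(-mu + sigma^2/k_B T, sigma^2) (reversed window order),
#' so forward/backward hysteresis vanishes as the sample size grows.
#'
#' @param mu,sigma per-window mean and sd of Delta U, kcal/mol (recycled to
#'   the number of windows of `schedule`).
#' @param n samples per window (>= 1).
#' @param schedule lambda values (see [fep_schedule()]); windows are the
#'   consecutive pairs.
#' @param temperature Kelvin.
#' @param seed integer seed.
#' @return list: `forward` and `backward` sample tables (columns
#'   `window`, `lambda_from`, `lambda_to`, `delta_u`), `delta_g_true`
#'   (total forward Delta G, kcal/mol).
#' @export
generate_fep_samples <- function(mu, sigma, n, schedule = fep_schedule("pore"),
                                 temperature = 298, seed = 1) {
  stopifnot(n >= 1)
  nw <- length(schedule) - 1L
  mu <- rep_len(mu, nw)
  sigma <- rep_len(sigma, nw)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fwd <- do.call(rbind, lapply(seq_len(nw), function(i) {
    data.frame(window = i, lambda_from = schedule[i],
               lambda_to = schedule[i + 1],
               delta_u = rnorm(n, mu[i], sigma[i]))
  }))
  kT <- kBT(temperature)
  bwd <- do.call(rbind, lapply(seq_len(nw), function(i) {
    j <- nw + 1L - i
    data.frame(window = i, lambda_from = schedule[j + 1],
               lambda_to = schedule[j],
               delta_u = rnorm(n, -mu[j] + sigma[j]^2 / kT, sigma[j]))
  }))
  list(forward = fwd, backward = bwd,
       delta_g_true = sum(mu - sigma^2 / (2 * kT)))
}

#' Synthetic whole-cell recording for a linear single-channel conductance
#'
#' Plateau currents follow \eqn{I = \gamma (V - E_{rev})} plus an ohmic leak
#' and Gaussian sampling noise; a matched "inhibited" sweep set retains only
#' `inhibited_fraction` of the channel component (leak unchanged), for
#' background-subtraction tests.
#'
#' @param gamma_pS channel conductance, pS.
#' @param e_rev_mV reversal potential, mV.
#' @param noise_sd per-sample current noise, pA.
#' @param voltages step voltages, mV.
#' @param leak_pS ohmic background conductance reversing at 0 mV.
#' @param inhibited_fraction channel fraction remaining under inhibitor.
#' @param t_ms sample times per sweep, ms.
#' @param seed integer seed.
#' @return list with `control` and `inhibited` sweep tables (columns
#'   `voltage`, `time`, `current`, `condition`) and the generating truth.
#' @export
generate_synthetic_recording <- function(gamma_pS, e_rev_mV, noise_sd = 0,
                                         voltages = seq(-100, 100, by = 20),
                                         leak_pS = 0.5,
                                         inhibited_fraction = 0.1,
                                         t_ms = seq(0, 100, by = 0.5),
                                         seed = 1) {
  stopifnot(gamma_pS >= 0, noise_sd >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sweep_set <- function(frac, condition) {
    do.call(rbind, lapply(voltages, function(v) {
      i_chan <- frac * gamma_pS * (v - e_rev_mV) * 1e-3  # pS * mV -> pA
      i_leak <- leak_pS * v * 1e-3
      data.frame(voltage = v, time = t_ms,
                 current = i_chan + i_leak +
                   rnorm(length(t_ms), 0, noise_sd),
                 condition = condition)
    }))
  }
  list(control = sweep_set(1, "control"),
       inhibited = sweep_set(inhibited_fraction, "inhibited"),
       truth = list(gamma_pS = gamma_pS, e_rev_mV = e_rev_mV,
                    leak_pS = leak_pS,
                    inhibited_fraction = inhibited_fraction))
}

# Save/restore the global RNG state so generators are pure in (params, seed)
# without clobbering the caller's stream.
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
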