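# Independent oracles and small fixture builders shared across tests.

# brute-force projection of positions onto an axis through `origin`
oracle_pore_coords <- function(positions, origin, u) {
  t(apply(rbind(positions), 1, function(p) {
    d <- p - origin
    z <- sum(d * u)
    c(z = z, r = sqrt(sum((d - z * u)^2)))
  }))
}

# hand-rolled crossing scanner built on run-length encoding of the region
# symbol sequence (+1 above, -1 below, 0 inside): a transit is an inside run
# flanked by opposite outside runs, valid if r stayed within r0 throughout
oracle_transits <- function(z, r, z_lo, z_hi, r0) {
  sym <- ifelse(z > z_hi, 1L, ifelse(z < z_lo, -1L, 0L))
  runs <- rle(sym)
  vals <- runs$values
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  inward <- 0L; outward <- 0L
  for (j in seq_along(vals)) {
    if (vals[j] == 0L && j > 1L && j < length(vals) &&
        all(r[starts[j]:ends[j]] <= r0)) {
      if (vals[j - 1] == 1L && vals[j + 1] == -1L) inward <- inward + 1L
      if (vals[j - 1] == -1L && vals[j + 1] == 1L) outward <- outward + 1L
    }
  }
  list(inward = inward, outward = outward)
}

# direct high-precision soft-min formula
oracle_softmin <- function(dz, beta = 100, C = 2) {
  beta / log(sum(exp(beta / (abs(dz) + C)))) - C
}

# per-hill analytic Gaussian with the four-image construction
oracle_hill_field <- function(zeta_a, zeta_b, cA, cB, sA, sB, h) {
  ga <- exp(-(zeta_a - cA)^2 / (2 * sA^2)) + exp(-(zeta_a + cA)^2 / (2 * sA^2))
  gb <- exp(-(zeta_b - cB)^2 / (2 * sB^2)) + exp(-(zeta_b + cB)^2 / (2 * sB^2))
  h * ga * gb
}

# uniform-permittivity dielectric lattice (all regions set to `eps`)
uniform_dielectric <- function(n, spacing, eps) {
  dielectric_map(NULL,
                 region_spec(eps_protein = eps, eps_membrane = eps,
                             eps_bulk = eps, eps_pore_water = eps,
                             eps_ion_cavity = eps),
                 lattice_spec(n = n, spacing = spacing))
}

# analytic image-charge potential for a charge q at (0, 0, d) above a planar
# interface at z = 0 separating eps1 (z > 0) from eps2 (z < 0)
oracle_image_potential <- function(x, y, z, d, q, eps1, eps2,
                                   rmin = 0.5) {
  k <- permeon_constants$coulomb
  rr <- pmax(sqrt(x^2 + y^2 + (z - d)^2), rmin)
  ri <- pmax(sqrt(x^2 + y^2 + (z + d)^2), rmin)
  qi <- (eps1 - eps2) / (eps1 + eps2)
  qt <- 2 * eps2 / (eps1 + eps2)
  ifelse(z >= 0, k * q / eps1 * (1 / rr + qi / ri), k * q / eps2 * qt / rr)
}

# random rigid rotation matrix from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  qr.Q(qr(m))
}
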