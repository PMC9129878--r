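test_that("region geometry without atoms matches the analytic slab and
           cylinder volumes", {
  g <- lattice_spec(n = 40, spacing = 1)
  reg <- region_spec(membrane_thickness = 10, pore_cylinder_radius = 6,
                     pore_cylinder_height = 10)
  dm <- dielectric_map(NULL, reg, g)
  vox <- g$spacing^3
  n_mem <- sum(dm$region == 1L) * vox
  n_cyl <- sum(dm$region == 2L) * vox
  slab_vol <- 39^2 * 11  # node-counting: 11 planes of the 39 A x 39 A box
  cyl_vol <- pi * 6^2 * 11
  expect_lt(abs(n_cyl - cyl_vol) / cyl_vol, 0.15)  # one surface voxel layer
  expect_lt(abs(n_mem + n_cyl - slab_vol) / slab_vol, 0.05)
  expect_true(all(dm$eps[dm$region == 0L] == 80))
  expect_true(all(dm$eps[dm$region == 2L] == 40))
})

test_that("a single atom claims the probe-inflated sphere", {
  g <- lattice_spec(n = 21, spacing = 1)
  reg <- region_spec(membrane_thickness = 1, pore_cylinder_radius = 1,
                     pore_cylinder_height = 1)
  dm <- dielectric_map(data.frame(x = 0, y = 0, z = 0, radius = 2), reg, g)
  nodes <- expand.grid(x = g$x, y = g$y, z = g$z)
  r <- sqrt(nodes$x^2 + nodes$y^2 + nodes$z^2)
  prot <- as.vector(dm$region) == 4L
  expect_true(all(prot[r <= 3]))          # radius + probe
  expect_true(all(!prot[r > 4.8]))        # closing adds at most one voxel
  expect_error(dielectric_map(data.frame(x = 100, y = 0, z = 0, radius = 2),
                              reg, g), "beyond")
})

test_that("zero charges give a zero potential and the solve is linear", {
  dm <- uniform_dielectric(24, 1, 80)
  pot0 <- solve_poisson(data.frame(x = 0, y = 0, z = 0, q = 0), dm)
  expect_equal(max(abs(pot0$phi)), 0, tolerance = 1e-10)
  ch <- data.frame(x = c(-2, 3), y = c(1, 0), z = c(0, 2), q = c(1, -0.5))
  p1 <- solve_poisson(ch, dm, tol = 1e-7)
  ch2 <- ch; ch2$q <- 2 * ch$q
  p2 <- solve_poisson(ch2, dm, tol = 1e-7)
  expect_equal(p2$phi, 2 * p1$phi, tolerance = 1e-4)
})

test_that("point-charge potential matches Coulomb in a uniform dielectric", {
  dm <- uniform_dielectric(48, 1, 80)
  pot <- solve_poisson(data.frame(x = 0, y = 0, z = 0, q = 1), dm,
                       tol = 1e-6)
  pts <- as.matrix(expand.grid(x = seq(-15, 15, 5), y = seq(-15, 15, 5),
                               z = seq(-15, 15, 5)))
  r <- sqrt(rowSums(pts^2))
  keep <- r >= 5
  phi <- interpolate_potential(pot, pts[keep, ])
  ana <- permeon_constants$coulomb / (80 * r[keep])
  expect_lt(max(abs(phi - ana) / ana), 0.03)
})

test_that("reciprocity: interaction energy is symmetric in the two charges", {
  dm <- uniform_dielectric(32, 1, 40)
  a <- c(-4, 0, 0); b <- c(5, 2, -1)
  pa <- solve_poisson(data.frame(x = a[1], y = a[2], z = a[3], q = 1), dm,
                      tol = 1e-7)
  pb <- solve_poisson(data.frame(x = b[1], y = b[2], z = b[3], q = 1), dm,
                      tol = 1e-7)
  e_ab <- ion_protein_energy(1, pa, b)
  e_ba <- ion_protein_energy(1, pb, a)
  expect_equal(e_ab, e_ba, tolerance = 1e-3)
})

test_that("ion-protein energy is zero for a neutral probe and linear in q", {
  dm <- uniform_dielectric(24, 1, 80)
  pot <- solve_poisson(data.frame(x = 0, y = 0, z = 0, q = 1), dm)
  expect_equal(ion_protein_energy(0, pot, c(4, 0, 0)), 0)
  e1 <- ion_protein_energy(1, pot, c(4, 0, 0))
  expect_equal(ion_protein_energy(2.5, pot, c(4, 0, 0)), 2.5 * e1)
  expect_error(ion_protein_energy(1, pot, c(100, 0, 0)), "outside")
})

test_that("a negative charge ring attracts a cation with the minimum at
           closest approach, matching per-frame energies", {
  # four negative charges ringing the pore at z = 0
  ring <- data.frame(x = c(6, -6, 0, 0), y = c(0, 0, 6, -6), z = 0,
                     q = rep(-0.25, 4))
  g <- lattice_spec(n = 32, spacing = 1.25)
  reg <- region_spec(eps_membrane = 80, eps_pore_water = 80)  # uniform water
  ax <- pore_axis(rbind(c(0, 0, 1)), rbind(c(0, 0, -1)))
  zs <- c(-8, -4, 0, 4, 8)
  frames <- lapply(zs, function(z0) {
    list(protein = cbind(ring, radius = 1.5),
         ions = data.frame(x = 0, y = 0, z = z0, q = 1))
  })
  eb <- structure(list(grid = bias_grid(-2, 4, 0.5), window = c(0, 1)),
                  class = "effective_bias")
  w <- snapshot_weights(rep(1, 5), rep(1, 5), eb)
  prof <- electrostatic_profile(frames, ax, w, breaks = seq(-10, 10, 2),
                                region = reg, grid = g, tol = 1e-6)
  vals <- prof$value[!is.na(prof$value)]
  expect_true(all(vals < 0))
  expect_equal(prof$z[which.min(prof$value)], 1)  # bin holding z = 0
  # compositional oracle: each bin equals the direct per-frame energy
  for (i in seq_along(zs)) {
    dmi <- dielectric_map(frames[[i]]$protein, reg, g,
                          ion_positions = rbind(c(0, 0, zs[i])))
    poti <- solve_poisson(ring, dmi, tol = 1e-6)
    ei <- ion_protein_energy(1, poti, c(0, 0, zs[i]))
    bin <- findInterval(zs[i], seq(-10, 10, 2), rightmost.closed = TRUE)
    expect_equal(prof$value[bin], ei, tolerance = 1e-6)
  }
  # neutral ring gives an identically zero profile
  frames0 <- lapply(frames, function(f) { f$protein$q <- 0; f })
  prof0 <- electrostatic_profile(frames0, ax, w, breaks = seq(-10, 10, 2),
                                 region = reg, grid = g, tol = 1e-6)
  expect_equal(max(abs(prof0$value), na.rm = TRUE), 0, tolerance = 1e-10)
})
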