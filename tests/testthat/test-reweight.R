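# helpers to build a tiny effective bias with prescribed values at CV points
flat_ebias <- function(value = 0, lo = -2, hi = 6, spacing = 0.5) {
  g <- bias_grid(lo, hi, spacing)
  g$values[] <- value
  structure(list(grid = g, window = c(0, 1)), class = "effective_bias")
}

test_that("constant bias gives uniform weights; kBT ln 2 difference gives a
           2:1 ratio", {
  eb <- flat_ebias(3.21)
  w <- snapshot_weights(rep(1, 10), rep(1, 10), eb)
  expect_equal(w$weights, rep(0.1, 10), tolerance = 1e-12)
  # two snapshots at cells differing by kBT ln 2
  eb2 <- flat_ebias(0)
  kT <- kBT(298)
  ia <- which.min(abs(eb2$grid$zeta - 2))
  eb2$grid$values[ia, ia] <- kT * log(2)
  w2 <- snapshot_weights(c(2, 0), c(2, 0), eb2, temperature = 298)
  expect_equal(w2$weights[1] / w2$weights[2], 2, tolerance = 1e-9)
})

test_that("weights match the explicit formula for a random bias", {
  set.seed(1)
  eb <- flat_ebias(0)
  eb$grid$values[] <- runif(eb$grid$n^2, 0, 3)
  za <- runif(50, 0, 5); zb <- runif(50, 0, 5)
  w <- snapshot_weights(za, zb, eb, temperature = 310)
  kT <- kBT(310)
  g <- eb$grid
  v <- g$values[cbind(round((za - g$lo) / g$spacing) + 1,
                      round((zb - g$lo) / g$spacing) + 1)]
  expect_equal(w$weights, exp(v / kT) / sum(exp(v / kT)), tolerance = 1e-12)
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
  # scale invariance: adding a constant to the bias changes nothing
  eb_shift <- eb
  eb_shift$grid$values <- eb$grid$values + 7.7
  w_shift <- snapshot_weights(za, zb, eb_shift, temperature = 310)
  expect_equal(w_shift$weights, w$weights, tolerance = 1e-12)
})

test_that("out-of-grid CV values are clamped with a warning", {
  eb <- flat_ebias(0)
  expect_warning(snapshot_weights(c(1, 99), c(1, 1), eb), "clamped")
  expect_error(snapshot_weights(numeric(0), numeric(0), eb), "no snapshots")
})

test_that("occupancy lands in the right bins and respects the R0 gate", {
  eb <- flat_ebias(0)
  w <- snapshot_weights(rep(1, 4), rep(1, 4), eb)
  breaks <- seq(-2, 2, by = 0.5)
  ions <- data.frame(snapshot = 1:4, z = rep(0.1, 4), r = c(0, 1, 12, 3))
  occ <- occupancy_profile(ions, w, breaks, r0 = 10)
  expect_equal(sum(occ$value), 0.75)  # ion with r = 12 excluded
  expect_equal(occ$value[occ$z == 0.25], 0.75)
  expect_error(occupancy_profile(ions, w, c(0, 0, 1)), "zero-width")
})

test_that("a flat occupancy gives F = 0 and ratios give kBT", {
  z <- seq(-1, 1, by = 0.5)
  kT <- kBT(298)
  occ <- pore_profile(c(-0.5, 0.5), c(exp(-1), 1), c(1, 1),
                      quantity = "occupancy")
  f <- pmf_from_occupancy(occ, 298, anchor = c(0, 1))
  expect_equal(f$value[1] - f$value[2], kT, tolerance = 1e-9)
  flat <- pore_profile(seq(-40, 40, 1), rep(0.2, 81), rep(1, 81))
  f2 <- pmf_from_occupancy(flat, 298)
  expect_equal(f2$value, rep(0, 81), tolerance = 1e-9)
  # occupancy-weighted anchor mean is zero
  expect_equal(sum(f2$value * flat$value) / sum(flat$value), 0,
               tolerance = 1e-9)
  empty <- pore_profile(c(0, 1), c(0, 0))
  expect_error(pmf_from_occupancy(empty), "zero everywhere")
})

test_that("empty bins are masked, never zero-filled", {
  occ <- pore_profile(seq(-35.5, 35.5, 1), c(rep(1, 30), rep(0, 12),
                                             rep(1, 30)))
  f <- pmf_from_occupancy(occ, 298)
  expect_true(all(is.na(f$value[occ$value == 0])))
  expect_true(all(!is.na(f$value[occ$value > 0])))
})

test_that("observable profiles reproduce constants, positions and the
           weighted-mean oracle", {
  eb <- flat_ebias(0)
  breaks <- seq(-5, 5, by = 1)
  set.seed(12)
  ns <- 200
  w <- snapshot_weights(runif(ns, 0, 4), runif(ns, 0, 4), eb)
  ions <- data.frame(snapshot = rep(1:ns, 2),
                     z = runif(2 * ns, -5, 5), r = runif(2 * ns, 0, 3))
  # constant observable
  ions$obs <- 4.2
  prof <- observable_profile(ions, w, breaks)
  expect_equal(prof$value[!is.na(prof$value)],
               rep(4.2, sum(!is.na(prof$value))), tolerance = 1e-12)
  # O = z reproduces bin centres to half a bin width
  ions$obs <- ions$z
  prof_z <- observable_profile(ions, w, breaks)
  ok <- !is.na(prof_z$value)
  expect_true(all(abs(prof_z$value[ok] - prof_z$z[ok]) <= 0.5))
  # random O matches a direct weighted mean per bin
  ions$obs <- rnorm(nrow(ions))
  prof_r <- observable_profile(ions, w, breaks)
  idx <- findInterval(ions$z, breaks, rightmost.closed = TRUE)
  for (b in which(!is.na(prof_r$value))) {
    sel <- idx == b
    expect_equal(prof_r$value[b],
                 sum(w$weights[ions$snapshot[sel]] * ions$obs[sel]) /
                   sum(w$weights[ions$snapshot[sel]]),
                 tolerance = 1e-12)
  }
  expect_error(observable_profile(ions[, 1:3], w, breaks), "no observable")
})

test_that("reweighting identity: constant bias reproduces the naive
           Boltzmann histogram", {
  set.seed(3)
  ns <- 5000
  z <- rnorm(ns, 0, 10)
  z <- z[abs(z) < 20]
  ions <- data.frame(snapshot = seq_along(z), z = z, r = 0)
  eb <- flat_ebias(1.23)
  w <- snapshot_weights(rep(1, length(z)), rep(1, length(z)), eb)
  breaks <- seq(-20, 20, by = 2)
  occ <- occupancy_profile(ions, w, breaks)
  f <- pmf_from_occupancy(occ, 298, anchor = c(0, 20))
  hist_counts <- hist(z, breaks = breaks, plot = FALSE)$counts
  f_naive <- -kBT(298) * log(hist_counts / length(z))
  rho <- hist_counts / length(z)
  offset <- sum(f_naive * rho) / sum(rho)
  expect_equal(f$value, f_naive - offset, tolerance = 1e-9)
})

test_that("split-half on duplicated halves vanishes; disjoint constants give
           their difference", {
  eb <- flat_ebias(0)
  ns <- 40
  half_z <- runif(ns / 2, -3, 3)
  ions <- data.frame(snapshot = 1:ns, z = c(half_z, half_z), r = 0)
  ions$obs <- 1
  sh <- split_half_profiles(ions, rep(1, ns), rep(1, ns), times = 1:ns,
                            ebias = eb, breaks = seq(-4, 4, 1), r0 = 10,
                            anchor = c(0, 4))
  expect_equal(sh$mean_abs_difference, 0, tolerance = 1e-12)
  # constant observable c1 in the first half, c2 in the second
  ions$obs <- rep(c(2.5, 4.0), each = ns / 2)
  sh2 <- split_half_profiles(ions, rep(1, ns), rep(1, ns), times = 1:ns,
                             ebias = eb, breaks = seq(-4, 4, 1),
                             observable = TRUE)
  expect_equal(sh2$mean_abs_difference, 1.5, tolerance = 1e-12)
  expect_error(split_half_profiles(ions[1, ], 1, 1, times = 1, ebias = eb),
               "two snapshots")
})
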