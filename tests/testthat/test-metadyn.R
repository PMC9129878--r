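test_that("an on-boundary hill has zero bias slope across zeta = 0", {
  g <- bias_grid(lo = -2, hi = 6, spacing = 0.05)
  h <- hill_records(time = 0, zeta_a = 0, zeta_b = 0, height = 0.01)
  g <- deposit_hills(g, h)
  i0 <- which(abs(g$zeta) < 1e-12)
  # symmetric neighbours across zetaA = 0 (and zetaB = 0) are equal
  expect_equal(g$values[i0 - 1, ], g$values[i0 + 1, ], tolerance = 1e-12)
  expect_equal(g$values[, i0 - 1], g$values[, i0 + 1], tolerance = 1e-12)
})

test_that("image contributions are negligible for hills far from the boundary", {
  g <- bias_grid(lo = -2, hi = 15, spacing = 0.05)
  g <- deposit_hills(g, hill_records(0, 10, 10, height = 1))
  ia <- which.min(abs(g$zeta - 10))
  peak <- g$values[ia, ia]
  expect_equal(peak, 1, tolerance = 1e-10)  # image adds < 1e-12 of height
})

test_that("deposition is additive, order-independent and matches the
           per-hill analytic oracle", {
  set.seed(99)
  n_hills <- 1000
  hills <- hill_records(time = seq_len(n_hills),
                        zeta_a = runif(n_hills, 0, 8),
                        zeta_b = runif(n_hills, 0, 8),
                        sigma_a = 0.25, sigma_b = 0.25,
                        height = runif(n_hills, 0.001, 0.01))
  g0 <- bias_grid(lo = -2, hi = 9, spacing = 0.1)
  g <- deposit_hills(g0, hills)
  # oracle: sum of analytic per-hill fields at a sample of lattice points
  idx <- cbind(sample(g0$n, 40), sample(g0$n, 40))
  for (row in seq_len(nrow(idx))) {
    za <- g0$zeta[idx[row, 1]]; zb <- g0$zeta[idx[row, 2]]
    # 6-sigma deposition cutoff: restrict the oracle to contributing hills
    expect_equal(g$values[idx[row, 1], idx[row, 2]],
                 sum(oracle_hill_field(za, zb, hills$zeta_a, hills$zeta_b,
                                       0.25, 0.25, hills$height) *
                       (abs(za - hills$zeta_a) < 1.5 | abs(za + hills$zeta_a) < 1.5) *
                       (abs(zb - hills$zeta_b) < 1.5 | abs(zb + hills$zeta_b) < 1.5)),
                 tolerance = 1e-10)
  }
  shuffled <- hills[sample(n_hills), ]
  g2 <- deposit_hills(g0, shuffled)
  expect_equal(g$values, g2$values, tolerance = 1e-10)
  expect_true(all(g$values >= 0))
  expect_lt(max(g$values), n_hills * 0.01 * 4)
  expect_error(deposit_hills(g0, hill_records(0, 1, 1, sigma_a = -0.1,
                                              height = 1)))
})

test_that("hill heights follow the rise/hold/decay schedule", {
  sch <- height_schedule()  # 0.0035 -> 0.007 over 30 ns, back by 100 ns
  expect_equal(schedule_height(0, sch), 0.0035)
  expect_equal(schedule_height(30, sch), 0.007)
  expect_equal(schedule_height(200, sch), 0.0035)
  expect_equal(schedule_height(15, sch), 0.00525)  # linear ramp midpoint
  expect_equal(schedule_height(65, sch), 0.00525)  # linear decay midpoint
  expect_error(height_schedule(h0 = 0.01, h_peak = 0.005))
})

test_that("walker hill streams merge by time with walker-id tie-break", {
  a <- hill_records(c(1, 3, 5), 1, 1, height = 1, walker = 0)
  b <- hill_records(c(2, 3, 6), 1, 1, height = 1, walker = 1)
  m <- merge_walker_hills(list(b, a))
  expect_equal(m$time, c(1, 2, 3, 3, 5, 6))
  expect_equal(m$walker[m$time == 3], c(0L, 1L))
  expect_identical(merge_walker_hills(list(a))$time, a$time)
  set.seed(5)
  streams <- lapply(0:7, function(w)
    hill_records(sort(runif(50, 0, 100)), runif(50, 0, 5), runif(50, 0, 5),
                 height = 0.005, walker = w))
  m8 <- merge_walker_hills(streams)
  all_cat <- do.call(rbind, streams)
  expect_equal(m8$time, sort(all_cat$time))
  expect_false(is.unsorted(m8$time))
  bad <- hill_records(c(5, 1), 1, 1, height = 1)
  expect_error(merge_walker_hills(list(bad)), "sorted")
})

test_that("time averaging of bias snapshots is the pointwise mean", {
  g <- bias_grid(lo = -2, hi = 3, spacing = 0.5)
  g1 <- g; g1$values[] <- 1
  g2 <- g; g2$values[] <- 3
  eb <- time_average_bias(list(g1, g1, g1), c(1, 2, 3), c(0, 4))
  expect_equal(eb$grid$values, g1$values)
  eb2 <- time_average_bias(list(g1, g2), c(1, 2), c(0, 3))
  expect_equal(unique(as.vector(eb2$grid$values)), 2)
  set.seed(31)
  grids <- lapply(1:6, function(i) { gi <- g; gi$values[] <- rnorm(g$n^2); gi })
  eb3 <- time_average_bias(grids, 1:6, c(2, 5))
  manual <- (grids[[2]]$values + grids[[3]]$values + grids[[4]]$values +
               grids[[5]]$values) / 4
  expect_equal(eb3$grid$values, manual, tolerance = 1e-12)
  expect_error(time_average_bias(grids, 1:6, c(10, 20)), "window")
})

test_that("effective bias from a hill log equals snapshot-built averages", {
  set.seed(8)
  hills <- hill_records(time = sort(runif(60, 0, 100)),
                        zeta_a = runif(60, 0, 4), zeta_b = runif(60, 0, 4),
                        height = runif(60, 0.002, 0.01))
  g <- bias_grid(lo = -2, hi = 6, spacing = 0.1)
  ts <- seq(40, 100, length.out = 7)
  eb <- effective_bias_from_hills(hills, g, c(40, 100), n_samples = 7)
  grids <- lapply(ts, function(t) deposit_hills(g, hills[hills$time <= t, ]))
  eb_manual <- time_average_bias(grids, ts, c(39, 101))
  expect_equal(eb$grid$values, eb_manual$grid$values, tolerance = 1e-10)
})

test_that("hills files round-trip at the printed precision", {
  set.seed(2)
  hills <- hill_records(time = sort(runif(20, 0, 50)),
                        zeta_a = runif(20, 0, 30), zeta_b = runif(20, 0, 30),
                        sigma_a = 0.25, sigma_b = 0.25,
                        height = runif(20, 0.001, 0.01),
                        walker = sample(0:3, 20, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".hills")
  write_hills(hills, path)
  back <- read_hills(path)
  reprint <- function(x) as.numeric(sprintf("%.10g", x))
  expect_identical(back$time, reprint(hills$time))
  expect_identical(back$height, reprint(hills$height))
  expect_identical(back$walker, hills$walker)
  path2 <- withr::local_tempfile(fileext = ".hills")
  write_hills(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
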