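test_that("IV extraction averages the plateau window per voltage", {
  sweeps <- data.frame(voltage = rep(c(-20, 20), each = 100),
                       time = rep(seq(0, 99), 2),
                       current = c(rep(5, 100), rep(-3, 100)))
  iv <- iv_from_sweeps(sweeps, window = c(40, 80))
  expect_equal(iv$current[iv$voltage == -20], 5)
  expect_equal(iv$current[iv$voltage == 20], -3)
  expect_error(iv_from_sweeps(sweeps, window = c(90, 120)), "outside")
  # plateau value recovered within 3 SEM under noise
  set.seed(1)
  tr <- data.frame(voltage = 100, time = seq(0, 200, 0.5))
  tr$current <- ifelse(tr$time < 20, 0, 8) + rnorm(nrow(tr), 0, 1)
  ivn <- iv_from_sweeps(tr, window = c(50, 200))
  n_in <- sum(tr$time >= 50)
  expect_lt(abs(ivn$current - 8), 3 / sqrt(n_in) + 0.2)
})

test_that("background subtraction is the pointwise difference", {
  v <- seq(-100, 100, 20)
  ctrl <- structure(data.frame(voltage = v, current = v * 0.01 + 1),
                    class = c("iv_curve", "data.frame"))
  inh <- structure(data.frame(voltage = v, current = v * 0.004),
                   class = c("iv_curve", "data.frame"))
  dif <- subtract_background(ctrl, inh)
  expect_equal(dif$current, ctrl$current - inh$current)
  expect_equal(subtract_background(ctrl, ctrl)$current, rep(0, length(v)))
  zero <- inh; zero$current <- 0
  expect_equal(subtract_background(ctrl, zero)$current, ctrl$current)
  bad <- inh; bad$voltage <- bad$voltage + 1
  expect_error(subtract_background(ctrl, bad), "grids")
})

test_that("reversal potential is exact for a line and matches a root-finder
           for a cubic IV", {
  v <- seq(-100, 100, 20)
  iv <- structure(data.frame(voltage = v, current = 0.4 * (v + 76)),
                  class = c("iv_curve", "data.frame"))
  expect_equal(reversal_potential(iv), -76, tolerance = 1e-12)
  # scaling invariance
  iv2 <- iv; iv2$current <- iv$current * 17
  expect_equal(reversal_potential(iv2), -76, tolerance = 1e-12)
  pos <- iv; pos$current <- abs(iv$current) + 1
  expect_error(reversal_potential(pos), "cross")
  f <- function(v) 1e-5 * (v - 31)^3 + 0.002 * (v - 31)
  ivc <- structure(data.frame(voltage = v, current = f(v)),
                   class = c("iv_curve", "data.frame"))
  root <- uniroot(f, c(-100, 100))$root
  expect_lt(abs(reversal_potential(ivc) - root), 1)
})

test_that("multiple crossings pick the one nearest 0 mV with a warning", {
  v <- seq(-100, 100, 20)
  i <- sin((v + 10) / 25)
  iv <- structure(data.frame(voltage = v, current = i),
                  class = c("iv_curve", "data.frame"))
  expect_warning(e <- reversal_potential(iv), "multiple")
  expect_lt(abs(e + 10), 10)
})

test_that("bi-ionic permeability ratios reproduce the printed wild-type and
           mutant values", {
  expect_equal(permeability_ratio(0), 1)
  expect_equal(signif(permeability_ratio(-76), 2), 20)
  expect_equal(signif(permeability_ratio(-13), 2), 1.7)
  expect_equal(signif(permeability_ratio(-16), 2), 1.9)
  # symmetry: reversing the potential inverts the ratio
  expect_equal(permeability_ratio(-40) * permeability_ratio(40), 1,
               tolerance = 1e-12)
})

test_that("dose-response fit recovers noiseless parameters and is monotone", {
  conc <- c(0, 0.2, 0.5, 1, 2, 5, 10, 20)
  truth <- list(i_max = 1, i_min = 0.12, ic50 = 2)
  i <- truth$i_min + (truth$i_max - truth$i_min) * truth$ic50 /
    (truth$ic50 + conc)
  fit <- fit_dose_response(conc, i)
  expect_equal(fit$ic50, 2, tolerance = 1e-6)
  expect_equal(fit$i_max, 1, tolerance = 1e-6)
  expect_equal(fit$i_min, 0.12, tolerance = 1e-6)
  # at the IC50 the model sits exactly halfway
  expect_equal(fit$fitted(2), (fit$i_max + fit$i_min) / 2, tolerance = 1e-6)
  cgrid <- seq(0, 30, 0.1)
  expect_true(all(diff(fit$fitted(cgrid)) <= 1e-12))
  expect_error(fit_dose_response(c(0, 1, 2), c(1, 0.5, 0.4)), "four")
  expect_error(fit_dose_response(c(5, 6, 7, 8), c(1, 0.9, 0.8, 0.7)),
               "near zero")
})

test_that("synthetic recordings close the loop from conductance to E_rev", {
  rec <- generate_synthetic_recording(0.4, -76, noise_sd = 0, seed = 2)
  ivc <- iv_from_sweeps(rec$control, c(10, 90))
  ivi <- iv_from_sweeps(rec$inhibited, c(10, 90))
  chan <- subtract_background(ivc, ivi)
  # subtraction leaves (1 - fraction) of the channel component
  expect_equal(reversal_potential(chan), -76, tolerance = 1e-9)
  slope <- diff(chan$current) / diff(chan$voltage) * 1e3
  expect_equal(mean(slope), 0.4 * (1 - 0.1), tolerance = 1e-9)
  # with the channel fully blocked the subtraction returns the channel IV
  rec0 <- generate_synthetic_recording(0.4, -76, noise_sd = 0,
                                       inhibited_fraction = 0, seed = 2)
  chan0 <- subtract_background(iv_from_sweeps(rec0$control, c(10, 90)),
                               iv_from_sweeps(rec0$inhibited, c(10, 90)))
  expect_equal(chan0$current, 0.4 * (chan0$voltage + 76) * 1e-3,
               tolerance = 1e-9)
  # noisy recovery is unbiased within 3 SE over 50 seeds (whole-cell scale:
  # nS conductances and pA-level noise)
  errs <- vapply(1:50, function(s) {
    r <- generate_synthetic_recording(2000, -76, noise_sd = 5,
                                      leak_pS = 500, seed = s)
    e <- reversal_potential(subtract_background(
      iv_from_sweeps(r$control, c(10, 90)),
      iv_from_sweeps(r$inhibited, c(10, 90))))
    e + 76
  }, numeric(1))
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)) + 0.01)
})
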