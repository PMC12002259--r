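test_that("Hill fit recovers parameters from noise-free and noisy curves", {
  concs <- c(12.5, 25, 50, 100, 200, 400, 800)
  clean <- simulate_binding_curve(100, 3, concs, noise_sd = 0)
  fit <- hill_fit(clean$conc, clean$fraction_bound)
  expect_equal(fit$kd_app, 100, tolerance = 1e-6)
  expect_equal(fit$hill, 3, tolerance = 1e-6)

  # H fixed to 1 on hyperbolic data: K is the half-saturation point
  hyp <- simulate_binding_curve(100, 1, concs, noise_sd = 0)
  fit1 <- hill_fit(hyp$conc, hyp$fraction_bound, fix_hill = 1)
  expect_equal(fit1$kd_app, 100, tolerance = 1e-6)
  expect_equal(predict(fit1, 100), 0.5, tolerance = 1e-6)

  noisy <- simulate_binding_curve(100, 3, concs, noise_sd = 0.05, seed = 7)
  fitn <- hill_fit(noisy$conc, noisy$fraction_bound, se = noisy$se)
  expect_equal(fitn$kd_app, 100, tolerance = 0.2)
  expect_lt(abs(fitn$hill - 3), 0.5)

  expect_error(hill_fit(concs, rep(0.5, length(concs))), "transition")
})

test_that("median Hill-coefficient error over many noisy curves is small", {
  # sqrt(2)-step titration bracketing the transition, as in a typical
  # gel-shift dilution series
  concs <- c(25, 35, 50, 70, 100, 140, 200, 280, 400)
  errs <- vapply(1:100, function(s) {
    tab <- simulate_binding_curve(100, 3, concs, noise_sd = 0.05, seed = s)
    f <- hill_fit(tab$conc, tab$fraction_bound, se = tab$se)
    abs(f$hill - 3)
  }, numeric(1))
  expect_lt(median(errs), 0.3)
})

test_that("annealing fit recovers the rate and reports the enhancement", {
  tab <- simulate_annealing(2.0, 1, times = c(1, 3, 8))
  fit <- annealing_fit(tab$time, tab$product_fraction,
                       control_rate = 1 / 15)
  expect_equal(fit$rate, 2.0, tolerance = 0.05)
  expect_equal(fit$rate_s, 2 / 60, tolerance = 0.05)   # ~ 0.033 s^-1
  expect_equal(fit$enhancement, 2.0 * 15, tolerance = 0.05)  # ~ 30x
  expect_equal(fit$time_constant, 0.5, tolerance = 0.05)

  dense <- simulate_annealing(0.8, 0.7, times = seq(0.5, 10, by = 0.5))
  fd <- annealing_fit(dense$time, dense$product_fraction)
  expect_equal(fd$rate, 0.8, tolerance = 1e-5)
  expect_equal(fd$amplitude, 0.7, tolerance = 1e-5)

  expect_warning(annealing_fit(1:5, c(0.9, 0.7, 0.5, 0.3, 0.1)), "decreas")
})

test_that("hill and annealing fits are scale-equivariant", {
  concs <- c(12.5, 25, 50, 100, 200, 400, 800)
  tab <- simulate_binding_curve(100, 3, concs, noise_sd = 0.03, seed = 2)
  f1 <- hill_fit(tab$conc, tab$fraction_bound, se = tab$se)
  f2 <- hill_fit(tab$conc * 1000, tab$fraction_bound, se = tab$se)
  expect_equal(f2$kd_app / f1$kd_app, 1000, tolerance = 1e-4)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-4)

  an <- simulate_annealing(2, 1, c(1, 3, 8), noise_sd = 0.02, seed = 3)
  a1 <- annealing_fit(an$time, an$product_fraction)
  a2 <- annealing_fit(an$time * 60, an$product_fraction)
  expect_equal(a1$rate / a2$rate, 60, tolerance = 1e-4)
})

test_that("off-rate, per-protomer Kd scaling and ring energy arithmetic", {
  expect_equal(off_rate(100, 1e8), 10)
  expect_equal(off_rate(0, 1e8), 0)
  expect_equal(off_rate(20, 1e8, unit = "pM"), 0.002)
  expect_error(off_rate(-1, 1e8))

  expect_equal(scaled_kd(100, 0), 100)
  # 0.34^8 ~ 2e-4: 100 nM -> ~20 pM
  expect_equal(scaled_kd(100, 8), 100 * 0.34^8)
  expect_equal(signif(scaled_kd(100, 8) * 1000, 1), 20)  # in pM
  expect_equal(scaled_kd(1, 10), 0.34^10)
  expect_lt(scaled_kd(1, 10), 1e-4)
  expect_error(scaled_kd(100, 2, f = 1.5))

  expect_equal(ring_closure_energy(1), 0)
  expect_equal(ring_closure_energy(exp(3)), 3)
  expect_equal(round(ring_closure_energy(1.9e6)), 14)
  expect_error(ring_closure_energy(0))
})

test_that("concentration unit round-trips are exact", {
  k1 <- off_rate(100, 1e8, unit = "nM")
  k2 <- off_rate(100e3, 1e8, unit = "pM")
  k3 <- off_rate(100e-9, 1e8, unit = "M")
  expect_identical(k1, k2)
  expect_identical(k1, k3)
})
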