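test_that("SD calibration line is fitted by least squares", {
  cal <- fit_sd_calibration(c(100, 300), c(10, 20))
  expect_equal(cal$sd_slope, 0.05)
  expect_equal(cal$sd_intercept, 5)
  expect_equal(calib_sd(cal, 200), 15)
  expect_error(fit_sd_calibration(c(100, 100), c(10, 11)))

  # a sample peak narrower than the calibration line is legitimate: the
  # line is only an upper bound (no stoichiometric spread)
  expect_lt(15.6, calib_sd(cal, 279.6))

  # recovery from noisy standards
  set.seed(31)
  m <- seq(60, 800, length.out = 12)
  sd_obs <- 0.03 * m + 6 + rnorm(12, sd = 0.6)
  cal2 <- fit_sd_calibration(m, sd_obs)
  se_slope <- summary(lm(sd_obs ~ m))$coefficients["m", "Std. Error"]
  expect_lt(abs(cal2$sd_slope - 0.03), 2.5 * se_slope)
})

test_that("a single Gaussian event cloud yields one undecamer peak", {
  calib <- default_calibration()
  set.seed(41)
  masses <- rnorm(5000, mean = 278.3, sd = 15.6)
  masses <- masses[masses >= calib$mass_min]
  ps <- deconvolve(masses, monomer_mass = 25.3, calib = calib,
                   max_components = 5)
  expect_equal(nrow(ps$peaks), 1L)
  expect_equal(ps$peaks$center, 278.3, tolerance = 2 / 278.3)
  expect_equal(ps$peaks$n, 11L)
  expect_equal(ps$peaks$area_fraction, 1)
  # SD respects the calibration upper bound
  expect_lte(ps$peaks$sd, calib_sd(calib, ps$peaks$center) + 1e-8)
})

test_that("two well-separated components are resolved with correct area split", {
  calib <- default_calibration()
  set.seed(42)
  m1 <- rnorm(4000, 100, calib_sd(calib, 100))
  m2 <- rnorm(1000, 500, calib_sd(calib, 500))
  masses <- c(m1, m2)
  masses <- masses[masses >= calib$mass_min]
  ps <- deconvolve(masses, monomer_mass = 100, calib = calib,
                   max_components = 6)
  expect_equal(ps$k, 2L)
  expect_equal(sort(ps$peaks$n), c(1L, 5L))
  expect_equal(sort(ps$peaks$area_fraction), c(0.2, 0.8), tolerance = 0.15)
  expect_equal(sum(ps$peaks$area_fraction), 1)
})

test_that("peaks below the 2% area threshold are pruned after selection", {
  calib <- default_calibration()
  set.seed(43)
  main <- rnorm(5000, 200, calib_sd(calib, 200))
  contam <- rnorm(75, 600, calib_sd(calib, 600))   # 1.5% contaminant
  masses <- c(main, contam)
  masses <- masses[masses >= calib$mass_min]
  ps <- deconvolve(masses, monomer_mass = 200, calib = calib,
                   max_components = 4)
  expect_equal(nrow(ps$peaks), 1L)
  expect_equal(ps$peaks$n, 1L)
  expect_equal(ps$peaks$area_fraction, 1)
})

test_that("AIC selection uses N log(RSS/N) + 2p and breaks ties downward", {
  expect_equal(select_components(c(`1` = 10, `2` = 5, `3` = 7)), 2L)
  expect_equal(select_components(c(`1` = 5, `2` = 5 + 1e-12)), 1L)
  expect_equal(select_components(c(`2` = 3)), 2L)
  expect_error(select_components(numeric(0)))
})

test_that("AIC picks the true component count on well-separated mixtures", {
  calib <- default_calibration()
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    m <- c(rnorm(1400, 100, calib_sd(calib, 100)),
           rnorm(900, 400, calib_sd(calib, 400)))
    m <- m[m >= calib$mass_min]
    ps <- deconvolve(m, monomer_mass = 100, calib = calib,
                     max_components = 5)
    ps$k == 2L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("detection-limit events never contribute to fitted peaks", {
  calib <- default_calibration()
  set.seed(44)
  masses <- c(rnorm(3000, 150, 10), runif(500, 5, 39.9))
  ps <- deconvolve(masses, monomer_mass = 150, calib = calib,
                   max_components = 3)
  expect_equal(ps$n_events, sum(masses >= calib$mass_min &
                                  masses <= calib$mass_max))
  expect_true(all(ps$histogram$breaks >= calib$mass_min))
})

test_that("round trip: events from a known peak set are recovered", {
  calib <- default_calibration()
  mm <- 100
  truth <- data.frame(n = c(1L, 2L, 4L),
                      frac = c(0.5, 0.3, 0.2))
  set.seed(77)
  n_ev <- 5000
  cnt <- round(truth$frac * n_ev)
  masses <- unlist(Map(function(n, k) {
    rnorm(k, n * mm, calib_sd(calib, n * mm))
  }, truth$n, cnt))
  masses <- masses[masses >= calib$mass_min]
  ps <- deconvolve(masses, monomer_mass = mm, calib = calib,
                   max_components = 6)
  got <- ps$peaks[order(ps$peaks$n), ]
  expect_equal(got$n, truth$n)
  for (i in seq_len(nrow(got))) {
    tol_center <- 0.5 * got$sd[i] / sqrt(got$area[i])
    expect_lt(abs(got$center[i] - truth$n[i] * mm), tol_center + 1)
    expect_lt(abs(got$area_fraction[i] - truth$frac[i]), 0.03)
  }
  expect_equal(sum(ps$peaks$area_fraction), 1, tolerance = 1e-9)
  expect_true(all(ps$peaks$sd <= calib_sd(calib, ps$peaks$center) + 1e-8))
})

test_that("counts convert to concentrations by protomer mass balance", {
  p <- ref_params()
  calib <- default_calibration()
  # single monomer peak at nominal 10 nM -> species concentration 10 nM
  set.seed(51)
  masses <- rnorm(2000, 60, calib_sd(calib, 60))
  ps <- deconvolve(masses[masses >= 40], monomer_mass = 60, calib = calib,
                   max_components = 3)
  tab <- counts_to_concentrations(ps, 10)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$conc, 10)

  # equal areas for n = 1 and n = 11 at nominal 12 nM -> 1 nM each
  set.seed(52)
  masses <- c(rnorm(3000, 50, calib_sd(calib, 50)),
              rnorm(3000, 550, calib_sd(calib, 550)))
  masses <- masses[masses >= 40]
  ps2 <- deconvolve(masses, monomer_mass = 50, calib = calib,
                    max_components = 12)
  tab2 <- counts_to_concentrations(ps2, 12)
  expect_setequal(tab2$n, c(1L, 11L))
  expect_equal(tab2$conc[tab2$n == 1], 1, tolerance = 0.15)
  expect_equal(tab2$conc[tab2$n == 11], 1, tolerance = 0.15)
  expect_equal(sum(tab2$n * tab2$conc), 12, tolerance = 1e-9)
})
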