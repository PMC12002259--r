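test_that("event simulation is reproducible under a fixed seed", {
  p <- ref_params()
  e1 <- simulate_events(p, 50, n_events = 500, seed = 9)
  e2 <- simulate_events(p, 50, n_events = 500, seed = 9)
  expect_identical(e1$masses, e2$masses)
  e3 <- simulate_events(p, 50, n_events = 500, seed = 10)
  expect_false(identical(e1$masses, e3$masses))
})

test_that("sub-detection discards match the Gaussian tail probability", {
  # pure monomers: all species mass at n = 1 via huge Kd and no rings
  mono <- assembly_params(kd = 1e9, kc0 = 0, n_opt = 10.8, sigma_ring = 0.79)
  calib <- default_calibration()
  mm <- 25.3
  n <- 20000L
  ev <- simulate_events(mono, 5, n_events = n, monomer_mass = mm,
                        calib = calib, seed = 4)
  p_keep <- pnorm(calib$mass_min, mean = mm, sd = calib_sd(calib, mm),
                  lower.tail = FALSE)
  se <- sqrt(p_keep * (1 - p_keep) / n)
  expect_equal(length(ev$masses) / n, p_keep, tolerance = 4 * se / p_keep)
  expect_equal(ev$meta$n_drawn - ev$meta$n_discarded, length(ev$masses))
  expect_true(all(ev$masses >= calib$mass_min))
})

test_that("species draw frequencies converge to species-concentration fractions", {
  p <- ref_params()
  d <- equilibrium_distribution(100, p)
  sp <- d$open + d$ring
  frac <- sp / sum(sp)
  # noise-free sampling check: use a calibration with negligible noise and
  # no detection floor so each event's size is exactly recoverable
  calib0 <- sd_calibration(1e-6, 1e-4, mass_min = 0.1, mass_max = 1e5)
  ev <- simulate_events(p, 100, n_events = 1e5, monomer_mass = 48.4,
                        calib = calib0, seed = 12)
  sizes <- round(ev$masses / 48.4)
  obs <- tabulate(sizes, nbins = p$n_max)
  keep <- frac > 1e-5
  chi <- chisq.test(obs[keep], p = frac[keep] / sum(frac[keep]))
  expect_gt(chi$p.value, 0.001)
})

test_that("simulated titrations land the dominant ring peak near the undecamer mass", {
  p <- ref_params()
  # with a 25.3 kDa protomer the dominant ring is the undecamer at
  # 11 x 25.3 = 278.3 kDa
  ev <- simulate_events(p, 200, n_events = 5000, monomer_mass = 25.3,
                        seed = 21)
  h <- hist(ev$masses, breaks = seq(0, max(ev$masses) + 10, by = 10),
            plot = FALSE)
  expect_equal(h$mids[which.max(h$counts)], 278.3, tolerance = 0.1)
})

test_that("binding-curve and annealing generators evaluate their models exactly at zero noise", {
  b <- simulate_binding_curve(100, 3, c(50, 100, 200), noise_sd = 0)
  expect_equal(b$fraction_bound[2], 0.5)          # half-saturation at K
  expect_equal(b$fraction_bound[3], 8 / 9)        # 200^3/(100^3+200^3)
  expect_equal(b$fraction_bound[1], 1 / 9)

  a <- simulate_annealing(2, 1, times = c(0, 1))
  expect_equal(a$product_fraction[1], 0)
  expect_equal(a$product_fraction[2], 1 - exp(-2))
  flat <- simulate_annealing(0, 1, times = c(0, 1, 5))
  expect_true(all(flat$product_fraction == 0))

  n1 <- simulate_binding_curve(100, 3, c(50, 100), noise_sd = 0.05, seed = 5)
  n2 <- simulate_binding_curve(100, 3, c(50, 100), noise_sd = 0.05, seed = 5)
  expect_identical(n1, n2)
})
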