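test_that("ring-closure constant follows the Gaussian bending-energy law", {
  p <- ref_params()
  # at the optimal size the exponent vanishes
  expect_identical(ring_closure_constant(p$n_opt, p), p$kc0)
  expect_identical(ring_bending_energy(p$n_opt, p), 0)
  # direct evaluation away from the optimum
  expect_equal(ring_closure_constant(11, p),
               1.9e6 * exp(-0.5 * (0.2 / 0.79)^2), tolerance = 1e-12)
  # small rings are utterly negligible
  expect_lt(ring_closure_constant(3, p) / p$kc0, 1e-14)
  # symmetry about the optimum
  for (delta in c(0.3, 1, 2.5)) {
    expect_equal(ring_closure_constant(p$n_opt + delta, p),
                 ring_closure_constant(p$n_opt - delta, p))
  }
  expect_error(ring_closure_constant(NaN, p))
  expect_error(ring_closure_constant(0.5, p))
})

test_that("free-monomer solver inverts the mass balance", {
  p <- ref_params()
  expect_identical(solve_free_monomer(0, p), 0)
  expect_error(solve_free_monomer(-1, p))

  # pure isodesmic closed form: c_total = Kd x/(1-x)^2 with x = c1/Kd
  iso <- assembly_params(kd = 14, kc0 = 0, n_opt = 10.8, sigma_ring = 0.79,
                         n_max = 2000)
  expect_equal(solve_free_monomer(28, iso), 7, tolerance = 1e-9)
  for (x in c(0.1, 0.5, 0.9)) {
    ct <- 14 * x / (1 - x)^2
    expect_equal(solve_free_monomer(ct, iso) / 14, x, tolerance = 1e-6)
  }

  # brute-force grid-search oracle at several concentrations
  for (ct in c(0.5, 2, 10, 50, 200)) {
    expect_equal(solve_free_monomer(ct, p), grid_free_monomer(ct, p),
                 tolerance = 1e-6)
  }
})

test_that("equilibrium distributions conserve protomer mass and respect cutoffs", {
  p <- ref_params()
  d0 <- equilibrium_distribution(0, p)
  expect_true(all(d0$open == 0) && all(d0$ring == 0))

  for (ct in c(0.1, 1, 2, 10, 50, 100, 200, 1000)) {
    d <- equilibrium_distribution(ct, p)
    expect_true(all(d$open >= 0) && all(d$ring >= 0))
    expect_equal(sum(d$n * (d$open + d$ring)), ct, tolerance = 1e-9)
    expect_true(all(d$ring[d$n < p$n_ring_min] == 0))
  }
})

test_that("free monomer and ring pool are nondecreasing in total concentration", {
  p <- ref_params()
  cts <- c(0.1, 0.5, 1, 2, 5, 10, 25, 50, 100, 200)
  c1 <- solve_free_monomer(cts, p)
  expect_true(all(diff(c1) > 0))
  rings <- vapply(cts, function(ct) {
    pool_summary(equilibrium_distribution(ct, p))$ring_pool
  }, numeric(1))
  expect_true(all(diff(rings) >= 0))
})

test_that("pool summaries sum the configured windows and flag empty ring pools", {
  p <- ref_params()
  # hand-built species table: 1-mer 2 nM, 3-mer 1 nM, 10-ring 0.5 nM
  d <- equilibrium_distribution(10, p)
  d$open[] <- 0; d$ring[] <- 0
  d$open[1] <- 2; d$open[3] <- 1; d$ring[10] <- 0.5
  ps <- pool_summary(d)
  expect_equal(ps$short_pool, 3)
  expect_equal(ps$ring_pool, 0.5)
  expect_equal(ps$ratio, 6)

  d$ring[10] <- 0
  ps0 <- pool_summary(d)
  expect_identical(ps0$ratio, NA_real_)
  expect_equal(ps0$short_pool, 3)
})

test_that("above the critical concentration the short pool plateaus while rings grow linearly", {
  p <- ref_params()
  cts <- seq(10, 200, by = 10)
  pools <- pool_curve(cts, p)
  # reservoir: short pool varies by less than a factor 2 over 10-200 nM
  expect_lt(max(pools$short_pool) / min(pools$short_pool), 2)
  # ring pool approximately linear with slope ~ 1/n_opt
  slope <- coef(lm(ring_pool ~ c_total, data = pools))[["c_total"]]
  expect_equal(slope, 1 / p$n_opt, tolerance = 0.15)
})

test_that("critical concentration from maximum curvature is grid-stable", {
  p <- ref_params()
  cc <- critical_concentration(p)
  cc_fine <- critical_concentration(
    p, c_grid = exp(seq(log(0.1), log(50), length.out = 800)))
  expect_equal(as.numeric(cc_fine), as.numeric(cc), tolerance = 0.1)

  no_rings <- assembly_params(kd = 14, kc0 = 0, n_opt = 10.8,
                              sigma_ring = 0.79)
  expect_error(critical_concentration(no_rings), "no ring phase")
})
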