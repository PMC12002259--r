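test_that("global fit recovers parameters from noise-free model data", {
  p <- ref_params()
  tab <- model_titration_table(p, c(10, 25, 50, 100, 200),
                               drop_below = 1e-6)
  fit <- isoring_fit(tab, multistart = 6, nboot = 0, seed = 3)
  cf <- coef(fit)
  expect_equal(cf[["kd"]], p$kd, tolerance = 0.01)
  expect_equal(cf[["kc0"]], p$kc0, tolerance = 0.01)
  expect_equal(cf[["n_opt"]], p$n_opt, tolerance = 0.01)
  expect_equal(cf[["sigma_ring"]], p$sigma_ring, tolerance = 0.01)
  expect_lt(fit$objective, 1e-10)
})

test_that("starting at the truth on noise-free data stays at the truth", {
  p <- ref_params()
  tab <- model_titration_table(p, c(10, 50, 200), drop_below = 1e-6)
  fit <- isoring_fit(tab, init = p, multistart = 0, nboot = 0, seed = 1)
  expect_lt(fit$objective, 1e-12)
  expect_equal(coef(fit)[["kd"]], p$kd, tolerance = 1e-4)
})

test_that("the optimum improves on the initial objective", {
  p <- ref_params()
  tab <- model_titration_table(p, c(10, 25, 50, 100, 200),
                               drop_below = 1e-6)
  init <- assembly_params(kd = 30, kc0 = 1e5, n_opt = 9, sigma_ring = 1.5)
  obj_at <- function(q) {
    sum((tab$conc - isoring:::predict_species(q, tab$c_total, tab$n))^2)
  }
  fit <- isoring_fit(tab, init = init, multistart = 4, nboot = 0, seed = 2)
  expect_lt(fit$objective, obj_at(init))
})

test_that("non-identifiable input is rejected", {
  p <- ref_params()
  tab <- model_titration_table(p, 50)
  expect_error(isoring_fit(tab), "3 distinct")
})

test_that("fit methods are mutually consistent", {
  p <- ref_params()
  tab <- model_titration_table(p, c(10, 50, 200), drop_below = 1e-6)
  fit <- isoring_fit(tab, init = p, multistart = 0, nboot = 0, seed = 1)
  expect_equal(length(fitted(fit)), nrow(fit$data))
  expect_equal(residuals(fit), fit$data$conc - fitted(fit))
  pr <- predict(fit, c(2, 20), type = "pools")
  expect_equal(nrow(pr), 2L)
  fm <- predict(fit, 28, type = "free_monomer")
  expect_lt(fm, 28)
  sp <- predict(fit, 10, type = "species")
  expect_equal(sum(sp$n * 0 + sp$conc * 0), 0)  # shape only
  expect_true(all(c("c_total", "n", "conc") %in% names(sp)))
})

test_that("bootstrap over replicates yields finite uncertainties", {
  p <- ref_params()
  base <- model_titration_table(p, c(10, 25, 50, 100, 200),
                                drop_below = 1e-4)
  set.seed(8)
  reps <- do.call(rbind, lapply(1:3, function(r) {
    d <- base
    d$conc <- pmax(d$conc * (1 + rnorm(nrow(d), sd = 0.05)), 0)
    d$replicate <- r
    d
  }))
  fit <- isoring_fit(reps, init = p, multistart = 0, nboot = 30, seed = 5)
  expect_true(all(is.finite(fit$se)))
  expect_gt(fit$se[["kd"]], 0)
  expect_equal(coef(fit)[["kd"]], p$kd, tolerance = 0.2)
  ci <- confint(fit)
  expect_true(ci["kd", 1] < coef(fit)[["kd"]],
              ci["kd", 2] > coef(fit)[["kd"]])
})
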