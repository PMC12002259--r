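#' @export
coef.isoring_fit <- function(object, ...) {
  p <- object$params
  c(kd = p$kd, kc0 = p$kc0, n_opt = p$n_opt, sigma_ring = p$sigma_ring)
}

#' @export
vcov.isoring_fit <- function(object, ...) {
  if (!is.null(object$boot) && nrow(object$boot) >= 10L) {
    stats::cov(object$boot)
  } else {
    diag(object$se^2, nrow = 4,
         ncol = 4) -> V
    dimnames(V) <- list(names(object$se), names(object$se))
    V
  }
}

#' @export
confint.isoring_fit <- function(object, parm, level = 0.95, ...) {
  cf <- coef(object)
  if (missing(parm)) parm <- names(cf)
  a <- (1 - level) / 2
  if (!is.null(object$boot) && nrow(object$boot) >= 20L) {
    ci <- t(apply(object$boot[, parm, drop = FALSE], 2,
                  stats::quantile, probs = c(a, 1 - a)))
  } else {
    z <- stats::qnorm(1 - a)
    ci <- cbind(cf[parm] - z * object$se[parm], cf[parm] + z * object$se[parm])
    colnames(ci) <- paste0(format(100 * c(a, 1 - a), trim = TRUE), " %")
  }
  ci
}

#' @export
fitted.isoring_fit <- function(object, ...) {
  predict_species(object$params, object$data$c_total, object$data$n)
}

#' @export
residuals.isoring_fit <- function(object, type = c("response", "weighted"),
                                  ...) {
  type <- match.arg(type)
  r <- object$data$conc - fitted(object)
  if (type == "weighted") r <- sqrt(object$weights_used) * r
  r
}

#' Predictions from a fitted assembly model
#'
#' @param object An `"isoring_fit"`.
#' @param c_total Total protomer concentrations (nM) at which to predict.
#' @param type `"species"` returns the per-size observable species
#'   concentrations (open + ring, long data frame); `"pools"` returns the
#'   short-pool / ring-pool summary curve; `"distribution"` returns a list
#'   of full [equilibrium_distribution()] objects; `"free_monomer"` the
#'   free monomer concentration.
#' @param short_sizes,ring_sizes Pool windows for `type = "pools"`.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.isoring_fit <- function(object, c_total,
                                type = c("species", "pools", "distribution",
                                         "free_monomer"),
                                short_sizes = 1:4, ring_sizes = 8:12, ...) {
  type <- match.arg(type)
  p <- object$params
  switch(type,
    species = {
      grid <- expand.grid(n = seq_len(p$n_max), c_total = c_total)
      data.frame(c_total = grid$c_total, n = grid$n,
                 conc = predict_species(p, grid$c_total, grid$n))
    },
    pools = pool_curve(c_total, p, short_sizes, ring_sizes),
    distribution = lapply(c_total, equilibrium_distribution, params = p),
    free_monomer = solve_free_monomer(c_total, p)
  )
}

#' @export
print.isoring_fit <- function(x, ...) {
  cat("Isodesmic + ring-closure assembly model fit\n")
  cf <- coef(x)
  se <- x$se
  cat(sprintf("  K_d        = %.3g +/- %.2g nM\n", cf["kd"], se["kd"]))
  cat(sprintf("  K_c0       = %.3g +/- %.2g\n", cf["kc0"], se["kc0"]))
  cat(sprintf("  n_opt      = %.3g +/- %.2g protomers\n",
              cf["n_opt"], se["n_opt"]))
  cat(sprintf("  sigma_ring = %.3g +/- %.2g protomers\n",
              cf["sigma_ring"], se["sigma_ring"]))
  cat(sprintf("  ring-closure free energy: %.3g kBT\n",
              ring_closure_energy(cf["kc0"])))
  cat(sprintf("  weighted RSS = %.4g on %d observations%s\n",
              x$objective, nrow(x$data),
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' @export
summary.isoring_fit <- function(object, ...) {
  cf <- coef(object)
  tab <- cbind(Estimate = cf, `Std. Error` = object$se)
  structure(list(coefficients = tab, objective = object$objective,
                 nobs = nrow(object$data), converged = object$converged,
                 at_bounds = object$at_bounds,
                 nboot = if (is.null(object$boot)) 0L else nrow(object$boot),
                 dG_ring = ring_closure_energy(cf[["kc0"]]),
                 c_crit = tryCatch(
                   as.numeric(critical_concentration(object$params)),
                   error = function(e) NA_real_)),
            class = "summary.isoring_fit")
}

#' @export
print.summary.isoring_fit <- function(x, ...) {
  cat("Global fit of the isodesmic ring-closure assembly model\n\n")
  print(signif(x$coefficients, 3))
  cat(sprintf("\nRing-closure free energy: %.3g kBT\n", x$dG_ring))
  if (is.finite(x$c_crit)) {
    cat(sprintf("Critical concentration (max curvature): %.2g nM\n", x$c_crit))
  }
  cat(sprintf("Weighted RSS %.4g on %d observations; %d bootstrap resamples\n",
              x$objective, x$nobs, x$nboot))
  if (any(x$at_bounds)) {
    cat("Warning: parameters at bounds:",
        paste(names(x$at_bounds)[x$at_bounds], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot an assembly-model fit as pool curves with observed pools
#'
#' Draws the model's short-oligomer and ring pool concentrations versus
#' total protomer concentration (log-log), overlaying pools summed from
#' the fitted data (averaged over replicates).
#'
#' @param x An `"isoring_fit"`.
#' @param short_sizes,ring_sizes Pool windows.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the plotted model pool curve.
#' @export
plot.isoring_fit <- function(x, short_sizes = 1:4, ring_sizes = 8:12, ...) {
  dat <- x$data
  cts <- sort(unique(dat$c_total))
  obs_pool <- function(sizes) {
    vapply(cts, function(ct) {
      d <- dat[dat$c_total == ct & dat$n %in% sizes, ]
      if (nrow(d) == 0) return(0)
      sum(tapply(d$conc, d$n, mean))
    }, numeric(1))
  }
  grid <- exp(seq(log(min(cts) / 2), log(max(cts) * 1.5), length.out = 100))
  mod <- pool_curve(grid, x$params, short_sizes, ring_sizes)
  graphics::matplot(grid, cbind(mod$short_pool, mod$ring_pool), type = "l",
                    lty = 1, col = c("firebrick", "steelblue"), log = "xy",
                    xlab = "total protomer concentration (nM)",
                    ylab = "pool species concentration (nM)", ...)
  graphics::points(cts, obs_pool(short_sizes), col = "firebrick", pch = 16)
  graphics::points(cts, obs_pool(ring_sizes), col = "steelblue", pch = 17)
  graphics::legend("topleft", bty = "n",
                   legend = c("short pool (model)", "ring pool (model)",
                              "short pool (data)", "ring pool (data)"),
                   col = rep(c("firebrick", "steelblue"), 2),
                   lty = c(1, 1, NA, NA), pch = c(NA, NA, 16, 17))
  invisible(mod)
}

#' Simulate mass-photometry event lists from a fitted model
#'
#' Draws synthetic landing-event lists from the fitted equilibrium
#' distribution at the data's total concentrations (or at `c_total`),
#' using [simulate_events()].
#'
#' @param object An `"isoring_fit"`.
#' @param nsim Number of replicate event lists per concentration.
#' @param seed Integer seed.
#' @param c_total Concentrations to simulate at (default: those in the
#'   fitted data).
#' @param monomer_mass Protomer mass, kDa.
#' @param calib An `"sd_calibration"`; default [default_calibration()].
#' @param n_events Events drawn per reading before detection losses.
#' @param ... Unused.
#' @return A list of `"event_list"` objects.
#' @export
simulate.isoring_fit <- function(object, nsim = 1, seed = NULL,
                                 c_total = NULL, monomer_mass = 48.4,
                                 calib = default_calibration(),
                                 n_events = 2000L, ...) {
  if (is.null(c_total)) c_total <- sort(unique(object$data$c_total))
  if (is.null(seed)) seed <- object$seed
  sims <- list()
  k <- 0L
  for (ct in c_total) {
    for (r in seq_len(nsim)) {
      k <- k + 1L
      sims[[k]] <- simulate_events(object$params, ct, n_events = n_events,
                                   monomer_mass = monomer_mass, calib = calib,
                                   replicate = r, seed = seed + k)
    }
  }
  sims
}
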