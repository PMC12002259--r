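#' Empirical linear ring model with a critical concentration
#'
#' Above the onset of cyclization the ring species concentration grows
#' approximately linearly with the total protomer concentration,
#' \eqn{c_{ring} = (c_{protomer} - c_{crit}) / n_{avg}}: the slope is the
#' reciprocal of the average number of protomers per ring, and the
#' intercept encodes the critical concentration. This fits that line by
#' (optionally weighted) least squares and, when short-pool levels are
#' supplied, also reports their mean plateau, which condensation-type
#' assembly predicts to equal the critical concentration.
#'
#' @param c_total Total protomer concentrations, nM.
#' @param ring_pool Summed ring species concentrations at `c_total`, nM.
#' @param short_pool Optional summed monomer/short-oligomer levels, nM,
#'   whose mean is reported as the plateau.
#' @param weights Optional least-squares weights (e.g. inverse variances).
#' @return Object of class `"empirical_ring_fit"`: a list with `c_crit`,
#'   `n_avg`, their standard errors (`c_crit_se`, `n_avg_se` by the delta
#'   method from the line-fit covariance), `plateau_short`,
#'   `plateau_short_se`, a `negative_c_crit` flag, and the underlying
#'   [stats::lm] fit.
#' @examples
#' ct <- c(10, 25, 50, 100, 200)
#' fit <- fit_empirical_linear(ct, (ct - 5) / 10.6)
#' fit$c_crit  # 5
#' @export
fit_empirical_linear <- function(c_total, ring_pool, short_pool = NULL,
                                 weights = NULL) {
  stopifnot(is.numeric(c_total), is.numeric(ring_pool),
            length(c_total) == length(ring_pool))
  ok <- is.finite(c_total) & is.finite(ring_pool)
  if (sum(ring_pool[ok] > 0) < 3L) {
    stop("need at least 3 concentrations with a nonzero ring pool",
         call. = FALSE)
  }
  if (length(unique(c_total[ok])) < 2L) {
    stop("rank deficient: need at least two distinct total concentrations",
         call. = FALSE)
  }
  df <- data.frame(ct = c_total[ok], ring = ring_pool[ok])
  fit <- if (is.null(weights)) {
    stats::lm(ring ~ ct, data = df)
  } else {
    stats::lm(ring ~ ct, data = df, weights = weights[ok])
  }
  b <- stats::coef(fit)
  # suppress the "essentially perfect fit" note for noise-free input
  V <- suppressWarnings(stats::vcov(fit))
  slope <- unname(b["ct"])
  intercept <- unname(b["(Intercept)"])
  if (slope <= 0) {
    stop("ring pool does not increase with concentration; no linear ring phase",
         call. = FALSE)
  }
  n_avg <- 1 / slope
  c_crit <- -intercept / slope
  # delta method: n_avg = 1/b1, c_crit = -b0/b1
  g_n <- c(0, -1 / slope^2)
  g_c <- c(-1 / slope, intercept / slope^2)
  n_avg_se <- sqrt(drop(t(g_n) %*% V %*% g_n))
  c_crit_se <- sqrt(drop(t(g_c) %*% V %*% g_c))
  neg <- c_crit < 0
  if (neg) warning("fitted critical concentration is negative")
  plateau <- plateau_se <- NA_real_
  if (!is.null(short_pool)) {
    sp <- short_pool[is.finite(short_pool)]
    plateau <- mean(sp)
    plateau_se <- stats::sd(sp) / sqrt(length(sp))
  }
  structure(
    list(c_crit = c_crit, c_crit_se = c_crit_se,
         n_avg = n_avg, n_avg_se = n_avg_se,
         plateau_short = plateau, plateau_short_se = plateau_se,
         negative_c_crit = neg, lm = fit),
    class = "empirical_ring_fit"
  )
}

#' @export
print.empirical_ring_fit <- function(x, ...) {
  cat("Empirical ring model: c_ring = (c_protomer - c_crit) / n_avg\n")
  cat(sprintf("  c_crit : %.3g +/- %.2g nM%s\n", x$c_crit, x$c_crit_se,
              if (x$negative_c_crit) "  (negative!)" else ""))
  cat(sprintf("  n_avg  : %.3g +/- %.2g protomers per ring\n",
              x$n_avg, x$n_avg_se))
  if (is.finite(x$plateau_short)) {
    cat(sprintf("  short-pool plateau: %.3g +/- %.2g nM (expected ~ c_crit)\n",
                x$plateau_short, x$plateau_short_se))
  }
  invisible(x)
}

#' Predicted ring concentration under the empirical linear model
#'
#' @param object An `"empirical_ring_fit"`.
#' @param c_total Total protomer concentrations, nM.
#' @param ... Unused.
#' @return Predicted ring species concentrations, nM (floored at zero
#'   below the critical concentration).
#' @export
predict.empirical_ring_fit <- function(object, c_total, ...) {
  pmax((c_total - object$c_crit) / object$n_avg, 0)
}
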