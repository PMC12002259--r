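#' Weighted Hill fit of a cooperative binding curve
#'
#' Fits the Hill equation \eqn{\theta(c) = c^H/(K^H + c^H)} to measured
#' bound fractions by nonlinear least squares weighted with the supplied
#' per-point errors (weights `1/se^2`), as is standard for gel-shift
#' quantifications with error bars.
#'
#' @param conc Protein concentrations, nM (>= 4 values spanning the
#'   transition).
#' @param fraction_bound Bound fractions in \[0, 1\].
#' @param se Per-point standard errors (> 0); default equal weights.
#' @param fix_hill Optional: fix H at this value and fit only K.
#' @return Object of class `"hill_fit"`: list with `kd_app`, `hill`,
#'   their standard errors, `wrss` (weighted residual sum of squares)
#'   and the observed data. Methods: `print`, `coef`, `predict`.
#' @examples
#' tab <- simulate_binding_curve(100, 3, c(25, 50, 100, 200, 400),
#'                               noise_sd = 0)
#' hill_fit(tab$conc, tab$fraction_bound)
#' @export
hill_fit <- function(conc, fraction_bound, se = NULL, fix_hill = NULL) {
  stopifnot(length(conc) == length(fraction_bound), length(conc) >= 4L)
  if (is.null(se)) se <- rep(1, length(conc))
  stopifnot(all(se > 0))
  if (diff(range(fraction_bound)) < 0.05) {
    stop("no binding transition in the data; Hill parameters not identifiable",
         call. = FALSE)
  }
  w <- 1 / se^2
  k0 <- stats::approx(fraction_bound, conc, xout = 0.5, ties = mean)$y
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(conc)
  free_h <- is.null(fix_hill)
  resid_fun <- function(theta) {
    K <- exp(theta[1])
    H <- if (free_h) exp(theta[2]) else fix_hill
    sqrt(w) * (fraction_bound - conc^H / (K^H + conc^H))
  }
  par0 <- if (free_h) c(log(k0), log(1.5)) else log(k0)
  res <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  K <- exp(res$par[1])
  H <- if (free_h) exp(res$par[2]) else fix_hill
  npar <- length(res$par)
  s2 <- res$deviance / max(length(conc) - npar, 1)
  V <- try(s2 * solve(res$hessian), silent = TRUE)
  se_log <- if (inherits(V, "try-error")) rep(NA_real_, npar) else
    sqrt(pmax(diag(V), 0))
  structure(
    list(kd_app = K, hill = H,
         kd_app_se = K * se_log[1],
         hill_se = if (free_h) H * se_log[2] else NA_real_,
         wrss = res$deviance,
         data = data.frame(conc = conc, fraction_bound = fraction_bound,
                           se = se)),
    class = "hill_fit"
  )
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(kd_app = object$kd_app, hill = object$hill)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill fit: theta(c) = c^H / (K^H + c^H)\n")
  cat(sprintf("  K_d,app = %.3g +/- %.2g nM\n", x$kd_app, x$kd_app_se))
  cat(sprintf("  H       = %.3g +/- %.2g\n", x$hill, x$hill_se))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, conc, ...) {
  conc^object$hill / (object$kd_app^object$hill + conc^object$hill)
}

#' Single-exponential fit of an annealing time course
#'
#' Fits \eqn{P(t) = A(1 - e^{-kt})} to product fractions versus time.
#' When a control rate (protein-free hybridization) is supplied, the rate
#' enhancement `k / control_rate` is reported.
#'
#' @param time Time points, minutes (>= 3).
#' @param product_fraction Product fractions.
#' @param control_rate Optional protein-free rate, per minute.
#' @return Object of class `"annealing_fit"`: `rate` (min^-1),
#'   `rate_s` (s^-1), `amplitude`, `time_constant` (min), `rate_se`,
#'   `amplitude_se`, `enhancement` (or `NA`), `wrss`.
#' @examples
#' tab <- simulate_annealing(2, 1, c(1, 3, 8))
#' annealing_fit(tab$time, tab$product_fraction, control_rate = 1 / 15)
#' @export
annealing_fit <- function(time, product_fraction, control_rate = NULL) {
  stopifnot(length(time) == length(product_fraction), length(time) >= 3L)
  if (length(time) >= 4L) {
    o <- order(time)
    if (stats::cor(time[o], product_fraction[o]) < 0) {
      warning("product fraction decreases with time; fit may be meaningless")
    }
  }
  a0 <- max(product_fraction)
  if (a0 <= 0) a0 <- 0.5
  k0 <- 1 / max(stats::median(time), .Machine$double.eps)
  resid_fun <- function(theta) {
    A <- exp(theta[1]); k <- exp(theta[2])
    product_fraction - A * (1 - exp(-k * time))
  }
  res <- minpack.lm::nls.lm(par = c(log(a0), log(k0)), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  A <- exp(res$par[1]); k <- exp(res$par[2])
  s2 <- res$deviance / max(length(time) - 2, 1)
  V <- try(s2 * solve(res$hessian), silent = TRUE)
  se_log <- if (inherits(V, "try-error")) c(NA_real_, NA_real_) else
    sqrt(pmax(diag(V), 0))
  structure(
    list(rate = k, rate_s = k / 60, amplitude = A,
         time_constant = if (k > 0) 1 / k else Inf,
         rate_se = k * se_log[2], amplitude_se = A * se_log[1],
         enhancement = if (is.null(control_rate)) NA_real_ else
           k / control_rate,
         control_rate = control_rate %||% NA_real_,
         wrss = res$deviance,
         data = data.frame(time = time, product_fraction = product_fraction)),
    class = "annealing_fit"
  )
}

#' @export
coef.annealing_fit <- function(object, ...) {
  c(rate = object$rate, amplitude = object$amplitude)
}

#' @export
print.annealing_fit <- function(x, ...) {
  cat("Annealing kinetics: P(t) = A (1 - exp(-k t))\n")
  cat(sprintf("  k = %.3g +/- %.2g min^-1  (%.3g s^-1; time constant %.3g min)\n",
              x$rate, x$rate_se, x$rate_s, x$time_constant))
  cat(sprintf("  A = %.3g +/- %.2g\n", x$amplitude, x$amplitude_se))
  if (is.finite(x$enhancement)) {
    cat(sprintf("  enhancement over control: %.3g x\n", x$enhancement))
  }
  invisible(x)
}

#' @export
predict.annealing_fit <- function(object, time, ...) {
  object$amplitude * (1 - exp(-object$rate * time))
}

#' Dissociation off-rate from equilibrium constant and on-rate
#'
#' At equilibrium \eqn{k_{off} = K_d \cdot k_{on}}. Concentrations may be
#' given in M, mM, uM, nM or pM.
#'
#' @param kd Dissociation constant (>= 0).
#' @param k_on Association rate constant, per molar per second; the
#'   diffusion-limited default is 1e8.
#' @param unit Unit of `kd` (default `"nM"`).
#' @return Off-rate, per second.
#' @examples
#' off_rate(100, 1e8)        # 10 s^-1
#' off_rate(20, 1e8, "pM")   # 0.002 s^-1
#' @export
off_rate <- function(kd, k_on = 1e8, unit = "nM") {
  stopifnot(is.numeric(kd), all(kd >= 0), k_on > 0)
  conc_to_molar(kd, unit) * k_on
}

#' Per-protomer scaling of a dissociation constant
#'
#' For cooperative single-strand-annealing proteins each additional
#' protomer in the DNA-bound complex lowers the complex dissociation
#' constant by roughly a constant factor f (about 0.34 for the Red-beta
#' homologue): \eqn{K_d(n_{ref} + \Delta n) = K_{d,ref} f^{\Delta n}}.
#'
#' @param kd_ref Reference dissociation constant (any unit; the result is
#'   in the same unit).
#' @param delta_n Number of additional protomers (>= 0, integer).
#' @param f Per-protomer scaling factor in (0, 1\].
#' @return Scaled dissociation constant, same unit as `kd_ref`.
#' @examples
#' scaled_kd(100, 8)              # ~ 2e-2 nM, i.e. ~ 20 pM
#' @export
scaled_kd <- function(kd_ref, delta_n, f = 0.34) {
  stopifnot(kd_ref >= 0, delta_n >= 0, delta_n == round(delta_n))
  if (!(f > 0 && f <= 1)) {
    stop("scaling factor f must be in (0, 1]", call. = FALSE)
  }
  kd_ref * f^delta_n
}

#' Ring-closure free-energy gain
#'
#' The free-energy gain of forming the extra intramolecular bond at the
#' optimal ring size, \eqn{\Delta G_{ring} = k_BT \ln K_c^\circ},
#' returned in units of \eqn{k_BT}.
#'
#' @param kc0 Ring-closure equilibrium constant at the optimum (> 0).
#' @return Free energy in k_BT.
#' @examples
#' ring_closure_energy(1.9e6)  # about 14.5 kBT
#' @export
ring_closure_energy <- function(kc0) {
  stopifnot(is.numeric(kc0))
  if (any(kc0 <= 0)) stop("kc0 must be > 0", call. = FALSE)
  log(kc0)
}
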