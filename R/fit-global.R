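#' Global fit of the isodesmic ring-closure model to an oligomer titration
#'
#' Fits the four thermodynamic parameters of the assembly model — the
#' isodesmic dissociation constant `kd`, the ring-closure amplitude `kc0`,
#' the optimal ring size `n_opt` and its SD `sigma_ring` — jointly to
#' per-oligomer species concentrations measured at several total protomer
#' concentrations, by weighted nonlinear least squares. Because an
#' n-mer's mass does not distinguish an open chain from a closed ring,
#' the model prediction for the observed species concentration at size n
#' is the sum of the open-chain and ring species of that size.
#'
#' Optimization uses Levenberg-Marquardt with box bounds on a transformed
#' scale (log for `kd`, `kc0`, `sigma_ring`), restarted from `multistart`
#' random initial points (plus `init` if given); the best optimum is kept.
#' Uncertainties are estimated by a nonparametric bootstrap over replicate
#' readings (case resampling of replicates within each concentration),
#' refitting from the point estimate.
#'
#' @param data Data frame of titration observations with columns
#'   `c_total` (nM), `n` (oligomer size), `conc` (species concentration,
#'   nM), and optionally `count` (event count behind the concentration)
#'   and `replicate`. The CSV column names `c_total_nM` / `conc_nM` are
#'   also accepted.
#' @param init Optional [assembly_params()] used as one of the starting
#'   points (and supplying `n_max` / `n_ring_min`).
#' @param weights Weighting scheme. `"equal"` (default) uses unit
#'   weights: per-size concentrations obtained by histogram deconvolution
#'   carry allocation errors from overlapping peaks that are far larger
#'   than counting noise, so inverse-count weighting over-trusts
#'   low-count observations. `"poisson"` weights by `1/max(count, 1)`,
#'   appropriate when observations are genuinely count-limited (e.g.
#'   well-separated peaks).
#' @param n_max,n_ring_min Size cutoffs if `init` is not supplied.
#' @param multistart Number of random starting points (seeded).
#' @param nboot Bootstrap resamples for uncertainties (0 to skip;
#'   asymptotic errors from the final Jacobian are then reported).
#' @param seed Integer seed controlling multistart draws and bootstrap.
#' @param lower,upper Optional named numeric vectors overriding the
#'   default box bounds on `kd`, `kc0`, `n_opt`, `sigma_ring`.
#'
#' @return An object of class `"isoring_fit"` with components
#'   `params` (fitted [assembly_params()]), `se` (standard errors),
#'   `boot` (matrix of bootstrap parameter draws, if any), `objective`
#'   (weighted RSS at the optimum), `data`, `weights_used`, `converged`,
#'   `at_bounds` (logical flags per parameter), `seed`, and `settings`.
#'   Supports [coef()], [vcov()], [confint()], [predict()], [fitted()],
#'   [residuals()], [summary()], [plot()] and [simulate()].
#' @examples
#' tab <- model_titration_table(rad52_params(), c(10, 50, 200))
#' fit <- isoring_fit(tab, multistart = 2, nboot = 0, seed = 1)
#' coef(fit)
#' @export
isoring_fit <- function(data, init = NULL, weights = c("equal", "poisson"),
                        n_max = 25L, n_ring_min = 3L,
                        multistart = 10L, nboot = 200L, seed = 1L,
                        lower = NULL, upper = NULL) {
  weights <- match.arg(weights)
  data <- normalize_titration(data)
  if (length(unique(data$c_total)) < 3L) {
    stop("global fit needs at least 3 distinct total concentrations",
         call. = FALSE)
  }
  if (!is.null(init)) {
    init <- as_assembly_params(init)
    n_max <- init$n_max
    n_ring_min <- init$n_ring_min
  }
  w <- if (weights == "poisson") 1 / pmax(data$count, 1) else rep(1, nrow(data))

  # transformed parameter vector: (log kd, log kc0, n_opt, log sigma_ring)
  lb <- c(log_kd = log(0.1), log_kc0 = log(1), n_opt = max(n_ring_min, 4),
          log_sigma = log(0.05))
  ub <- c(log_kd = log(1e4), log_kc0 = log(1e12), n_opt = n_max - 1,
          log_sigma = log(5))
  if (!is.null(lower)) {
    lb[paste0("log_", names(lower))] <- log(lower)
    if ("n_opt" %in% names(lower)) lb["n_opt"] <- lower[["n_opt"]]
  }
  if (!is.null(upper)) {
    ub[paste0("log_", names(upper))] <- log(upper)
    if ("n_opt" %in% names(upper)) ub["n_opt"] <- upper[["n_opt"]]
  }

  resid_fun <- function(theta) {
    p <- theta_to_params(theta, n_max, n_ring_min)
    sqrt(w) * (data$conc - predict_species(p, data$c_total, data$n))
  }

  # always start from a data-driven guess (and `init` if given); random
  # multistarts guard against local optima of the joint objective
  starts <- list(params_to_theta(init_from_data(data, n_max, n_ring_min)))
  if (!is.null(init)) starts <- c(starts, list(params_to_theta(init)))
  starts <- c(starts, with_seed(seed, {
    lapply(seq_len(multistart), function(i) {
      stats::runif(4, min = lb, max = ub)
    })
  }))

  best <- NULL
  for (th0 in starts) {
    res <- try(minpack.lm::nls.lm(
      par = pmin(pmax(th0, lb), ub), lower = lb, upper = ub, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)

  theta_hat <- best$par
  params_hat <- theta_to_params(theta_hat, n_max, n_ring_min)
  at_bounds <- (abs(theta_hat - lb) < 1e-6) | (abs(theta_hat - ub) < 1e-6)
  names(at_bounds) <- c("kd", "kc0", "n_opt", "sigma_ring")
  if (any(at_bounds)) {
    warning("parameter(s) at bounds: ",
            paste(names(at_bounds)[at_bounds], collapse = ", "))
  }

  boot <- NULL
  if (nboot > 0L && !is.null(data$replicate)) {
    boot <- with_seed(seed + 1L, {
      boot_fit_replicates(data, w, theta_hat, lb, ub, n_max, n_ring_min, nboot)
    })
  }
  se <- if (!is.null(boot) && nrow(boot) >= 10L) {
    apply(boot, 2, stats::sd)
  } else {
    asymptotic_se(best, theta_hat, length(resid_fun(theta_hat)))
  }
  names(se) <- c("kd", "kc0", "n_opt", "sigma_ring")

  structure(
    list(params = params_hat, se = se, boot = boot,
         objective = best$deviance, data = data, weights_used = w,
         converged = best$info %in% 1:4, at_bounds = at_bounds,
         seed = seed,
         settings = list(weights = weights, multistart = multistart,
                         nboot = nboot, n_max = n_max,
                         n_ring_min = n_ring_min)),
    class = "isoring_fit"
  )
}

## Moment-style starting values read off the titration itself: Kd from the
## isodesmic ratio of monomer and dimer species concentrations, the
## optimal ring size from the ring-region mode, the ring-closure
## amplitude from the ring-to-predicted-open ratio at that size.
init_from_data <- function(data, n_max, n_ring_min) {
  kd_est <- 20
  cts <- unique(data$c_total)
  ratios <- unlist(lapply(cts, function(ct) {
    d <- data[data$c_total == ct, ]
    c1 <- mean(d$conc[d$n == 1]); c2 <- mean(d$conc[d$n == 2])
    if (length(c1) && length(c2) && is.finite(c1) && is.finite(c2) &&
        c2 > 0) c1^2 / c2 else NULL
  }))
  if (length(ratios)) kd_est <- stats::median(ratios)
  kd_est <- min(max(kd_est, 0.2), 5000)

  ring <- data[data$n >= max(6, n_ring_min), ]
  if (nrow(ring)) {
    avg <- tapply(ring$conc, ring$n, mean)
    n_opt_est <- as.numeric(names(avg)[which.max(avg)])
    wt <- avg / sum(avg)
    mu <- sum(as.numeric(names(avg)) * wt)
    sigma_est <- sqrt(max(sum((as.numeric(names(avg)) - mu)^2 * wt), 0.09))
  } else {
    n_opt_est <- 11; sigma_est <- 1
  }
  n_opt_est <- min(max(n_opt_est, max(n_ring_min, 4) + 0.5), n_max - 1.5)
  sigma_est <- min(max(sigma_est, 0.2), 3)

  kc0_est <- 1e6
  ct_big <- max(cts)
  d <- data[data$c_total == ct_big, ]
  c1 <- mean(d$conc[d$n == 1])
  cn <- mean(d$conc[d$n == round(n_opt_est)])
  if (is.finite(c1) && is.finite(cn) && c1 > 0 && cn > 0 && c1 < kd_est) {
    open_pred <- kd_est * (c1 / kd_est)^round(n_opt_est)
    if (open_pred > 0) kc0_est <- cn / open_pred
  }
  kc0_est <- min(max(kc0_est, 10), 1e10)

  assembly_params(kd = kd_est, kc0 = kc0_est, n_opt = n_opt_est,
                  sigma_ring = sigma_est, n_max = n_max,
                  n_ring_min = n_ring_min)
}

theta_to_params <- function(theta, n_max, n_ring_min) {
  assembly_params(kd = exp(theta[[1]]), kc0 = exp(theta[[2]]),
                  n_opt = theta[[3]], sigma_ring = exp(theta[[4]]),
                  n_max = n_max, n_ring_min = n_ring_min)
}

params_to_theta <- function(p) {
  c(log(p$kd), log(max(p$kc0, 1)), p$n_opt, log(p$sigma_ring))
}

## Model-predicted observable species concentration (open + ring) at the
## given sizes, for a vector of (c_total, n) observation pairs.
predict_species <- function(params, c_total, n) {
  uc <- unique(c_total)
  pred <- numeric(length(c_total))
  for (ct in uc) {
    d <- equilibrium_distribution(ct, params)
    tot <- d$open + d$ring
    idx <- c_total == ct
    pred[idx] <- ifelse(n[idx] >= 1 & n[idx] <= params$n_max,
                        tot[n[idx]], 0)
  }
  pred
}

boot_fit_replicates <- function(data, w, theta_hat, lb, ub,
                                n_max, n_ring_min, nboot) {
  key <- paste(data$c_total, data$replicate, sep = "|")
  levs <- unique(key)
  by_conc <- split(levs, sub("\\|.*$", "", levs))
  draws <- matrix(NA_real_, nrow = nboot, ncol = 4,
                  dimnames = list(NULL, c("kd", "kc0", "n_opt", "sigma_ring")))
  for (b in seq_len(nboot)) {
    pick <- unlist(lapply(by_conc, function(levs) {
      sample(levs, length(levs), replace = TRUE)
    }))
    idx <- unlist(lapply(pick, function(l) which(key == l)), use.names = FALSE)
    db <- data[idx, , drop = FALSE]
    wb <- w[idx]
    rf <- function(theta) {
      p <- theta_to_params(theta, n_max, n_ring_min)
      sqrt(wb) * (db$conc - predict_species(p, db$c_total, db$n))
    }
    res <- try(minpack.lm::nls.lm(
      par = theta_hat, lower = lb, upper = ub, fn = rf,
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (!inherits(res, "try-error")) {
      draws[b, ] <- c(exp(res$par[1]), exp(res$par[2]),
                      res$par[3], exp(res$par[4]))
    }
  }
  draws[stats::complete.cases(draws), , drop = FALSE]
}

asymptotic_se <- function(lmres, theta_hat, nobs) {
  p <- length(theta_hat)
  s2 <- lmres$deviance / max(nobs - p, 1)
  V <- try(s2 * solve(lmres$hessian), silent = TRUE)
  if (inherits(V, "try-error")) return(rep(NA_real_, p))
  se_theta <- sqrt(pmax(diag(V), 0))
  # delta method back to the natural scale for the log-parameterized entries
  nat <- c(exp(theta_hat[1]), exp(theta_hat[2]), 1, exp(theta_hat[4]))
  se_theta * abs(c(nat[1], nat[2], 1, nat[4]))
}

normalize_titration <- function(data) {
  data <- as.data.frame(data)
  nm <- names(data)
  map <- c(c_total_nM = "c_total", conc_nM = "conc")
  for (i in seq_along(map)) {
    if (names(map)[i] %in% nm && !(map[[i]] %in% nm)) {
      names(data)[names(data) == names(map)[i]] <- map[[i]]
    }
  }
  req <- c("c_total", "n", "conc")
  if (!all(req %in% names(data))) {
    stop("titration data needs columns c_total(_nM), n, conc(_nM)",
         call. = FALSE)
  }
  if (is.null(data$count)) data$count <- 1
  if (is.null(data$replicate)) data$replicate <- 1L
  stopifnot(all(data$c_total > 0), all(data$n >= 1), all(data$conc >= 0))
  data
}

#' Noise-free titration table from the assembly model
#'
#' Evaluates the model's observable species concentrations (open + ring)
#' on a grid of sizes at each total concentration — the ideal data a
#' perfect measurement would produce. Mainly used for self-consistency
#' tests and as a plotting overlay.
#'
#' @param params An [assembly_params()] object.
#' @param c_total Vector of total protomer concentrations, nM.
#' @param sizes Oligomer sizes to tabulate (default 1..`n_max`).
#' @param drop_below Species concentrations below this value (nM) are
#'   dropped from the table, mimicking undetectable species; default 0
#'   keeps everything.
#' @return Data frame with columns `c_total`, `n`, `conc`, `count` (= 1),
#'   `replicate` (= 1).
#' @export
model_titration_table <- function(params, c_total, sizes = NULL,
                                  drop_below = 0) {
  params <- as_assembly_params(params)
  if (is.null(sizes)) sizes <- seq_len(params$n_max)
  rows <- lapply(c_total, function(ct) {
    d <- equilibrium_distribution(ct, params)
    tot <- d$open + d$ring
    data.frame(c_total = ct, n = d$n[sizes], conc = tot[sizes],
               count = 1, replicate = 1L)
  })
  out <- do.call(rbind, rows)
  out[out$conc >= drop_below, , drop = FALSE]
}
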