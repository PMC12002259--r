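#' Multi-Gaussian deconvolution of a mass-photometry histogram
#'
#' Decomposes a calibrated landing-event mass histogram into Gaussian
#' components whose centers lie near integer multiples of the monomer
#' mass, as oligomer peaks of a self-assembling protein. For each
#' candidate component count k = 1..`max_components`, a k-component
#' mixture (components at multiples 1..k) is fitted to the binned counts
#' by bounded Levenberg-Marquardt least squares:
#' \itemize{
#'   \item centers start at `j * monomer_mass` and may move by at most
#'     `center_tol` monomer masses, keeping the oligomer assignment
#'     unambiguous;
#'   \item each SD is parameterized as a fraction (0, 1] of the
#'     calibration-line prediction at the component's current center, so
#'     the instrument-resolution upper bound holds exactly while narrower
#'     peaks (no stoichiometric spread) remain allowed;
#'   \item amplitudes (events per component, full-Gaussian area) are
#'     nonnegative; because the predicted bin counts integrate the full
#'     Gaussian over each bin, mass hidden below the detection floor is
#'     implicitly restored in the fitted area.
#' }
#' The component count is then chosen by the Akaike information
#' criterion ([select_components()]), peaks holding less than
#' `prune` of the total fitted area are excluded, area fractions are
#' renormalized, and each retained peak is assigned the protomer number
#' `round(center / monomer_mass)`; peaks beyond `n_max` protomers are
#' labelled as ring clusters and carry no protomer assignment.
#'
#' @param events An `"event_list"` from [simulate_events()] /
#'   [read_events()], or a bare numeric vector of event masses (kDa).
#' @param monomer_mass Protomer mass, kDa.
#' @param calib An `"sd_calibration"` providing the SD bound and the
#'   detection limits.
#' @param max_components Largest number of mixture components tried.
#' @param bin_width Histogram bin width, kDa.
#' @param prune Minimum retained area fraction (default 0.02).
#' @param center_tol Maximum center displacement from its integer
#'   multiple, in monomer-mass units. Real mass offsets of oligomer peaks
#'   are small (a fraction of a percent), so a tight bound stabilises the
#'   allocation of overlapping ring peaks; it must stay below 0.5 to keep
#'   the protomer assignment unambiguous.
#' @param n_max Largest protomer count treated as a single oligomer;
#'   heavier peaks are labelled clusters.
#' @param ring_n Protomer count of the dominant ring, used only to label
#'   cluster peaks as multiples of the ring mass.
#' @return An object of class `"peak_set"`: list with `peaks` (data frame
#'   `center`, `sd`, `area`, `area_fraction`, `n`, `cluster`, `label`),
#'   `k` (selected components), `aic` (per-k AIC table), `n_events`,
#'   `histogram`, `monomer_mass`, `calib`, `meta`.
#' @examples
#' ev <- simulate_events(rad52_params(), 100, n_events = 500,
#'                       monomer_mass = 48.4, seed = 7)
#' ps <- deconvolve(ev, monomer_mass = 48.4, max_components = 14)
#' ps
#' @export
deconvolve <- function(events, monomer_mass, calib = default_calibration(),
                       max_components = 16L, bin_width = 4, prune = 0.02,
                       center_tol = 0.2, n_max = 25L, ring_n = 11L) {
  masses <- if (inherits(events, "event_list")) events$masses else
    as.numeric(events)
  meta <- if (inherits(events, "event_list")) events$meta else NULL
  stopifnot(monomer_mass > 0, bin_width > 0)
  masses <- masses[is.finite(masses) &
                     masses >= calib$mass_min & masses <= calib$mass_max]
  if (length(masses) < 50L) {
    stop("too few events in the detection range (need >= 50)", call. = FALSE)
  }

  breaks <- seq(calib$mass_min,
                max(masses) + bin_width, by = bin_width)
  h <- graphics::hist(masses, breaks = breaks, plot = FALSE)
  counts <- h$counts
  lo <- utils::head(h$breaks, -1)
  hi <- utils::tail(h$breaks, -1)

  # candidate centers: integer multiples of the monomer mass up to the
  # histogram edge, ranked by how many events land nearest each multiple;
  # the k-component model uses the k best-populated candidates, so sparse
  # intermediate sizes need not consume components
  j_cap <- max(1L, ceiling(max(masses) / monomer_mass))
  nearest <- pmax(1L, pmin(j_cap, round(masses / monomer_mass)))
  occ <- tabulate(nearest, nbins = j_cap)
  ranking <- order(-occ, seq_len(j_cap))
  ranking <- ranking[occ[ranking] > 0 | seq_along(ranking) == 1L]
  k_cap <- min(as.integer(max_components), length(ranking))

  fits <- vector("list", k_cap)
  for (k in seq_len(k_cap)) {
    mult_k <- sort(ranking[seq_len(k)])
    fits[[k]] <- tryCatch(
      fit_mixture_k(counts, lo, hi, occ, mult_k, monomer_mass, calib,
                    center_tol),
      error = function(e) {
        warning(sprintf("mixture fit with k = %d failed: %s",
                        k, conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no mixture fit converged", call. = FALSE)
  aic_tab <- data.frame(
    k = which(ok),
    aic = vapply(fits[ok], `[[`, numeric(1), "aic"),
    rss = vapply(fits[ok], `[[`, numeric(1), "rss"))
  k_best <- select_components(stats::setNames(aic_tab$aic, aic_tab$k))
  best <- fits[[k_best]]

  pk <- best$peaks
  # prune sub-threshold peaks after model selection, then renormalize
  frac <- pk$area / sum(pk$area)
  keep <- frac >= prune
  if (!any(keep)) keep <- frac == max(frac)
  pk <- pk[keep, , drop = FALSE]
  pk$area_fraction <- pk$area / sum(pk$area)
  n_assigned <- round(pk$center / monomer_mass)
  pk$cluster <- n_assigned > n_max
  pk$n <- ifelse(pk$cluster, NA_integer_, as.integer(n_assigned))
  pk$label <- ifelse(pk$cluster,
                     paste0("cluster_",
                            round(pk$center / (ring_n * monomer_mass))),
                     paste0("n", n_assigned))
  rownames(pk) <- NULL

  structure(
    list(peaks = pk[, c("center", "sd", "area", "area_fraction", "n",
                        "cluster", "label")],
         k = k_best, aic = aic_tab, rss = best$rss,
         n_events = length(masses),
         histogram = list(breaks = h$breaks, counts = counts, mids = h$mids),
         monomer_mass = monomer_mass, calib = calib, meta = meta),
    class = "peak_set"
  )
}

## Bounded LM fit of a k-component Gaussian mixture to binned counts,
## with components at the supplied integer multiples of the monomer mass.
## theta = (mu_1..mu_k, s_1..s_k, a_1..a_k): centers, SD fractions of the
## calibration bound at the current center, and sqrt-amplitudes (so the
## nonnegativity bound is never active at an interior optimum).
fit_mixture_k <- function(counts, lo, hi, occ, multiples, monomer_mass,
                          calib, center_tol = 0.2) {
  k <- length(multiples)
  centers0 <- monomer_mass * multiples
  # initial amplitudes: events nearest each candidate multiple
  a0 <- occ[multiples] + 1
  theta0 <- c(centers0, rep(0.9, k), sqrt(a0))
  stopifnot(center_tol > 0, center_tol < 0.5)
  lower <- c(centers0 - center_tol * monomer_mass, rep(0.05, k), rep(0, k))
  upper <- c(centers0 + center_tol * monomer_mass, rep(1, k), rep(Inf, k))

  predict_bins <- function(theta) {
    mu <- theta[1:k]
    sds <- theta[(k + 1):(2 * k)] * calib_sd(calib, mu)
    a <- theta[(2 * k + 1):(3 * k)]^2
    pred <- numeric(length(counts))
    for (j in seq_len(k)) {
      pred <- pred + a[j] * (stats::pnorm(hi, mu[j], sds[j]) -
                               stats::pnorm(lo, mu[j], sds[j]))
    }
    pred
  }

  res <- minpack.lm::nls.lm(
    par = theta0, lower = lower, upper = upper,
    fn = function(theta) counts - predict_bins(theta),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  rss <- res$deviance
  nbin <- length(counts)
  p <- 3 * k
  aic <- nbin * log(rss / nbin) + 2 * p
  mu <- res$par[1:k]
  sds <- res$par[(k + 1):(2 * k)] * calib_sd(calib, mu)
  a <- res$par[(2 * k + 1):(3 * k)]^2
  list(
    peaks = data.frame(center = mu, sd = sds, area = a),
    rss = rss, aic = aic, converged = res$info %in% 1:4
  )
}

#' Choose the number of mixture components by AIC
#'
#' For least-squares fits the AIC is `N log(RSS/N) + 2p` with `p` free
#' parameters. Returns the component count with minimal AIC; ties (within
#' 1e-9) are broken toward the smaller count.
#'
#' @param aic Named numeric vector of AIC values; names are the component
#'   counts.
#' @return The selected component count (integer).
#' @export
select_components <- function(aic) {
  if (length(aic) == 0L) stop("no successful fits to select from",
                              call. = FALSE)
  ks <- as.integer(names(aic))
  if (any(is.na(ks))) ks <- seq_along(aic)
  o <- order(ks)
  ks <- ks[o]; aic <- aic[o]
  ks[which(aic <= min(aic) + 1e-9)][1]
}

#' Convert fitted peak areas to oligomer species concentrations
#'
#' Event counts are proportional to species (particle) concentrations
#' under equal per-particle landing probability. Species concentrations
#' are therefore `c_i = f_i * S` with `f_i` the retained (non-cluster)
#' area fractions and the scale `S` set by protomer mass balance,
#' `sum_i n_i c_i = nominal_total`.
#'
#' @param peaks A `"peak_set"` from [deconvolve()].
#' @param nominal_total Nominal total protomer concentration, nM.
#' @param replicate Replicate identifier carried into the output.
#' @return Titration-table rows: data frame with columns `c_total`, `n`,
#'   `conc` (nM), `count` (events behind the peak), `replicate`.
#' @examples
#' ev <- simulate_events(rad52_params(), 50, n_events = 500,
#'                       monomer_mass = 48.4, seed = 3)
#' ps <- deconvolve(ev, 48.4, max_components = 14)
#' counts_to_concentrations(ps, 50)
#' @export
counts_to_concentrations <- function(peaks, nominal_total,
                                     replicate = NULL) {
  stopifnot(inherits(peaks, "peak_set"), nominal_total > 0)
  pk <- peaks$peaks[!peaks$peaks$cluster, , drop = FALSE]
  if (nrow(pk) == 0L) {
    stop("all retained peaks are ring clusters; no protomer assignment",
         call. = FALSE)
  }
  if (is.null(replicate)) {
    replicate <- if (!is.null(peaks$meta$replicate)) peaks$meta$replicate else 1L
  }
  f <- pk$area / sum(pk$area)
  s <- nominal_total / sum(pk$n * f)
  data.frame(c_total = nominal_total, n = pk$n, conc = f * s,
             count = round(pk$area), replicate = replicate)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Mass-histogram deconvolution: %d events, %d components (AIC), %d retained peaks\n",
              x$n_events, x$k, nrow(x$peaks)))
  print.data.frame(cbind(
    format(x$peaks[, c("center", "sd")], digits = 4),
    area = round(x$peaks$area, 1),
    fraction = signif(x$peaks$area_fraction, 3),
    label = x$peaks$label), row.names = FALSE)
  invisible(x)
}

#' Plot a deconvolved mass histogram with its Gaussian components
#'
#' @param x A `"peak_set"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly `x`.
#' @export
plot.peak_set <- function(x, ...) {
  h <- x$histogram
  bw <- diff(h$breaks[1:2])
  graphics::plot(h$mids, h$counts, type = "h", lwd = 2, col = "grey60",
                 xlab = "mass (kDa)", ylab = sprintf("events / %g kDa", bw),
                 ...)
  grid <- seq(min(h$breaks), max(h$breaks), length.out = 600)
  env <- numeric(length(grid))
  for (i in seq_len(nrow(x$peaks))) {
    comp <- x$peaks$area[i] * bw *
      stats::dnorm(grid, x$peaks$center[i], x$peaks$sd[i])
    env <- env + comp
    graphics::lines(grid, comp, col = "steelblue")
  }
  graphics::lines(grid, env, col = "grey20", lwd = 2)
  invisible(x)
}
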