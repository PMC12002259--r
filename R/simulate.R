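#' Simulate a mass-photometry event list from the assembly model
#'
#' Draws single-molecule landing events from the equilibrium species
#' distribution at one total protomer concentration. Each event picks a
#' species with probability proportional to its species (particle)
#' concentration — equal landing probability per particle — and receives
#' a mass `n * monomer_mass` blurred by Gaussian measurement noise with
#' SD given by the calibration line at the true mass. Events falling
#' below the detection floor are discarded and not replaced, mimicking
#' real count loss; the number of discards is recorded in the metadata.
#' An optional contaminant fraction of ring clusters (particles at 2x and
#' 3x the dominant ring mass) can be injected to exercise peak pruning.
#'
#' @param params An [assembly_params()] object.
#' @param c_total Total protomer concentration, nM.
#' @param n_events Events drawn before detection losses.
#' @param monomer_mass Protomer mass, kDa.
#' @param calib An `"sd_calibration"` (noise law + detection limits).
#' @param cluster_fraction Fraction of drawn events that are ring-cluster
#'   contaminants (default 0).
#' @param replicate Replicate id stored in the metadata.
#' @param duration_s Acquisition duration stored in the metadata, s.
#' @param seed Integer seed; the same seed reproduces the list exactly.
#' @return An object of class `"event_list"`: list with `masses` (kDa)
#'   and `meta` (c_total, replicate, duration_s, n_drawn, n_discarded,
#'   monomer_mass, seed).
#' @examples
#' ev <- simulate_events(rad52_params(), 100, n_events = 1000,
#'                       monomer_mass = 48.4, seed = 1)
#' length(ev$masses)
#' @export
simulate_events <- function(params, c_total, n_events = 2000L,
                            monomer_mass = 48.4,
                            calib = default_calibration(),
                            cluster_fraction = 0, replicate = 1L,
                            duration_s = 60, seed = NULL) {
  params <- as_assembly_params(params)
  stopifnot(n_events > 0, monomer_mass > 0,
            cluster_fraction >= 0, cluster_fraction < 1)
  d <- equilibrium_distribution(c_total, params)
  sp_conc <- d$open + d$ring
  if (sum(sp_conc) <= 0) {
    warning("no species present; returning an empty event list")
    return(new_event_list(numeric(0), c_total, replicate, duration_s,
                          0L, 0L, monomer_mass, seed))
  }
  ring_mass <- round(params$n_opt) * monomer_mass
  with_seed(seed, {
    n_clu <- stats::rbinom(1, n_events, cluster_fraction)
    n_mono <- n_events - n_clu
    sizes <- sample(d$n, n_mono, replace = TRUE, prob = sp_conc)
    true_mass <- sizes * monomer_mass
    if (n_clu > 0) {
      m <- sample(2:3, n_clu, replace = TRUE)
      true_mass <- c(true_mass, m * ring_mass)
    }
    drawn <- stats::rnorm(length(true_mass), mean = true_mass,
                          sd = calib_sd(calib, true_mass))
    kept <- drawn[drawn >= calib$mass_min]
    new_event_list(kept, c_total, replicate, duration_s,
                   length(drawn), length(drawn) - length(kept),
                   monomer_mass, seed)
  })
}

new_event_list <- function(masses, c_total, replicate, duration_s,
                           n_drawn, n_discarded, monomer_mass, seed) {
  structure(
    list(masses = as.numeric(masses),
         meta = list(c_total = c_total, replicate = replicate,
                     duration_s = duration_s, n_drawn = n_drawn,
                     n_discarded = n_discarded,
                     monomer_mass = monomer_mass, seed = seed)),
    class = "event_list"
  )
}

#' @export
print.event_list <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Mass-photometry event list: %d events (%d drawn, %d below detection)\n",
              length(x$masses), m$n_drawn %||% NA, m$n_discarded %||% NA))
  cat(sprintf("  c_total %.4g nM, replicate %s, %g s reading\n",
              m$c_total %||% NA, format(m$replicate %||% NA),
              m$duration_s %||% NA))
  invisible(x)
}

#' Simulate a full mass-photometry titration
#'
#' One event list per (concentration, replicate) pair, with seeds derived
#' deterministically from `seed` so each reading is independently
#' reproducible.
#'
#' @inheritParams simulate_events
#' @param concentrations Total protomer concentrations, nM.
#' @param replicates Readings per concentration.
#' @param events_per_reading Events drawn per reading before losses.
#' @param seed Base seed.
#' @return List of `"event_list"` objects.
#' @export
simulate_titration <- function(params, concentrations = c(10, 25, 50, 100, 200),
                               replicates = 4L, events_per_reading = 2000L,
                               monomer_mass = 48.4,
                               calib = default_calibration(),
                               cluster_fraction = 0, seed = 1L) {
  out <- list()
  k <- 0L
  for (i in seq_along(concentrations)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      out[[k]] <- simulate_events(
        params, concentrations[i], n_events = events_per_reading,
        monomer_mass = monomer_mass, calib = calib,
        cluster_fraction = cluster_fraction, replicate = r,
        seed = (seed * 1000L + k) %% .Machine$integer.max)
    }
  }
  out
}

#' Simulate a cooperative (Hill) binding curve
#'
#' Fraction bound follows the Hill equation
#' \eqn{\theta(c) = c^H / (K^H + c^H)} with additive Gaussian noise,
#' clipped to the unit interval.
#'
#' @param kd_app Apparent dissociation constant K, nM.
#' @param hill Hill coefficient H.
#' @param conc Protein concentrations, nM.
#' @param noise_sd Gaussian noise SD (fraction units).
#' @param seed Integer seed.
#' @return Data frame with `conc`, `fraction_bound`, `se` (the noise SD,
#'   as the per-point uncertainty).
#' @examples
#' simulate_binding_curve(100, 3, c(50, 100, 200), noise_sd = 0)
#' @export
simulate_binding_curve <- function(kd_app, hill, conc, noise_sd = 0.05,
                                   seed = NULL) {
  stopifnot(kd_app > 0, hill > 0, all(conc >= 0), noise_sd >= 0)
  theta <- conc^hill / (kd_app^hill + conc^hill)
  with_seed(seed, {
    y <- theta + stats::rnorm(length(conc), sd = noise_sd)
    data.frame(conc = conc, fraction_bound = pmin(pmax(y, 0), 1),
               se = rep(max(noise_sd, 1e-6), length(conc)))
  })
}

#' Simulate a single-strand annealing time course
#'
#' Product formation follows a single exponential,
#' \eqn{P(t) = A (1 - e^{-kt})}, with additive Gaussian noise.
#'
#' @param k Annealing rate constant, per minute.
#' @param amplitude Final product fraction A.
#' @param times Time points, minutes.
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return Data frame with `time` (min) and `product_fraction`.
#' @examples
#' simulate_annealing(2, 1, c(1, 3, 8), noise_sd = 0)
#' @export
simulate_annealing <- function(k, amplitude = 1, times = c(1, 3, 8),
                               noise_sd = 0, seed = NULL) {
  stopifnot(k >= 0, all(times >= 0), noise_sd >= 0)
  p <- amplitude * (1 - exp(-k * times))
  with_seed(seed, {
    data.frame(time = times,
               product_fraction = p + stats::rnorm(length(times),
                                                   sd = noise_sd))
  })
}
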