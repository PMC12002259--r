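#' Size-dependent ring-closure equilibrium constant
#'
#' Evaluates \eqn{K_c(n) = K_c^\circ \exp[-E_b(n)/k_BT]} with the elastic
#' bending energy \eqn{E_b(n) = \tfrac12 ((n - n_o)/\sigma_{ring})^2} in
#' units of \eqn{k_BT}. `n` may be fractional; the Gaussian is symmetric
#' about the optimal ring size.
#'
#' @param n Oligomer size(s), protomer units; must be finite and >= 1.
#' @param params An [assembly_params()] object.
#' @return Numeric vector of equilibrium constants, same length as `n`.
#' @seealso [ring_bending_energy()] for the exponent itself.
#' @examples
#' ring_closure_constant(10.8, rad52_params())  # at the optimum: K_c0
#' @export
ring_closure_constant <- function(n, params) {
  params <- as_assembly_params(params)
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1)) {
    stop("'n' must be finite and >= 1", call. = FALSE)
  }
  params$kc0 * exp(-ring_bending_energy(n, params))
}

#' Elastic bending energy of a closed ring
#'
#' The Hookean bending-energy cost, in \eqn{k_BT} units, of closing a ring
#' of `n` protomers instead of the optimal `n_opt`:
#' \eqn{E_b = \tfrac12((n - n_o)/\sigma_{ring})^2}.
#'
#' @inheritParams ring_closure_constant
#' @return Energies in k_BT, same length as `n`.
#' @export
ring_bending_energy <- function(n, params) {
  params <- as_assembly_params(params)
  if (!is.numeric(n) || any(!is.finite(n))) {
    stop("'n' must be finite", call. = FALSE)
  }
  0.5 * ((n - params$n_opt) / params$sigma_ring)^2
}

## Species concentrations for a given free-monomer concentration c1:
## open chains follow the isodesmic law c_open(n) = K_d (c1/K_d)^n and the
## closed rings c_ring(n) = K_c(n) c_open(n) for n >= n_ring_min.
species_at_c1 <- function(c1, params) {
  ns <- seq_len(params$n_max)
  x <- c1 / params$kd
  # log-space with a cap keeps the root search finite even when a trial
  # c1 exceeds kd and x^n would overflow at large n_max
  open <- if (x > 0) exp(pmin(log(params$kd) + ns * log(x), 600)) else
    rep(0, params$n_max)
  kc <- ifelse(ns >= params$n_ring_min,
               params$kc0 * exp(-0.5 * ((ns - params$n_opt) / params$sigma_ring)^2),
               0)
  ring <- kc * open
  ring[kc == 0] <- 0
  list(n = ns, open = open, ring = ring)
}

protomer_total_at_c1 <- function(c1, params) {
  sp <- species_at_c1(c1, params)
  sum(sp$n * (sp$open + sp$ring))
}

#' Free-monomer concentration from total protomer concentration
#'
#' Inverts the protomer mass balance
#' \eqn{\sum_n n\,[c_{open}(n) + c_{ring}(n)] = c_{total}} for the free
#' monomer concentration \eqn{c_1}. The left side is strictly increasing
#' in \eqn{c_1}, so a bracketing root search on \eqn{[0, c_{total}]}
#' followed by Newton polishing converges to near machine precision;
#' mass balance is satisfied to better than 1e-9 relative.
#'
#' @param c_total Total protomer concentration(s), nM; must be >= 0.
#' @param params An [assembly_params()] object.
#' @return Free monomer concentration(s), nM (vectorized over `c_total`).
#' @examples
#' solve_free_monomer(28, assembly_params(14, 0, 10.8, 0.79, n_max = 2000))
#' @export
solve_free_monomer <- function(c_total, params) {
  params <- as_assembly_params(params)
  if (!is.numeric(c_total) || any(!is.finite(c_total)) || any(c_total < 0)) {
    stop("'c_total' must be finite and >= 0", call. = FALSE)
  }
  vapply(c_total, solve_free_monomer_one, numeric(1), params = params)
}

solve_free_monomer_one <- function(ct, params) {
  if (ct == 0) return(0)
  f <- function(c1) protomer_total_at_c1(c1, params) - ct
  # c1 = ct gives total >= ct (the n = 1 term alone equals ct), so the
  # root is bracketed in [0, ct].
  root <- stats::uniroot(f, lower = 0, upper = ct,
                         tol = .Machine$double.eps^0.75)$root
  # Newton polish: the derivative of the protomer total w.r.t. c1 is
  # sum n^2 (open + ring) / c1.
  for (i in 1:4) {
    sp <- species_at_c1(root, params)
    tot <- sum(sp$n * (sp$open + sp$ring))
    if (root <= 0) break
    dtot <- sum(sp$n^2 * (sp$open + sp$ring)) / root
    step <- (tot - ct) / dtot
    root <- root - step
    if (abs(step) < 1e-14 * root) break
  }
  max(root, 0)
}

#' Equilibrium oligomer distribution at one total protomer concentration
#'
#' Solves the assembly model for all species: open chains of sizes
#' 1..`n_max` and closed rings of sizes `n_ring_min`..`n_max`, at protomer
#' mass balance with the requested total concentration.
#'
#' @inheritParams solve_free_monomer
#' @param c_total Total protomer concentration, nM (scalar).
#' @return An object of class `"species_distribution"`: a data frame with
#'   columns `n`, `open` and `ring` (species concentrations in nM) and
#'   attributes `c_total`, `c_free_monomer` and `params`.
#' @examples
#' d <- equilibrium_distribution(2, rad52_params())
#' pool_summary(d)
#' @export
equilibrium_distribution <- function(c_total, params) {
  params <- as_assembly_params(params)
  stopifnot(length(c_total) == 1L)
  c1 <- solve_free_monomer(c_total, params)
  sp <- species_at_c1(c1, params)
  out <- data.frame(n = sp$n, open = sp$open, ring = sp$ring)
  structure(out,
            c_total = c_total,
            c_free_monomer = c1,
            params = params,
            class = c("species_distribution", "data.frame"))
}

#' @export
print.species_distribution <- function(x, ...) {
  cat(sprintf("Equilibrium species at c_total = %.4g nM (free monomer %.4g nM)\n",
              attr(x, "c_total"), attr(x, "c_free_monomer")))
  keep <- x$open > 1e-12 * max(x$open) | x$ring > 1e-12 * max(x$open)
  print.data.frame(format(x[keep, ], digits = 4), row.names = FALSE)
  invisible(x)
}

#' Monomer/short-oligomer and ring pool summaries
#'
#' Sums species concentrations over the short-oligomer window (open chains,
#' default sizes 1-4) and the ring window (closed rings, default sizes
#' 8-12), and reports their ratio. The ratio is `NA` when the ring pool is
#' zero (below the onset of cyclization), never infinite.
#'
#' @param dist A `"species_distribution"` from [equilibrium_distribution()].
#' @param short_sizes Integer sizes summed for the short pool (open chains).
#' @param ring_sizes Integer sizes summed for the ring pool (closed rings).
#' @return A list with `short_pool` (nM), `ring_pool` (nM) and `ratio`
#'   (dimensionless, `NA` if undefined).
#' @export
pool_summary <- function(dist, short_sizes = 1:4, ring_sizes = 8:12) {
  stopifnot(inherits(dist, "species_distribution"))
  short_pool <- sum(dist$open[dist$n %in% short_sizes])
  ring_pool <- sum(dist$ring[dist$n %in% ring_sizes])
  ratio <- if (ring_pool > 0) short_pool / ring_pool else NA_real_
  list(short_pool = short_pool, ring_pool = ring_pool, ratio = ratio)
}

#' Pool concentrations over a titration of total protomer concentration
#'
#' Convenience wrapper evaluating [pool_summary()] on the equilibrium
#' distribution at each requested total concentration.
#'
#' @param c_total Vector of total protomer concentrations, nM.
#' @inheritParams pool_summary
#' @param params An [assembly_params()] object.
#' @return Data frame with columns `c_total`, `short_pool`, `ring_pool`,
#'   `ratio`.
#' @export
pool_curve <- function(c_total, params, short_sizes = 1:4, ring_sizes = 8:12) {
  params <- as_assembly_params(params)
  rows <- lapply(c_total, function(ct) {
    p <- pool_summary(equilibrium_distribution(ct, params),
                      short_sizes = short_sizes, ring_sizes = ring_sizes)
    data.frame(c_total = ct, short_pool = p$short_pool,
               ring_pool = p$ring_pool, ratio = p$ratio)
  })
  do.call(rbind, rows)
}

#' Critical concentration for ring formation by maximum curvature
#'
#' Locates the onset of the ring phase as the total protomer concentration
#' at which the curvature (numerical second derivative) of the ring-pool
#' concentration versus total concentration is maximal. The second
#' derivative is taken by central differences on the supplied grid
#' (which may be non-uniform; a log-spaced default grid of 400 points
#' between 0.1 and 50 nM is used when none is given).
#'
#' @param params An [assembly_params()] object; must allow rings
#'   (`kc0 > 0`), otherwise there is no ring phase and an error is raised.
#' @param c_grid Optional increasing grid of total concentrations, nM.
#' @param ring_sizes Ring sizes summed for the ring pool.
#' @return The critical concentration in nM, with the grid and curvature
#'   attached as attributes `grid` and `curvature`.
#' @examples
#' critical_concentration(rad52_params())  # about 2 nM
#' @export
critical_concentration <- function(params, c_grid = NULL, ring_sizes = 8:12) {
  params <- as_assembly_params(params)
  if (params$kc0 <= 0) {
    stop("no ring phase: kc0 = 0 admits no closed rings", call. = FALSE)
  }
  if (is.null(c_grid)) {
    c_grid <- exp(seq(log(0.1), log(50), length.out = 400L))
  }
  stopifnot(length(c_grid) >= 5L, all(diff(c_grid) > 0))
  ring <- vapply(c_grid, function(ct) {
    d <- equilibrium_distribution(ct, params)
    sum(d$ring[d$n %in% ring_sizes])
  }, numeric(1))
  m <- length(c_grid)
  curv <- rep(NA_real_, m)
  h1 <- c_grid[2:(m - 1)] - c_grid[1:(m - 2)]
  h2 <- c_grid[3:m] - c_grid[2:(m - 1)]
  curv[2:(m - 1)] <- 2 * (h1 * ring[3:m] - (h1 + h2) * ring[2:(m - 1)] +
                            h2 * ring[1:(m - 2)]) / (h1 * h2 * (h1 + h2))
  i <- which.max(curv)
  structure(c_grid[i], grid = c_grid, curvature = curv)
}
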