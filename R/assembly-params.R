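#' Thermodynamic parameters of the isodesmic ring-closure assembly model
#'
#' Bundles the four thermodynamic parameters of the noncooperative
#' (isodesmic) self-assembly model with preferential cyclization, together
#' with the size cutoffs used when species tables are enumerated.
#'
#' The model assumes stepwise growth of open chains with a single
#' monomer-addition dissociation constant `kd` (isodesmic growth), and a
#' size-dependent ring-closure equilibrium
#' \deqn{K_c(n) = K_c^\circ \exp\left[-\tfrac12\left(\frac{n - n_o}{\sigma_{ring}}\right)^2\right],}
#' i.e. closing an open n-mer into a ring is most favourable at an optimal
#' protomer number `n_opt` and is penalised by a Hookean elastic bending
#' energy away from it, with softness `sigma_ring` (protomer units).
#'
#' @param kd Isodesmic dissociation constant for monomer addition, in nM.
#' @param kc0 Dimensionless ring-closure equilibrium constant at the
#'   optimal size (the amplitude of the Gaussian in \eqn{K_c(n)}).
#' @param n_opt Optimal ring protomer number (need not be an integer).
#' @param sigma_ring SD of the ring protomer number, in protomer units;
#'   its inverse square is proportional to the effective bending stiffness.
#' @param n_max Largest oligomer size tracked when species are enumerated.
#' @param n_ring_min Smallest oligomer size allowed to cyclize.
#'
#' @return An object of class `"assembly_params"`: a validated list with
#'   the six fields above.
#' @seealso [rad52_params()] for the reference full-length RAD52 values,
#'   [equilibrium_distribution()], [isoring_fit()].
#' @examples
#' p <- assembly_params(kd = 14, kc0 = 1.9e6, n_opt = 10.8, sigma_ring = 0.79)
#' p
#' @export
assembly_params <- function(kd, kc0, n_opt, sigma_ring,
                            n_max = 25L, n_ring_min = 3L) {
  stopifnot(
    is.numeric(kd), length(kd) == 1L, is.finite(kd), kd > 0,
    is.numeric(kc0), length(kc0) == 1L, is.finite(kc0), kc0 >= 0,
    is.numeric(n_opt), length(n_opt) == 1L, is.finite(n_opt),
    is.numeric(sigma_ring), length(sigma_ring) == 1L,
    is.finite(sigma_ring), sigma_ring > 0,
    is.numeric(n_max), length(n_max) == 1L, is.finite(n_max),
    is.numeric(n_ring_min), length(n_ring_min) == 1L, is.finite(n_ring_min)
  )
  n_max <- as.integer(n_max)
  n_ring_min <- as.integer(n_ring_min)
  if (!(3L <= n_ring_min && n_ring_min <= n_opt && n_opt <= n_max)) {
    stop("size cutoffs must satisfy 3 <= n_ring_min <= n_opt <= n_max",
         call. = FALSE)
  }
  structure(
    list(kd = kd, kc0 = kc0, n_opt = n_opt, sigma_ring = sigma_ring,
         n_max = n_max, n_ring_min = n_ring_min),
    class = "assembly_params"
  )
}

#' Reference assembly parameters for full-length human RAD52
#'
#' The fitted parameter set for full-length human RAD52 self-assembly:
#' K_d = 14 nM, K_c-zero = 1.9e6, optimal ring size 10.8 protomers with
#' SD 0.79. Used as defaults throughout the examples and simulators.
#'
#' @inheritParams assembly_params
#' @return An `"assembly_params"` object.
#' @export
rad52_params <- function(n_max = 25L, n_ring_min = 3L) {
  assembly_params(kd = 14, kc0 = 1.9e6, n_opt = 10.8, sigma_ring = 0.79,
                  n_max = n_max, n_ring_min = n_ring_min)
}

#' @export
print.assembly_params <- function(x, ...) {
  cat("Isodesmic + ring-closure assembly parameters\n")
  cat(sprintf("  K_d         : %.4g nM\n", x$kd))
  cat(sprintf("  K_c0        : %.4g\n", x$kc0))
  cat(sprintf("  n_opt       : %.4g protomers\n", x$n_opt))
  cat(sprintf("  sigma_ring  : %.4g protomers\n", x$sigma_ring))
  cat(sprintf("  sizes       : 1..%d (rings from %d)\n", x$n_max, x$n_ring_min))
  invisible(x)
}

as_assembly_params <- function(x) {
  if (inherits(x, "assembly_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(assembly_params(x$kd, x$kc0, x$n_opt, x$sigma_ring,
                           n_max = x$n_max %||% 25L,
                           n_ring_min = x$n_ring_min %||% 3L))
  }
  stop("cannot interpret 'params' as assembly parameters", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
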