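# Reference parameter set used across tests (full-length RAD52 fit values)
ref_params <- function(...) rad52_params(...)

# Brute-force oracle for the free-monomer mass balance: dense grid search
# over c1, refined once, entirely independent of the package solver.
grid_free_monomer <- function(c_total, params, n_grid = 4000L) {
  total_at <- function(c1) {
    ns <- seq_len(params$n_max)
    x <- c1 / params$kd
    open <- params$kd * x^ns
    kc <- ifelse(ns >= params$n_ring_min,
                 params$kc0 * exp(-0.5 * ((ns - params$n_opt) /
                                            params$sigma_ring)^2), 0)
    sum(ns * open * (1 + kc))
  }
  lo <- 0; hi <- c_total
  for (pass in 1:3) {
    grid <- seq(lo, hi, length.out = n_grid)
    tot <- vapply(grid, total_at, numeric(1))
    i <- which.min(abs(tot - c_total))
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, n_grid)]
  }
  (lo + hi) / 2
}
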