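## Evaluate an expression under a fixed RNG seed, restoring the caller's
## RNG state afterwards so library calls never disturb user randomness.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

## Concentration unit conversion to molar; accepts M, mM, uM, nM, pM.
conc_to_molar <- function(value, unit = "nM") {
  fac <- switch(unit,
                M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12,
                stop("unknown concentration unit: ", unit, call. = FALSE))
  value * fac
}

molar_to <- function(value, unit = "nM") {
  value / conc_to_molar(1, unit)
}
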