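#' Read and write mass-photometry event lists
#'
#' Event lists are stored as a one-column CSV (`mass_kDa`) with a sidecar
#' JSON (`<path>.json`) holding the acquisition metadata. Malformed rows
#' are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return `read_events()` returns an `"event_list"`; `write_events()`
#'   returns `path` invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character")
  if (!"mass_kDa" %in% names(raw)) {
    stop("event CSV must have a 'mass_kDa' column", call. = FALSE)
  }
  masses <- suppressWarnings(as.numeric(raw$mass_kDa))
  bad <- which(!is.finite(masses) | masses <= 0)
  if (length(bad)) {
    stop("non-numeric or non-positive mass in ", path, " at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  new_event_list(masses, meta$c_total %||% NA_real_,
                 meta$replicate %||% 1L, meta$duration_s %||% NA_real_,
                 meta$n_drawn %||% length(masses),
                 meta$n_discarded %||% 0L,
                 meta$monomer_mass %||% NA_real_, meta$seed %||% NULL)
}

#' @rdname read_events
#' @param events An `"event_list"`.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_list"))
  # full double precision so that write -> read round-trips exactly
  utils::write.csv(data.frame(mass_kDa = sprintf("%.17g", events$masses)),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(events$meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read and write oligomer titration tables
#'
#' Titration tables are CSVs with header columns `c_total_nM`, `n`,
#' `conc_nM`, `count`, `replicate`.
#'
#' @param path CSV file path.
#' @return `read_titration()` returns a data frame with the internal
#'   column names (`c_total`, `n`, `conc`, `count`, `replicate`).
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stop("titration file not found: ", path,
                               call. = FALSE)
  normalize_titration(utils::read.csv(path))
}

#' @rdname read_titration
#' @param table Titration data frame (internal or CSV column names).
#' @export
write_titration <- function(table, path) {
  tab <- normalize_titration(table)
  out <- data.frame(c_total_nM = tab$c_total, n = tab$n,
                    conc_nM = tab$conc, count = tab$count,
                    replicate = tab$replicate)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Every report embeds the package version, the seed and a hash of the
#' configuration so that outputs are traceable to their inputs.
#'
#' @param x A named list of report content (must be JSON-representable).
#' @param path Output path.
#' @param seed Seed to record.
#' @param config Configuration list to hash and embed.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, seed = NULL, config = NULL) {
  payload <- c(
    list(tool = "isoring",
         version = as.character(utils::packageVersion("isoring")),
         seed = seed,
         config_hash = config_hash(config)),
    x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash for traceability; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' Collects everything a reproducible simulate/analyze run needs. The
#' configuration round-trips losslessly through its JSON file form.
#'
#' @param out_dir Output directory.
#' @param monomer_mass Protomer mass, kDa.
#' @param concentrations Titration concentrations, nM.
#' @param replicates Readings per concentration.
#' @param events_per_reading Events drawn per reading.
#' @param params Generator / initial [assembly_params()] (as a list of
#'   the four thermodynamic values plus cutoffs).
#' @param calib `"sd_calibration"` values as a list.
#' @param short_sizes,ring_sizes Pool windows.
#' @param max_components Deconvolution component cap.
#' @param seed Integer seed.
#' @return A `"run_config"` list.
#' @export
run_config <- function(out_dir,
                       monomer_mass = 48.4,
                       concentrations = c(10, 25, 50, 100, 200),
                       replicates = 4L,
                       events_per_reading = 2000L,
                       params = unclass(rad52_params()),
                       calib = unclass(default_calibration())[
                         c("sd_slope", "sd_intercept", "mass_min", "mass_max")],
                       short_sizes = 1:4, ring_sizes = 8:12,
                       max_components = 14L, seed = 1L) {
  structure(list(out_dir = out_dir, monomer_mass = monomer_mass,
                 concentrations = concentrations, replicates = replicates,
                 events_per_reading = events_per_reading,
                 params = params, calib = calib,
                 short_sizes = short_sizes, ring_sizes = ring_sizes,
                 max_components = max_components, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @param config A `"run_config"`.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

config_params <- function(config) {
  p <- config$params
  assembly_params(p$kd, p$kc0, p$n_opt, p$sigma_ring,
                  n_max = p$n_max %||% 25L, n_ring_min = p$n_ring_min %||% 3L)
}

config_calib <- function(config) {
  cl <- config$calib
  sd_calibration(cl$sd_slope, cl$sd_intercept, cl$mass_min, cl$mass_max)
}

#' Generate a complete titration fixture dataset on disk
#'
#' Simulates the configured mass-photometry titration and writes one
#' event CSV (plus metadata sidecar) per reading, a `truth.json` with the
#' exact generator parameters, and the configuration itself.
#'
#' @param config A [run_config()].
#' @return Invisibly, the vector of event-file paths.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- config_params(config)
  calib <- config_calib(config)
  sims <- simulate_titration(
    params, concentrations = config$concentrations,
    replicates = config$replicates,
    events_per_reading = config$events_per_reading,
    monomer_mass = config$monomer_mass, calib = calib, seed = config$seed)
  paths <- character(length(sims))
  for (i in seq_along(sims)) {
    m <- sims[[i]]$meta
    paths[i] <- file.path(config$out_dir,
                          sprintf("events_c%g_r%d.csv", m$c_total,
                                  m$replicate))
    write_events(sims[[i]], paths[i])
  }
  write_config(config, file.path(config$out_dir, "config.json"))
  write_report(list(generator = unclass(config$params),
                    calib = config$calib,
                    files = basename(paths)),
               file.path(config$out_dir, "truth.json"),
               seed = config$seed, config = unclass(config))
  invisible(paths)
}

#' Analyze a directory of event lists end to end
#'
#' Chains the measurement pipeline over every `events_*.csv` in the
#' configured directory: histogram deconvolution, count-to-concentration
#' conversion, the global assembly-model fit, and pool summaries.
#' Reports are written next to the inputs (`peaks_*.csv`,
#' `titration.csv`, `fit.json`, `pools.csv`).
#'
#' @param config A [run_config()]; `out_dir` must contain the event CSVs.
#' @param nboot Bootstrap resamples for the global fit.
#' @param multistart Optimizer restarts for the global fit.
#' @return The fitted `"isoring_fit"`, invisibly.
#' @export
run_analyze <- function(config, nboot = 0L, multistart = 10L) {
  stopifnot(inherits(config, "run_config"))
  files <- list.files(config$out_dir, pattern = "^events_.*\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0L) {
    stop("no event files (events_*.csv) found in ", config$out_dir,
         call. = FALSE)
  }
  calib <- config_calib(config)
  tabs <- list()
  for (f in files) {
    ev <- read_events(f)
    ps <- deconvolve(ev, monomer_mass = config$monomer_mass, calib = calib,
                     max_components = config$max_components)
    peak_path <- file.path(config$out_dir,
                           sub("^events_", "peaks_", basename(f)))
    utils::write.csv(ps$peaks, peak_path, row.names = FALSE, quote = FALSE)
    tabs[[f]] <- counts_to_concentrations(ps, ev$meta$c_total,
                                          replicate = ev$meta$replicate)
  }
  titr <- do.call(rbind, tabs)
  rownames(titr) <- NULL
  write_titration(titr, file.path(config$out_dir, "titration.csv"))

  fit <- isoring_fit(titr, init = config_params(config),
                     multistart = multistart, nboot = nboot,
                     seed = config$seed)
  pools <- predict(fit, sort(unique(titr$c_total)), type = "pools",
                   short_sizes = config$short_sizes,
                   ring_sizes = config$ring_sizes)
  utils::write.csv(pools, file.path(config$out_dir, "pools.csv"),
                   row.names = FALSE, quote = FALSE)
  write_report(
    list(estimates = as.list(coef(fit)),
         se = as.list(fit$se),
         objective = fit$objective,
         converged = fit$converged,
         n_observations = nrow(titr),
         dG_ring_kBT = ring_closure_energy(coef(fit)[["kc0"]])),
    file.path(config$out_dir, "fit.json"),
    seed = config$seed, config = unclass(config))
  invisible(fit)
}
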