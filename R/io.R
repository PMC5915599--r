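## Serialization (tidy CSV + JSON sidecars), run records and the run_command
## entry point behind the command-line script.

.fmt <- function(x) sprintf("%.17g", x)  # lossless 64-bit round trip

#' Write a well-mixed trajectory as tidy CSV
#'
#' Columns `time_s`, `species`, `value`, `units`; one row per species per
#' output time; numeric values at full double precision.
#'
#' @param traj an `actin_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  sp <- traj$network$species
  df <- data.frame(
    time_s = .fmt(rep(traj$times, times = length(sp))),
    species = rep(sp, each = length(traj$times)),
    value = .fmt(unlist(traj$states[sp], use.names = FALSE)),
    units = rep(unname(traj$network$units[sp]), each = length(traj$times)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy trajectory CSV
#'
#' @param path file written by [write_trajectory_csv()].
#' @return A data.frame with numeric `time_s`, `value` and character
#'   `species`, `units`.
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(time_s = "numeric", species = "character",
                                value = "numeric", units = "character"))
  df
}

#' Write radial barbed-end profiles as CSV
#'
#' Long format: `time_s`, `r_um`, `barbed_ends_per_um2`.
#'
#' @param traj a `spatial_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(traj, path) {
  nt <- length(traj$times)
  nr <- traj$grid$n_cells
  df <- data.frame(
    time_s = .fmt(rep(traj$times, each = nr)),
    r_um = .fmt(rep(traj$grid$r, times = nt)),
    barbed_ends_per_um2 = .fmt(as.numeric(t(traj$fields$B))),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a radial profile CSV
#'
#' @param path file written by [write_profile_csv()].
#' @return A data.frame with numeric columns `time_s`, `r_um`,
#'   `barbed_ends_per_um2`.
#' @export
read_profile_csv <- function(path) {
  read.csv(path, colClasses = "numeric")
}

#' Write a pyrene-like curve as CSV
#'
#' @param curve a [simulate_bulk()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  df <- data.frame(time_s = .fmt(curve$times), f_poly = .fmt(curve$f_poly),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pyrene-like curve CSV
#'
#' @param path file written by [write_curve_csv()].
#' @return A list with `times` and `f_poly` (usable by [extract_lag()]).
#' @export
read_curve_csv <- function(path) {
  df <- read.csv(path, colClasses = "numeric")
  list(times = df$time_s, f_poly = df$f_poly)
}

.run_record <- function(config, seed, files, elapsed_s, extra = list()) {
  c(list(package = "actocap",
         version = as.character(packageVersion("actocap")),
         seed = seed,
         elapsed_s = elapsed_s,
         files = lapply(files, function(f)
           list(path = basename(f), md5 = unname(tools::md5sum(f)))),
         config = unclass(config)),
    extra)
}

#' Run a named pipeline and write its outputs
#'
#' The programmatic face of the command-line interface: executes one of the
#' package pipelines under a validated configuration and writes tidy CSV
#' outputs plus a `run_record.json` sidecar (configuration snapshot, seed,
#' package version, wall time, output manifest with checksums) sufficient to
#' reproduce the run.
#'
#' Subcommands: `wellmixed` (finite-reservoir trajectory + growth phases),
#' `spatial` (single-domain radial run + pattern call + flatness time),
#' `bulk` (pyrene-like curve + tangent lag), `ensemble` (synthetic vesicle
#' population + morphology fractions), `classify` (re-classify the profiles
#' in a CSV written by the spatial subcommand; pass it as `input`).
#'
#' @param subcommand one of `"wellmixed"`, `"spatial"`, `"bulk"`,
#'   `"ensemble"`, `"classify"`.
#' @param config a [load_config()] / [default_config()] configuration.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for every stochastic element of the run.
#' @param input input file for `classify` (a profile CSV).
#' @return The run record (a list), invisibly; files are written to
#'   `out_dir`.
#' @export
run_command <- function(subcommand = c("wellmixed", "spatial", "bulk",
                                       "ensemble", "classify"),
                        config = default_config(), out_dir, seed = 1L,
                        input = NULL) {
  subcommand <- match.arg(subcommand)
  .validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  rates <- config_rates(config)
  geometry <- config_geometry(config)
  conc <- config$concentrations
  files <- character()
  extra <- list(subcommand = subcommand)

  if (subcommand == "wellmixed") {
    net <- build_network(rates, geometry, "finite")
    init <- initial_pool(net, conc$actin_uM, conc$vca_uM, conc$arp_uM,
                         conc$cp_nM)
    tg <- seq(0, config$spatial$t_end_s, by = config$spatial$dt_out_s)
    tr <- integrate_wellmixed(net, init, tg, rtol = config$solver$rtol,
                              atol = config$solver$atol)
    f <- file.path(out_dir, "trajectory.csv")
    write_trajectory_csv(tr, f)
    files <- f
    ph <- detect_phases(tr)
    extra$phases <- unclass(ph)
    extra$max_barbed_end_density <- max(tr$states$B)
  } else if (subcommand == "spatial") {
    tr <- simulate_domain(conc$cp_nM, rates = rates, geometry = geometry,
                          sp = config_spatial(config),
                          grid = config_grid(config),
                          t_end = config$spatial$t_end_s,
                          dt_out = config$spatial$dt_out_s,
                          actin_uM = conc$actin_uM, vca_uM = conc$vca_uM,
                          arp_uM = conc$arp_uM)
    f <- file.path(out_dir, "profiles.csv")
    write_profile_csv(tr, f)
    files <- f
    pat <- classify_pattern(tr, config$ratchet$ratio_threshold,
                            mechanical_floor(config_ratchet(config)))
    extra$pattern <- as.character(pat)
    extra$pattern_max_ratio <- attr(pat, "max_ratio")
    extra$flatness_time_s <- tryCatch(flatness_time(tr),
                                      error = function(e) NA_real_)
  } else if (subcommand == "bulk") {
    pc <- simulate_bulk(rates, conc$actin_uM, conc$vca_uM, conc$arp_uM,
                        conc$profilin_uM, conc$cp_nM,
                        t_end = config$bulk$t_end_s, dt = config$bulk$dt_s,
                        noise_sd = config$bulk$noise_sd, seed = seed)
    f <- file.path(out_dir, "pyrene_curve.csv")
    write_curve_csv(pc, f)
    files <- f
    lr <- extract_lag(pc, config$bulk$smooth_window)
    extra$lag <- unclass(lr)
  } else if (subcommand == "ensemble") {
    en <- config$ensemble
    specs <- sample_vesicles(en$n, conc$cp_nM, en$radius_range_um,
                             en$cp_sdlog, master_seed = seed)
    surrogate <- if (en$mode == "surrogate") {
      build_surrogate(geometry = geometry, rates = rates,
                      sp = config_spatial(config, n_domains = 1),
                      grid = config_grid(config),
                      t_end = config$spatial$t_end_s,
                      dt_out = config$spatial$dt_out_s)
    }
    stats <- run_ensemble(specs, en$mode, surrogate,
                          en$cortex_seed_threshold, en$volume_cp_nM)
    f1 <- file.path(out_dir, "vesicles.csv")
    utils::write.csv(stats$specs, f1, row.names = FALSE, quote = FALSE)
    f2 <- file.path(out_dir, "morphology_summary.csv")
    utils::write.csv(summarize_morphology(stats), f2, row.names = FALSE,
                     quote = FALSE)
    files <- c(f1, f2)
    extra$n_failed <- stats$n_failed
  } else if (subcommand == "classify") {
    if (is.null(input))
      stop("run_command: classify needs 'input' (a profile CSV)", call. = FALSE)
    df <- read_profile_csv(input)
    rp <- config_ratchet(config)
    calls <- lapply(split(df, df$time_s), function(d) {
      prof <- structure(list(radii = d$r_um, density = d$barbed_ends_per_um2,
                             time = d$time_s[1]), class = "radial_profile")
      pat <- tryCatch(classify_profile(prof, config$ratchet$ratio_threshold),
                      error = function(e) NA_character_)
      mc <- tryCatch(classify_morphology(
        velocity_profile(prof, rp), config$ratchet$ratio_threshold,
        config$ratchet$speed_threshold_frac), error = function(e) NULL)
      list(time_s = d$time_s[1],
           pattern = if (is.na(pat[1])) NA else as.character(pat),
           rim_center_ratio = if (is.na(pat[1])) NA_real_
                              else attr(pat, "rim_center_ratio"),
           morphology = if (is.null(mc)) NA else mc$label,
           mean_speed_nm_s = if (is.null(mc)) NA_real_ else mc$mean_speed)
    })
    f <- file.path(out_dir, "classification.json")
    jsonlite::write_json(unname(calls), f, auto_unbox = TRUE, digits = NA,
                         na = "null")
    files <- f
  }

  record <- .run_record(config, seed, files,
                        proc.time()[["elapsed"]] - t0, extra)
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(record)
}
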