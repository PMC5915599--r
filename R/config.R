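## Run configuration: nested key groups with units, YAML loading, validation.

#' Default run configuration
#'
#' Nested list of every tunable of the package, grouped as `rates` (uM- and
#' um-based rate constants; see [rate_params()] for units), `geometry` (um /
#' nm), `concentrations` (uM and nM, the encapsulated protein mix), `spatial`
#' (patch discretization and transport), `ratchet` (pN/um^2, nm, pN nm,
#' nm/s), `bulk` (pyrene emulation), `ensemble` (population synthesis) and
#' `solver` (integrator tolerances). The defaults are the calibrated study
#' conditions.
#'
#' @return A `run_config` (nested named list).
#' @export
default_config <- function() {
  structure(list(
    rates = unclass(rate_params()),
    geometry = list(R_vesicle_um = 10, shell_thickness_nm = 100),
    concentrations = list(actin_uM = 3, vca_uM = 0.3, arp_uM = 0.3,
                          profilin_uM = 13.5, cp_nM = 80),
    spatial = list(alpha_spread = 48, D_VCA = 0.05, D_Arp_star = 0.05,
                   N_domains = NA, seed_radius_um = 0.2, b_seed = 40,
                   r_max_um = 2.9, n_cells = 128L, t_end_s = 200,
                   dt_out_s = 2),
    ratchet = list(F_mem = 230, delta_nm = 2.7, kBT_pN_nm = .KBT_PN_NM,
                   v_free_nm_s = 11.6 * (3 - 0.1) * 2.7,
                   ratio_threshold = 1.5, speed_threshold_frac = 0.1),
    bulk = list(t_end_s = 900, dt_s = 1, noise_sd = 0, smooth_window = 1L),
    ensemble = list(n = 30L, radius_range_um = c(10, 25), cp_sdlog = 0.15,
                    mode = "surrogate", cortex_seed_threshold = 12L,
                    volume_cp_nM = 150),
    solver = list(rtol = 1e-8, atol = 1e-10, spatial_rtol = 1e-6,
                  spatial_atol = 1e-8)),
    class = "run_config")
}

.flatten_keys <- function(x, prefix = "") {
  out <- character()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    out <- c(out, key)
    if (is.list(x[[nm]])) out <- c(out, .flatten_keys(x[[nm]], key))
  }
  out
}

.merge_config <- function(base, override, prefix = "") {
  for (nm in names(override)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (!nm %in% names(base))
      stop("load_config: unknown key '", key, "'", call. = FALSE)
    if (is.list(base[[nm]]) && !is.list(override[[nm]]) &&
        length(base[[nm]]) > 1 && is.null(names(base[[nm]])))
      base[[nm]] <- override[[nm]]          # vector-valued leaf (e.g. ranges)
    else if (is.list(base[[nm]]) && !is.null(names(base[[nm]])))
      base[[nm]] <- .merge_config(base[[nm]], as.list(override[[nm]]), key)
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

.validate_config <- function(cfg) {
  tryCatch(do.call(rate_params, cfg$rates),
           error = function(e) stop("load_config: rates.* invalid: ",
                                    conditionMessage(e), call. = FALSE))
  tryCatch(do.call(vesicle_geometry, cfg$geometry),
           error = function(e) stop("load_config: geometry.* invalid: ",
                                    conditionMessage(e), call. = FALSE))
  conc <- cfg$concentrations
  for (nm in names(conc))
    if (!is.numeric(conc[[nm]]) || conc[[nm]] < 0)
      stop("load_config: concentrations.", nm, " must be >= 0", call. = FALSE)
  sp <- cfg$spatial
  tryCatch(spatial_params(sp$alpha_spread, sp$D_VCA, sp$D_Arp_star,
                          if (is.na(sp$N_domains)) 1 else sp$N_domains,
                          sp$seed_radius_um, sp$b_seed),
           error = function(e) stop("load_config: spatial.* invalid: ",
                                    conditionMessage(e), call. = FALSE))
  tryCatch(radial_grid(sp$r_max_um, sp$n_cells),
           error = function(e) stop("load_config: spatial grid invalid: ",
                                    conditionMessage(e), call. = FALSE))
  if (sp$t_end_s <= 0 || sp$dt_out_s <= 0)
    stop("load_config: spatial.t_end_s and spatial.dt_out_s must be > 0",
         call. = FALSE)
  tryCatch(do.call(ratchet_params,
                   cfg$ratchet[c("F_mem", "delta_nm", "kBT_pN_nm",
                                 "v_free_nm_s")]),
           error = function(e) stop("load_config: ratchet.* invalid: ",
                                    conditionMessage(e), call. = FALSE))
  if (cfg$bulk$smooth_window %% 2 != 1)
    stop("load_config: bulk.smooth_window must be odd", call. = FALSE)
  if (!cfg$ensemble$mode %in% c("surrogate", "full_spatial"))
    stop("load_config: ensemble.mode must be 'surrogate' or 'full_spatial'",
         call. = FALSE)
  if (min(unlist(cfg$solver)) <= 0)
    stop("load_config: solver tolerances must be > 0", call. = FALSE)
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file of (possibly partial) configuration overrides, merges it
#' over [default_config()], rejects unknown keys (naming the offending key),
#' and validates every group. An empty file yields the all-defaults
#' configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `run_config`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("concentrations:\n  cp_nM: 120", f)
#' cfg <- load_config(f)
#' cfg$concentrations$cp_nM
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("load_config: no such file: ", path, call. = FALSE)
    override <- yaml::read_yaml(path)
    if (!is.null(override)) {
      if (!is.list(override))
        stop("load_config: top level must be a mapping of key groups",
             call. = FALSE)
      cfg <- structure(.merge_config(unclass(cfg), override),
                       class = "run_config")
    }
  }
  .validate_config(cfg)
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("actocap run configuration (groups:",
      paste(names(x), collapse = ", "), ")\n")
  cat(sprintf("  CP %g nM, vesicle R %g um, spatial %d cells to %g s\n",
              x$concentrations$cp_nM, x$geometry$R_vesicle_um,
              x$spatial$n_cells, x$spatial$t_end_s))
  invisible(x)
}

## object builders from a config
config_rates <- function(cfg) do.call(rate_params, cfg$rates)
config_geometry <- function(cfg) do.call(vesicle_geometry, cfg$geometry)
config_spatial <- function(cfg, n_domains = NULL) {
  sp <- cfg$spatial
  n <- if (!is.null(n_domains)) n_domains
       else if (is.na(sp$N_domains)) default_n_domains(cfg$concentrations$cp_nM)
       else sp$N_domains
  spatial_params(sp$alpha_spread, sp$D_VCA, sp$D_Arp_star, n,
                 sp$seed_radius_um, sp$b_seed)
}
config_grid <- function(cfg) radial_grid(cfg$spatial$r_max_um, cfg$spatial$n_cells)
config_ratchet <- function(cfg)
  do.call(ratchet_params,
          cfg$ratchet[c("F_mem", "delta_nm", "kBT_pN_nm", "v_free_nm_s")])
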