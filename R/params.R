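#' Kinetic rate parameters
#'
#' Container for all rate constants of the membrane-localized branching/capping
#' reaction network, with units per field. Only `k_elong`, `k_cap`, `c_crit`
#' and `delta` are standard literature values; the remaining constants are
#' free parameters of the model, calibrated once and frozen as defaults (see
#' the methods vignette).
#'
#' @param k_bind_VG VCA + G-actin complex formation, uM^-1 s^-1.
#' @param k_act Arp2/3 activation by the VCA.G complex, uM^-1 s^-1.
#' @param k_seed de novo filament nucleation from Arp2/3* (no mother filament
#'   required), s^-1.
#' @param k_branch membrane branching, uM^-1 um^2 s^-1. The branching rate is
#'   `k_branch * max(G - c_crit, 0) * Arp2/3* * B`: branch formation requires
#'   monomer, so branching shuts down together with elongation when the monomer
#'   pool reaches the critical concentration.
#' @param k_branch_bulk solution-mode branching, uM^-2 s^-1 (all species
#'   volumetric in solution mode, hence different units).
#' @param k_elong barbed-end elongation, uM^-1 s^-1 (default 11.6, standard
#'   actin value).
#' @param k_cap CP binding to barbed ends, uM^-1 s^-1 (default 3).
#' @param k_regen regeneration of spent VCA, s^-1; slow relative to activation.
#' @param delta_nm monomer contribution to filament length, nm (default 2.7).
#' @param c_crit elongation critical concentration, uM (default 0.1).
#'
#' @return An object of class `rate_params` (a validated named list).
#' @export
#' @examples
#' p <- rate_params()
#' p$k_elong
rate_params <- function(k_bind_VG = 5,
                        k_act = 0.3,
                        k_seed = 3e-6,
                        k_branch = 6e-4,
                        k_branch_bulk = 4e-4,
                        k_elong = 11.6,
                        k_cap = 3,
                        k_regen = 0.04,
                        delta_nm = 2.7,
                        c_crit = 0.1) {
  p <- list(k_bind_VG = k_bind_VG, k_act = k_act, k_seed = k_seed,
            k_branch = k_branch, k_branch_bulk = k_branch_bulk,
            k_elong = k_elong, k_cap = k_cap, k_regen = k_regen,
            delta_nm = delta_nm, c_crit = c_crit)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("rate_params: '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("rate_params: '", nm, "' must be >= 0", call. = FALSE)
  }
  if (p$delta_nm <= 0)
    stop("rate_params: 'delta_nm' must be > 0", call. = FALSE)
  if (p$k_regen >= p$k_act)
    stop("rate_params: 'k_regen' must be < 'k_act' (regeneration is slow)",
         call. = FALSE)
  structure(p, class = "rate_params")
}

#' Vesicle geometry
#'
#' Geometry of the confining vesicle and of the membrane reaction layer used to
#' convert between bulk concentrations (uM) and membrane areal densities
#' (um^-2). For a sphere the area-to-volume ratio is 3/R, so one areal unit
#' corresponds to `(3/R)/602.214` uM.
#'
#' @param R_vesicle_um vesicle radius, um (the study encapsulates into vesicles
#'   of radius 10-25 um; default 10).
#' @param shell_thickness_nm membrane reaction-layer thickness, nm. Must be
#'   much smaller than the radius; it only enters diagnostics, since bulk
#'   mixing is treated as instantaneous in the well-mixed model.
#' @return An object of class `vesicle_geometry` with the derived conversion
#'   factor `conv_uM_per_um2` (uM per unit areal density).
#' @export
vesicle_geometry <- function(R_vesicle_um = 10, shell_thickness_nm = 100) {
  if (!is.numeric(R_vesicle_um) || R_vesicle_um <= 0)
    stop("vesicle_geometry: 'R_vesicle_um' must be > 0", call. = FALSE)
  if (!is.numeric(shell_thickness_nm) || shell_thickness_nm <= 0)
    stop("vesicle_geometry: 'shell_thickness_nm' must be > 0", call. = FALSE)
  if (shell_thickness_nm * 1e-3 >= 0.1 * R_vesicle_um)
    stop("vesicle_geometry: shell thickness must be << vesicle radius",
         call. = FALSE)
  structure(list(R_vesicle_um = R_vesicle_um,
                 shell_thickness_nm = shell_thickness_nm,
                 area_um2 = 4 * pi * R_vesicle_um^2,
                 volume_um3 = (4 / 3) * pi * R_vesicle_um^3,
                 conv_uM_per_um2 = (3 / R_vesicle_um) / .NA_UM),
            class = "vesicle_geometry")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Actin network rate parameters\n")
  units <- c(k_bind_VG = "uM^-1 s^-1", k_act = "uM^-1 s^-1", k_seed = "s^-1",
             k_branch = "uM^-1 um^2 s^-1", k_branch_bulk = "uM^-2 s^-1",
             k_elong = "uM^-1 s^-1", k_cap = "uM^-1 s^-1", k_regen = "s^-1",
             delta_nm = "nm", c_crit = "uM")
  for (nm in names(units))
    cat(sprintf("  %-14s %-10g %s\n", nm, x[[nm]], units[[nm]]))
  invisible(x)
}

#' @export
print.vesicle_geometry <- function(x, ...) {
  cat(sprintf("Vesicle geometry: R = %g um, shell = %g nm, A/V conversion = %.4g uM per um^-2\n",
              x$R_vesicle_um, x$shell_thickness_nm, x$conv_uM_per_um2))
  invisible(x)
}
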