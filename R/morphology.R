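## Brownian-ratchet mapping from barbed-end density to network protrusion
## velocity, and classification of the induced membrane deformation mode.

#' Ratchet parameters
#'
#' Load-sharing Brownian-ratchet law: the membrane load per unit area `F_mem`
#' is shared equally over the local barbed ends, so the per-filament force is
#' `F_mem / B` and the growth speed is
#' `v = v_free * exp(-F_mem * delta / (B * kBT))` -- increasing exponentially
#' with the number of pushing ends, as expected in the tension-dominated
#' regime at low filament densities.
#'
#' @param F_mem membrane load per unit area, pN/um^2. The default (230) makes
#'   the velocity span essentially 0 to ~65 nm/s over the model's barbed-end
#'   density range (0, 450] um^-2.
#' @param delta_nm monomer size, nm.
#' @param kBT_pN_nm thermal energy, pN nm (25 C).
#' @param v_free_nm_s unloaded network growth speed, nm/s; default
#'   `k_elong * (G - c_crit) * delta` at 3 uM actin (~91 nm/s).
#' @return A `ratchet_params` object.
#' @export
ratchet_params <- function(F_mem = 230, delta_nm = 2.7,
                           kBT_pN_nm = .KBT_PN_NM,
                           v_free_nm_s = 11.6 * (3 - 0.1) * 2.7) {
  if (F_mem < 0 || kBT_pN_nm <= 0 || v_free_nm_s < 0 || delta_nm <= 0)
    stop("ratchet_params: invalid parameter", call. = FALSE)
  structure(list(F_mem = F_mem, delta_nm = delta_nm, kBT_pN_nm = kBT_pN_nm,
                 v_free_nm_s = v_free_nm_s),
            class = "ratchet_params")
}

#' Unloaded growth speed for a monomer concentration
#'
#' `v_free = k_elong * max(G - c_crit, 0) * delta`, in nm/s.
#'
#' @param rates a [rate_params()].
#' @param G_uM monomer concentration, uM.
#' @return Speed in nm/s.
#' @export
free_speed <- function(rates = rate_params(), G_uM = 3) {
  rates$k_elong * max(G_uM - rates$c_crit, 0) * rates$delta_nm
}

#' Protrusion velocity of a network with B pushing ends
#'
#' @param B barbed-end areal density, um^-2 (vectorized; must be >= 0).
#' @param p a [ratchet_params()].
#' @return Speed(s) in nm/s: 0 at B = 0, strictly increasing in B, saturating
#'   at `v_free` as B grows.
#' @export
#' @examples
#' p <- ratchet_params()
#' protrusion_velocity(c(0, 50, 450), p)
protrusion_velocity <- function(B, p = ratchet_params()) {
  if (any(B < 0)) stop("protrusion_velocity: B must be >= 0", call. = FALSE)
  v <- ifelse(B > 0,
              p$v_free_nm_s * exp(-p$F_mem * p$delta_nm * 1e-3 /
                                    (B * p$kBT_pN_nm * 1e-3)),
              0)
  as.numeric(v)
}

#' Velocity profile induced by a radial barbed-end profile
#'
#' Pointwise application of [protrusion_velocity()]; the map is monotone, so
#' density ordering implies velocity ordering.
#'
#' @param profile a [radial_profile()].
#' @param p a [ratchet_params()].
#' @return A `velocity_profile`: `radii` (um) and `v` (nm/s).
#' @export
velocity_profile <- function(profile, p = ratchet_params()) {
  stopifnot(inherits(profile, "radial_profile"))
  structure(list(radii = profile$radii,
                 v = protrusion_velocity(profile$density, p),
                 time = profile$time, params = p),
            class = "velocity_profile")
}

#' Classify the membrane deformation mode of a velocity profile
#'
#' Decision rule (deterministic given the thresholds): a network too slow to
#' deform the membrane at all (mean speed at or below `speed_threshold_frac`
#' of the unloaded speed) is `flat`, whatever its shape; otherwise the
#' deformation is `concave` when the network grows faster at the domain rim
#' than in its centre (rim/centre velocity ratio above `ratio_threshold`),
#' and a `protrusion` when it grows homogeneously. Bands are fractions of the
#' occupied radius, so the call is invariant under uniform rescaling of radii.
#'
#' @param vp a [velocity_profile()].
#' @param ratio_threshold rim/centre velocity ratio for a concave call (1.5).
#' @param speed_threshold_frac protrusion threshold as a fraction of the
#'   unloaded speed (default 0.1).
#' @param center_band,rim_band,occ_frac as in [classify_profile()]; the
#'   occupied radius is measured on the velocity profile.
#' @return A `morphology_call`: `label` (protrusion | concave | flat),
#'   `rim_center_ratio`, `mean_speed` (nm/s) and the thresholds used.
#' @export
classify_morphology <- function(vp, ratio_threshold = 1.5,
                                speed_threshold_frac = 0.1,
                                center_band = c(0, 0.3), rim_band = c(0.7, 1),
                                occ_frac = 0.05) {
  stopifnot(inherits(vp, "velocity_profile"))
  r <- vp$radii; v <- vp$v
  if (!length(v)) stop("classify_morphology: empty profile", call. = FALSE)
  v_free <- vp$params$v_free_nm_s
  mean_speed <- mean(v)
  if (max(v) <= 0) {
    ratio <- 1
  } else {
    r_occ <- .occupied_radius(r, v, occ_frac)
    center <- mean(v[r >= center_band[1] * r_occ & r <= center_band[2] * r_occ])
    rim <- mean(v[r >= rim_band[1] * r_occ & r <= rim_band[2] * r_occ])
    ratio <- if (center > 0) rim / center else Inf
  }
  label <- if (mean_speed <= speed_threshold_frac * v_free) "flat"
           else if (ratio > ratio_threshold) "concave"
           else "protrusion"
  structure(list(label = label, rim_center_ratio = ratio,
                 mean_speed = mean_speed,
                 thresholds = list(ratio = ratio_threshold,
                                   speed_frac = speed_threshold_frac)),
            class = "morphology_call")
}

#' @export
print.morphology_call <- function(x, ...) {
  cat(sprintf("morphology: %s (rim/centre velocity ratio %.3g, mean speed %.3g nm/s)\n",
              x$label, x$rim_center_ratio, x$mean_speed))
  invisible(x)
}

#' Displaced actin front implied by a velocity profile
#'
#' Pure kinematics: `displacement(r) = v(r) * duration`. Also reports the sign
#' of the discrete curvature (second difference) of the displacement at the
#' domain centre -- negative for rim-dominant growth (a concave front).
#'
#' @param vp a [velocity_profile()].
#' @param duration growth time, s.
#' @return A list: `radii` (um), `displacement` (nm), `center_curvature_sign`
#'   (-1, 0, 1; zero when the second difference is below grid tolerance).
#' @export
front_shape <- function(vp, duration) {
  stopifnot(inherits(vp, "velocity_profile"))
  if (duration <= 0) stop("front_shape: duration must be > 0", call. = FALSE)
  disp <- vp$v * duration
  d2 <- diff(disp, differences = 2)
  curv <- if (length(d2)) mean(d2[seq_len(min(3, length(d2)))]) else 0
  tol <- 1e-9 * max(abs(disp), 1)
  # rim-dominant growth leaves the centre behind: concave front, negative sign
  sign_c <- if (abs(curv) <= tol) 0L else if (curv > 0) -1L else 1L
  list(radii = vp$radii, displacement = disp,
       center_curvature_sign = sign_c)
}

#' Barbed-end density below which the network cannot push the membrane
#'
#' The density at which the load-sharing ratchet velocity reaches one tenth of
#' the unloaded speed: `B = F_mem * delta / (kBT * ln 10)`. Densities below
#' this floor produce negligible growth against the membrane load (~66 um^-2
#' at the default ratchet parameters); the pattern classifier uses it to
#' ignore mechanically irrelevant residual profiles.
#'
#' @param p a [ratchet_params()].
#' @return Density, um^-2.
#' @export
mechanical_floor <- function(p = ratchet_params()) {
  p$F_mem * p$delta_nm * 1e-3 / (p$kBT_pN_nm * 1e-3 * log(10))
}
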