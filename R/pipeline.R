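## High-level single-domain pipeline: spatial run -> pattern and morphology
## calls at a defined classification time.

#' Default number of pool-sharing domains for a nominal CP concentration
#'
#' At low CP a vesicle typically nucleates a single dominant domain; at high
#' CP nucleation at multiple sites partitions the finite pools. The default
#' mapping (1 domain below 100 nM, 10 at and above) is part of the calibrated
#' study conditions.
#'
#' @param cp_nM nominal CP concentration, nM.
#' @return Integer domain count.
#' @export
default_n_domains <- function(cp_nM) {
  ifelse(cp_nM >= 100, 10L, 1L)
}

#' Simulate one spreading actin domain
#'
#' Convenience pipeline around [initial_field()] and [integrate_spatial()]:
#' growth of a single seeded domain at the study concentrations, with the
#' bulk pools shared between `n_domains` equivalent domains. Seeding is
#' represented by the explicit seeded disc, so the de novo seeding channel is
#' switched off for the field (`k_seed = 0`); set `keep_seeding = TRUE` to
#' retain it.
#'
#' @param cp_nM CP concentration, nM.
#' @param n_domains pool-sharing domain count; default [default_n_domains()].
#' @param rates a [rate_params()].
#' @param geometry a [vesicle_geometry()].
#' @param sp a [spatial_params()] (its `N_domains` is overridden by
#'   `n_domains`).
#' @param grid a [radial_grid()].
#' @param t_end,dt_out simulated time span and output spacing, s.
#' @param actin_uM,vca_uM,arp_uM encapsulated concentrations.
#' @param keep_seeding keep the de novo seeding channel active in the field.
#' @return A `spatial_trajectory`.
#' @export
simulate_domain <- function(cp_nM, n_domains = NULL, rates = rate_params(),
                            geometry = vesicle_geometry(),
                            sp = spatial_params(), grid = radial_grid(),
                            t_end = 200, dt_out = 2,
                            actin_uM = 3, vca_uM = 0.3, arp_uM = 0.3,
                            keep_seeding = FALSE) {
  if (is.null(n_domains)) n_domains <- default_n_domains(cp_nM)
  sp$N_domains <- as.integer(n_domains)
  if (!keep_seeding) {
    p <- unclass(rates)
    p$k_seed <- 0
    rates <- do.call(rate_params, p)
  }
  init <- initial_field(grid, sp, geometry, actin_uM = actin_uM,
                        vca_uM = vca_uM, arp_uM = arp_uM, cp_nM = cp_nM)
  integrate_spatial(sp, rates, init, grid, t_out = seq(0, t_end, by = dt_out))
}

#' Classification time of a domain trajectory
#'
#' The time of the domain's peak structural asymmetry: among output times at
#' which the barbed-end field is mechanically relevant (its maximum exceeds
#' `min_density`, by default the [mechanical_floor()]), the time with the
#' largest rim/centre density ratio. For a domain that never develops a rim
#' structure this is simply the moment its (flat) profile is most pronounced,
#' and for a domain that never reaches the floor it falls back to the peak of
#' the area-integrated barbed-end count.
#'
#' @param traj a `spatial_trajectory`.
#' @param min_density mechanical relevance floor, um^-2.
#' @param ... passed to [classify_profile()].
#' @return Time (s).
#' @export
classification_time <- function(traj, min_density = mechanical_floor(), ...) {
  rr <- pattern_ratio_series(traj, min_density, ...)
  if (all(is.na(rr))) return(traj$times[which.max(integrated_barbed_ends(traj))])
  traj$times[which.max(ifelse(is.na(rr), -Inf, rr))]
}

#' Rim/centre density ratio over time
#'
#' Applies [classify_profile()]'s rim/centre statistic to every output time of
#' a spatial trajectory; times at which the profile maximum is below
#' `min_density` (mechanically irrelevant) yield `NA`.
#'
#' @param traj a `spatial_trajectory`.
#' @param min_density relevance floor, um^-2 (default [mechanical_floor()]).
#' @param ... passed to [classify_profile()].
#' @return Numeric vector along `traj$times`.
#' @export
pattern_ratio_series <- function(traj, min_density = mechanical_floor(), ...) {
  sapply(seq_along(traj$times), function(i) {
    d <- traj$fields$B[i, ]
    if (max(d) < min_density) return(NA_real_)
    tryCatch(attr(classify_profile(radial_profile(traj, traj$times[i]), ...),
                  "rim_center_ratio"),
             error = function(e) NA_real_)
  })
}

#' Classify the radial barbed-end pattern of a whole growth episode
#'
#' A domain is `double_peaked` when a double-peaked barbed-end distribution
#' occurs at any point of its growth: the maximum over output times of the
#' rim/centre density ratio (taken while the field is mechanically relevant,
#' i.e. its maximum exceeds `min_density`) exceeds `ratio_threshold`.
#' Otherwise the pattern is `flat`. Restricting to mechanically relevant
#' times keeps residual near-zero fields -- whose relative shape is frozen
#' after the pools are spent -- from being mistaken for structure.
#'
#' @param traj a `spatial_trajectory`.
#' @param ratio_threshold rim/centre threshold (default 1.5, as in
#'   [classify_profile()]).
#' @param min_density relevance floor, um^-2 (default [mechanical_floor()]).
#' @param ... passed to [classify_profile()].
#' @return `"flat"` or `"double_peaked"`, with attributes `max_ratio` and
#'   `time` (when the maximum occurred).
#' @export
classify_pattern <- function(traj, ratio_threshold = 1.5,
                             min_density = mechanical_floor(), ...) {
  rr <- pattern_ratio_series(traj, min_density, ...)
  if (all(is.na(rr)))
    stop("classify_pattern: the domain never reaches a mechanically relevant ",
         "density", call. = FALSE)
  i <- which.max(ifelse(is.na(rr), -Inf, rr))
  structure(if (rr[i] > ratio_threshold) "double_peaked" else "flat",
            max_ratio = rr[i], time = traj$times[i])
}

#' Pattern and morphology of one simulated domain
#'
#' Runs [simulate_domain()], classifies the barbed-end pattern of the growth
#' episode ([classify_pattern()]), and maps the radial profile at the
#' [classification_time()] through the ratchet law to classify the induced
#' membrane deformation ([classify_morphology()]).
#'
#' @param cp_nM CP concentration, nM.
#' @param ratchet a [ratchet_params()].
#' @param traj optionally, a precomputed `spatial_trajectory` (then `cp_nM`
#'   is only documentation).
#' @param ... passed to [simulate_domain()].
#' @return A list: `pattern` (flat | double_peaked), `morphology` (a
#'   `morphology_call`), `profile`, `velocity`, `time`, `traj`.
#' @export
domain_morphology <- function(cp_nM, ratchet = ratchet_params(),
                              traj = NULL, ...) {
  if (is.null(traj)) traj <- simulate_domain(cp_nM, ...)
  floor_B <- mechanical_floor(ratchet)
  tc <- classification_time(traj, min_density = floor_B)
  prof <- radial_profile(traj, tc)
  vp <- velocity_profile(prof, ratchet)
  list(pattern = classify_pattern(traj, min_density = floor_B),
       morphology = classify_morphology(vp),
       profile = prof, velocity = vp, time = tc, traj = traj)
}
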