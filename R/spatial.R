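## Effective-2D (1D radially symmetric) finite-volume reaction-diffusion model
## of a single actin domain spreading along the membrane, coupled to finite,
## globally well-stirred bulk pools.

#' Uniform annular finite-volume grid
#'
#' Discretizes a circular membrane patch of radius `r_max_um` into `n_cells`
#' half-open annular cells `[r_i, r_{i+1})` of equal width. Cell areas are the
#' exact annulus areas, so the areas sum to the patch area to machine
#' precision and the finite-volume diffusion operator conserves mass exactly.
#'
#' @param r_max_um membrane patch radius, um (default 2.9: a single-domain
#'   footprint, domain diameters in the few-um range).
#' @param n_cells number of cells (>= 32; default 128).
#' @return A `radial_grid`: `cell_edges`, `r` (centers), `area` (um^2), `dr`.
#' @export
radial_grid <- function(r_max_um = 2.9, n_cells = 128) {
  if (n_cells < 32) stop("radial_grid: n_cells must be >= 32", call. = FALSE)
  if (r_max_um <= 0) stop("radial_grid: r_max_um must be > 0", call. = FALSE)
  edges <- seq(0, r_max_um, length.out = n_cells + 1)
  area <- pi * diff(edges^2)
  stopifnot(abs(sum(area) - pi * r_max_um^2) <= 1e-12 * pi * r_max_um^2)
  structure(list(r_max_um = r_max_um, n_cells = as.integer(n_cells),
                 cell_edges = edges, r = (edges[-1] + edges[-(n_cells + 1)]) / 2,
                 area = area, dr = edges[2] - edges[1]),
            class = "radial_grid")
}

#' Spatial model parameters
#'
#' @param alpha_spread dimensionless coupling of the barbed-end diffusivity to
#'   the polymerization speed: `D_B = alpha_spread * v_pol * delta`, with
#'   `v_pol = k_elong * max(G - c_crit, 0) * delta` the local network growth
#'   speed. Spreading therefore stops when the monomer pool is spent.
#' @param D_VCA,D_Arp_star lateral membrane diffusivities of the VCA states
#'   and of activated Arp2/3*, um^2/s (typical membrane-protein mobility).
#' @param N_domains number of equivalent domains sharing the vesicle's protein
#'   pools (the simulated patch receives a 1/N share of the bulk volume).
#' @param seed_radius_um radius of the initially seeded disc, um.
#' @param b_seed initial barbed-end density inside the seeded disc, um^-2.
#' @return A `spatial_params` object.
#' @export
spatial_params <- function(alpha_spread = 48, D_VCA = 0.05, D_Arp_star = 0.05,
                           N_domains = 1, seed_radius_um = 0.2, b_seed = 40) {
  if (alpha_spread <= 0) stop("spatial_params: alpha_spread must be > 0", call. = FALSE)
  if (N_domains < 1) stop("spatial_params: N_domains must be >= 1", call. = FALSE)
  if (min(D_VCA, D_Arp_star, seed_radius_um, b_seed) < 0)
    stop("spatial_params: negative parameter", call. = FALSE)
  structure(list(alpha_spread = alpha_spread, D_VCA = D_VCA,
                 D_Arp_star = D_Arp_star, N_domains = as.integer(N_domains),
                 seed_radius_um = seed_radius_um, b_seed = b_seed),
            class = "spatial_params")
}

#' Bulk protein pool shared by competing domains
#'
#' @param actin_uM,arp_uM total actin and Arp2/3 complex, uM.
#' @param cp_nM total capping protein, nM.
#' @param volume_um3 pool volume, um^3 (defaults to the vesicle volume of the
#'   supplied geometry).
#' @param geometry a [vesicle_geometry()] used for the default volume.
#' @return A `bulk_pool`: concentrations (uM) plus `volume_um3`.
#' @export
bulk_pool <- function(actin_uM = 3, arp_uM = 0.3, cp_nM = 80,
                      volume_um3 = NULL, geometry = vesicle_geometry()) {
  if (is.null(volume_um3)) volume_um3 <- geometry$volume_um3
  if (min(actin_uM, arp_uM, cp_nM) < 0 || volume_um3 <= 0)
    stop("bulk_pool: invalid pool", call. = FALSE)
  structure(list(conc = c(G = actin_uM, P = 0, Arp = arp_uM,
                          CPf = cp_nM * 1e-3),
                 volume_um3 = volume_um3),
            class = "bulk_pool")
}

#' Partition a shared pool between competing domains
#'
#' Domains sharing a vesicle's finite reservoirs each receive an equal 1/N
#' share: the pool volume (and hence every molecular amount) is divided by
#' `n_domains` while concentrations are unchanged, which is how competition
#' for the reservoir is represented in the per-domain simulation volume.
#'
#' @param pool a [bulk_pool()].
#' @param n_domains number of domains (>= 1).
#' @return The per-domain `bulk_pool`.
#' @export
#' @examples
#' p <- domain_competition(bulk_pool(cp_nM = 120), 4)
#' pool_amounts(p)  # one quarter of the shared amounts
domain_competition <- function(pool, n_domains) {
  stopifnot(inherits(pool, "bulk_pool"))
  if (!is.numeric(n_domains) || length(n_domains) != 1L || n_domains < 1)
    stop("domain_competition: n_domains must be >= 1", call. = FALSE)
  pool$volume_um3 <- pool$volume_um3 / n_domains
  pool
}

#' Molecule amounts held in a bulk pool
#'
#' @param pool a [bulk_pool()].
#' @return Named vector of molecule counts per species.
#' @export
pool_amounts <- function(pool) {
  stopifnot(inherits(pool, "bulk_pool"))
  pool$conc * .NA_UM * pool$volume_um3
}

#' Initial field state for a spreading domain
#'
#' Membrane fields start with VCA uniformly bound and free, no activated
#' Arp2/3*, and barbed ends only inside the seeded disc of radius
#' `sp$seed_radius_um`. The bulk pool is the vesicle reservoir partitioned by
#' `sp$N_domains` via [domain_competition()].
#'
#' @param grid a [radial_grid()].
#' @param sp a [spatial_params()].
#' @param geometry a [vesicle_geometry()].
#' @param actin_uM,vca_uM,arp_uM,cp_nM encapsulated concentrations.
#' @return A `field_state`: list of per-cell fields (`B`, `Astar`, `VCAf`,
#'   `VCAg`, `VCAs`, `Bcap`, um^-2), the per-domain `bulk` pool, and
#'   `Aused_uM` (Arp2/3* consumed into branches, uM-equivalent accumulator).
#' @export
initial_field <- function(grid, sp = spatial_params(),
                          geometry = vesicle_geometry(),
                          actin_uM = 3, vca_uM = 0.3, arp_uM = 0.3,
                          cp_nM = 80) {
  stopifnot(inherits(grid, "radial_grid"), inherits(sp, "spatial_params"))
  n <- grid$n_cells
  vca_areal <- vca_uM / geometry$conv_uM_per_um2
  B <- ifelse(grid$r <= sp$seed_radius_um, sp$b_seed, 0)
  if (all(B == 0))
    stop("initial_field: seed disc smaller than the first grid cell", call. = FALSE)
  pool <- domain_competition(
    bulk_pool(actin_uM, arp_uM, cp_nM, geometry = geometry), sp$N_domains)
  structure(list(fields = list(B = B, Astar = numeric(n),
                               VCAf = rep(vca_areal, n), VCAg = numeric(n),
                               VCAs = numeric(n), Bcap = numeric(n)),
                 bulk = pool, Aused_uM = 0, grid = grid, sp = sp,
                 geometry = geometry),
            class = "field_state")
}

.FIELD_NAMES <- c("B", "Astar", "VCAf", "VCAg", "VCAs", "Bcap")

#' Integrate the radial spreading model
#'
#' Method-of-lines integration of the membrane fields (local branching/capping
#' kinetics plus lateral diffusion with no-flux boundaries at r = 0 and
#' r = r_max) coupled to the shared, spatially uniform but finite bulk pools.
#' Barbed ends spread with the polymerization-speed-scaled diffusivity
#' `D_B = alpha_spread * v_pol * delta`; VCA states and Arp2/3* diffuse with
#' fixed membrane diffusivities.
#'
#' @param sp a [spatial_params()].
#' @param rates a [rate_params()]. Set `k_seed = 0` to model growth from an
#'   explicit seeded disc only (the default pipeline does this; see
#'   [simulate_domain()]).
#' @param init a [initial_field()] state.
#' @param grid a [radial_grid()] (must match `init`).
#' @param t_out output times (s), starting at 0.
#' @param rtol,atol solver tolerances (sparse stiff integrator, lsodes).
#' @param cons_tol relative tolerance for global conservation closure.
#' @return A `spatial_trajectory`: `times`, per-field matrices (times x
#'   cells), `bulk` data.frame (times x G, P, Arp, CPf, Aused_uM), the grid
#'   and parameters.
#' @export
integrate_spatial <- function(sp, rates, init, grid = init$grid, t_out,
                              rtol = 1e-6, atol = 1e-8, cons_tol = 1e-5) {
  stopifnot(inherits(init, "field_state"), inherits(grid, "radial_grid"))
  if (!inherits(rates, "rate_params")) rates <- do.call(rate_params, rates)
  n <- grid$n_cells
  if (length(init$fields$B) != n)
    stop("integrate_spatial: grid does not match the initial field", call. = FALSE)
  if (t_out[1] != 0 || is.unsorted(t_out, strictly = TRUE))
    stop("integrate_spatial: t_out must start at 0 and increase", call. = FALSE)

  p <- rates
  delta_um <- p$delta_nm * 1e-3
  a <- grid$area
  V <- init$bulk$volume_um3
  cfac <- a / (.NA_UM * V)            # areal amount in cell i -> uM in bulk
  w <- 2 * pi * grid$cell_edges[2:n] / grid$dr  # interior-edge weights

  lap <- function(u, D) {
    flux <- D * w * (u[-1] - u[-n])   # inward-positive edge fluxes
    (c(flux, 0) - c(0, flux)) / a
  }

  idx <- function(k) (4 + (k - 1) * n + 1):(4 + k * n)
  y0 <- c(init$bulk$conc[c("G", "P", "Arp", "CPf")],
          unlist(init$fields[.FIELD_NAMES], use.names = FALSE), init$Aused_uM)

  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    G <- y[1]; Arp <- y[3]; CPf <- y[4]
    B <- y[idx(1)]; As <- y[idx(2)]; Vf <- y[idx(3)]
    Vg <- y[idx(4)]; Vs <- y[idx(5)]
    gd <- max(G - p$c_crit, 0)
    r1 <- p$k_bind_VG * G * Vf
    r2 <- p$k_act * Arp * Vg
    r3 <- p$k_seed * As
    r4 <- p$k_branch * gd * As * B
    r5 <- p$k_elong * gd * B          # no depolymerization branch in space
    r6 <- p$k_cap * CPf * B
    r7 <- p$k_regen * Vs
    v_pol <- p$k_elong * gd * delta_um
    D_B <- sp$alpha_spread * v_pol * delta_um

    dB <- r3 + r4 - r6 + lap(B, D_B)
    dAs <- r2 - r3 - r4 + lap(As, sp$D_Arp_star)
    dVf <- -r1 + r7 + lap(Vf, sp$D_VCA)
    dVg <- r1 - r2 + lap(Vg, sp$D_VCA)
    dVs <- r2 - r7 + lap(Vs, sp$D_VCA)
    dBcap <- r6
    dG <- -sum(cfac * (r1 + r5))
    dP <- sum(cfac * (r2 + r5))
    dArp <- -sum(cfac * r2)
    dCP <- -sum(cfac * r6)
    dAused <- sum(cfac * (r3 + r4))
    list(c(dG, dP, dArp, dCP, dB, dAs, dVf, dVg, dVs, dBcap, dAused))
  }

  sol <- deSolve::ode(y = y0, times = t_out, func = deriv, parms = NULL,
                      method = "lsodes", rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("integrate_spatial: solver failed (istate = ", diagn[1], ")",
         call. = FALSE)
  m <- sol[, -1, drop = FALSE]
  neg <- min(m)
  if (neg < -1e4 * atol)
    stop("integrate_spatial: negative density beyond tolerance (min = ",
         signif(neg, 3), ")", call. = FALSE)
  if (neg < -atol)
    warning("integrate_spatial: clamped small negative densities (min = ",
            signif(neg, 3), ")")
  m[m < 0] <- 0

  fields <- setNames(lapply(seq_along(.FIELD_NAMES), function(k)
    m[, idx(k), drop = FALSE]), .FIELD_NAMES)
  bulk <- data.frame(time_s = t_out, G = m[, 1], P = m[, 2], Arp = m[, 3],
                     CPf = m[, 4], Aused_uM = m[, ncol(m)])
  traj <- structure(list(times = t_out, fields = fields, bulk = bulk,
                         grid = grid, sp = sp, rates = rates,
                         volume_um3 = V, cfac = cfac),
                    class = "spatial_trajectory")
  dev <- spatial_conservation_error(traj)
  if (dev > cons_tol)
    stop("integrate_spatial: global conservation violated (relative error ",
         signif(dev, 3), " > ", cons_tol, ")", call. = FALSE)
  traj
}

#' Global conservation error of a spatial trajectory
#'
#' Checks closure of the actin, CP, VCA and Arp2/3 totals (area-integrated
#' membrane fields plus shared bulk pools) against their initial values.
#'
#' @param traj a `spatial_trajectory`.
#' @return Largest relative deviation over moieties and times.
#' @export
spatial_conservation_error <- function(traj) {
  f <- traj$fields
  cf <- traj$cfac
  int <- function(mat) as.numeric(mat %*% cf)  # uM-equivalents
  tot <- cbind(
    actin = traj$bulk$G + traj$bulk$P + int(f$VCAg),
    cp = traj$bulk$CPf + int(f$Bcap),
    vca = int(f$VCAf) + int(f$VCAg) + int(f$VCAs),
    arp = traj$bulk$Arp + int(f$Astar) + traj$bulk$Aused_uM)
  ref <- tot[1, ]
  scale <- pmax(abs(ref), max(abs(ref)) * 1e-3)
  max(abs(sweep(tot, 2, ref)) / rep(scale, each = nrow(tot)))
}

#' @export
print.spatial_trajectory <- function(x, ...) {
  cat(sprintf("spatial_trajectory: %d cells over %g um, %d times to %g s, N_domains = %d\n",
              x$grid$n_cells, x$grid$r_max_um, length(x$times), max(x$times),
              x$sp$N_domains))
  cat(sprintf("  max barbed-end density %.3g um^-2, final bulk G %.3g uM\n",
              max(x$fields$B), x$bulk$G[nrow(x$bulk)]))
  invisible(x)
}

#' Extract a radial barbed-end profile at one time
#'
#' @param traj a `spatial_trajectory`.
#' @param time requested time (s); the nearest output time is used.
#' @return A `radial_profile`: `radii` (cell centers, um), `density` (um^-2),
#'   `time` (the output time actually used).
#' @export
radial_profile <- function(traj, time) {
  stopifnot(inherits(traj, "spatial_trajectory"))
  i <- which.min(abs(traj$times - time))
  structure(list(radii = traj$grid$r, density = traj$fields$B[i, ],
                 time = traj$times[i]),
            class = "radial_profile")
}

.occupied_radius <- function(radii, density, occ_frac) {
  m <- max(density)
  occ <- density > occ_frac * m
  if (!any(occ)) return(NA_real_)
  max(radii[occ])
}

#' Classify a radial barbed-end profile as flat or double-peaked
#'
#' A profile is `double_peaked` when the mean density over the outer rim band
#' exceeds the mean over the central band by more than `ratio_threshold`;
#' bands are fractions of the occupied radius (the outermost radius where the
#' density exceeds `occ_frac` of the profile maximum), so the call is
#' invariant under uniform rescaling of radii.
#'
#' @param profile a [radial_profile()].
#' @param ratio_threshold rim/center mean-density ratio above which the
#'   profile is called double-peaked (default 1.5).
#' @param center_band,rim_band band limits as fractions of the occupied
#'   radius.
#' @param occ_frac support threshold as a fraction of the profile maximum.
#' @return `"flat"` or `"double_peaked"`, with attribute `rim_center_ratio`.
#' @export
classify_profile <- function(profile, ratio_threshold = 1.5,
                             center_band = c(0, 0.3), rim_band = c(0.7, 1),
                             occ_frac = 0.05) {
  stopifnot(inherits(profile, "radial_profile"))
  r <- profile$radii; d <- profile$density
  if (max(d) <= 0)
    stop("classify_profile: all-zero profile (no domain)", call. = FALSE)
  r_occ <- .occupied_radius(r, d, occ_frac)
  center <- mean(d[r >= center_band[1] * r_occ & r <= center_band[2] * r_occ])
  rim <- mean(d[r >= rim_band[1] * r_occ & r <= rim_band[2] * r_occ])
  ratio <- if (center > 0) rim / center else Inf
  structure(if (ratio > ratio_threshold) "double_peaked" else "flat",
            rim_center_ratio = ratio, time = profile$time)
}

#' Time at which a spreading domain becomes radially flat
#'
#' Earliest output time at which the coefficient of variation of the
#' barbed-end density over the spread region (every cell inside the occupied
#' radius, excluding the outermost 10% of that radius) falls below
#' `cv_threshold`. Only times at which the domain has spread over more than
#' half of the patch radius are considered.
#'
#' @param traj a `spatial_trajectory`.
#' @param cv_threshold flatness threshold on the coefficient of variation
#'   (default 0.10).
#' @param occ_frac support threshold as a fraction of the profile maximum.
#' @param support_frac minimum occupied radius as a fraction of the patch.
#' @param edge_exclude fraction of the occupied radius excluded at the edge.
#' @return Flatness time (s), or `NA` if the spread domain never flattens.
#'   Errors if the domain never spreads past `support_frac`.
#' @export
flatness_time <- function(traj, cv_threshold = 0.10, occ_frac = 0.05,
                          support_frac = 0.5, edge_exclude = 0.1) {
  stopifnot(inherits(traj, "spatial_trajectory"))
  r <- traj$grid$r
  spread_any <- FALSE
  for (i in seq_along(traj$times)) {
    d <- traj$fields$B[i, ]
    if (max(d) <= 0) next
    r_occ <- .occupied_radius(r, d, occ_frac)
    if (is.na(r_occ) || r_occ < support_frac * traj$grid$r_max_um) next
    spread_any <- TRUE
    region <- d[r <= (1 - edge_exclude) * r_occ]
    if (length(region) < 2 || mean(region) <= 0) next
    if (sd(region) / mean(region) < cv_threshold) return(traj$times[i])
  }
  if (!spread_any)
    stop("flatness_time: domain never spreads over ", support_frac,
         " of the patch radius", call. = FALSE)
  NA_real_
}

#' Area-integrated barbed-end count over time
#'
#' @param traj a `spatial_trajectory`.
#' @return Numeric vector (ends per domain) along `traj$times`.
#' @export
integrated_barbed_ends <- function(traj) {
  as.numeric(traj$fields$B %*% traj$grid$area)
}
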