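## Well-mixed deterministic integration, steady states and phase detection.

#' Integrate the well-mixed reaction network
#'
#' Deterministic (stiff ODE) integration of the network returned by
#' [build_network()], with conservation and non-negativity checks on the
#' output. In finite mode the four conserved moieties (actin, CP, VCA, Arp2/3)
#' must close to `cons_tol` relative at every output time, otherwise an
#' internal-consistency error is raised.
#'
#' @param network a [build_network()] object.
#' @param init named initial state from [initial_pool()].
#' @param t_grid output times, starting at 0 (s).
#' @param rtol,atol solver tolerances (lsoda defaults 1e-8 / 1e-10).
#' @param cons_tol relative tolerance for conservation closure (finite mode).
#' @return An `actin_trajectory`: list with `times`, `states` (data.frame, one
#'   column per species), `branch_rate` and `cap_rate` event-rate series
#'   (um^-2 s^-1, or uM/s in solution mode), and the network.
#' @export
#' @examples
#' net <- build_network(rate_params(), vesicle_geometry(), "finite")
#' tr <- integrate_wellmixed(net, initial_pool(net, cp_nM = 80), seq(0, 60, 0.5))
#' max(tr$states$B)
integrate_wellmixed <- function(network, init, t_grid,
                                rtol = 1e-8, atol = 1e-10, cons_tol = 1e-6) {
  stopifnot(inherits(network, "reaction_network"))
  if (t_grid[1] != 0) stop("integrate_wellmixed: t_grid must start at 0", call. = FALSE)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("integrate_wellmixed: t_grid must be strictly increasing", call. = FALSE)
  y0 <- init[network$species]
  if (anyNA(y0)) stop("integrate_wellmixed: init is missing species", call. = FALSE)
  if (any(y0 < 0)) stop("integrate_wellmixed: negative initial state", call. = FALSE)

  S <- network$S
  deriv <- function(t, y, parms) {
    list(drop(S %*% network$rate_fn(y)))
  }
  sol <- deSolve::ode(y = y0, times = t_grid, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("integrate_wellmixed: solver failed (istate = ", diagn[1], ")",
         call. = FALSE)
  states <- as.data.frame(sol[, network$species, drop = FALSE])

  # clamp solver-scale negative excursions, reject anything larger
  neg <- min(as.matrix(states))
  if (neg < -1e4 * atol - 1e-12)
    stop("integrate_wellmixed: negative species beyond tolerance (min = ",
         signif(neg, 3), ")", call. = FALSE)
  states[states < 0] <- 0

  traj <- structure(list(times = t_grid, states = states,
                         branch_rate = numeric(nrow(states)),
                         cap_rate = numeric(nrow(states)),
                         network = network),
                    class = "actin_trajectory")
  rates <- t(apply(as.matrix(states), 1, network$rate_fn))
  traj$branch_rate <- rates[, "branching"]
  traj$cap_rate <- rates[, "capping"]

  if (network$reservoir_mode != "infinite") {
    dev <- conservation_error(traj)
    if (dev > cons_tol)
      stop("integrate_wellmixed: conservation violated (relative error ",
           signif(dev, 3), " > ", cons_tol, ")", call. = FALSE)
  }
  traj
}

#' Maximum relative conservation error of a trajectory
#'
#' Largest relative deviation of any conserved moiety (actin, CP, VCA, Arp2/3)
#' from its initial total, over all output times. Moieties with zero total are
#' compared on the scale of the total actin pool.
#'
#' @param traj an `actin_trajectory`.
#' @return Single non-negative number.
#' @export
conservation_error <- function(traj) {
  tot <- t(apply(as.matrix(traj$states), 1, function(y)
    pool_totals(traj$network, y)))
  ref <- tot[1, ]
  scale <- pmax(abs(ref), max(abs(ref)) * 1e-3, .Machine$double.eps)
  max(abs(sweep(tot, 2, ref)) / rep(scale, each = nrow(tot)))
}

#' @export
print.actin_trajectory <- function(x, ...) {
  cat(sprintf("actin_trajectory: %d times over [0, %g] s (%s reservoir)\n",
              length(x$times), max(x$times), x$network$reservoir_mode))
  cat(sprintf("  barbed ends: max %.3g, final %.3g %s\n",
              max(x$states$B), x$states$B[nrow(x$states)],
              x$network$units[["B"]]))
  invisible(x)
}

#' Infinite-reservoir steady state
#'
#' Closed-form fixed point of the rate laws in infinite-reservoir mode. The
#' VCA cycle (free -> G-loaded -> spent -> free) carries a stationary flux
#' `phi = VCA_tot / (1/(k_bind_VG G) + 1/(k_act Arp) + 1/k_regen)`; balancing
#' Arp2/3* production against seeding plus branching, and barbed-end creation
#' against capping, gives `B_ss = phi / (k_cap CP)` and
#' `Astar_ss = phi / (k_seed + k_branch (G - c_crit) B_ss)`. The accumulators
#' `P` and `Bcap` grow linearly forever in infinite mode and are not part of
#' the fixed point. The result is verified against the rate laws (residual
#' below `atol`) before returning.
#'
#' If `k_seed = 0` and the initial state has no barbed ends, the barbed-end
#' subsystem is absorbing at `B = 0` (no seeding path); the absorbing state is
#' returned with `Astar = NA` (Arp2/3* has no sink there) and a warning.
#'
#' @param network a [build_network()] object in `"infinite"` mode.
#' @param init named initial state (supplies the held bulk levels and totals).
#' @param atol absolute residual tolerance for the fixed-point check.
#' @return Named steady-state vector over the network species (with `P`,
#'   `Bcap`, `Aused` set to `NA`, as they have no fixed point), with attribute
#'   `phi` (VCA cycle flux).
#' @export
steady_state <- function(network, init, atol = 1e-8) {
  stopifnot(inherits(network, "reaction_network"))
  if (network$reservoir_mode != "infinite")
    stop("steady_state: infinite reservoir mode only", call. = FALSE)
  p <- network$params
  y0 <- init[network$species]
  G <- y0[["G"]]; Arp <- y0[["Arp"]]; CP <- y0[["CPf"]]
  vca_tot <- y0[["VCAf"]] + y0[["VCAg"]] + y0[["VCAs"]]

  ss <- setNames(rep(NA_real_, length(network$species)), network$species)
  ss["G"] <- G; ss["Arp"] <- Arp; ss["CPf"] <- CP

  if (p$k_seed == 0 && y0[["B"]] == 0) {
    warning("steady_state: no seeding path and no initial barbed ends; ",
            "returning the absorbing state B = 0 (Arp2/3* has no sink)")
    ss["B"] <- 0
    ss[c("VCAf", "VCAg", "VCAs")] <- NA_real_
    return(ss)
  }
  if (G <= 0 || Arp <= 0 || p$k_regen <= 0 || p$k_bind_VG <= 0 || p$k_act <= 0)
    stop("steady_state: VCA cycle cannot carry flux (zero rate or pool)",
         call. = FALSE)
  phi <- vca_tot / (1 / (p$k_bind_VG * G) + 1 / (p$k_act * Arp) + 1 / p$k_regen)
  if (CP <= 0)
    stop("steady_state: no fixed point without capping (B grows unboundedly)",
         call. = FALSE)
  B <- phi / (p$k_cap * CP * 1)
  gd <- max(G - p$c_crit, 0)
  Astar <- phi / (p$k_seed + p$k_branch * gd * B)
  ss["VCAf"] <- phi / (p$k_bind_VG * G)
  ss["VCAg"] <- phi / (p$k_act * Arp)
  ss["VCAs"] <- phi / p$k_regen
  ss["Astar"] <- Astar
  ss["B"] <- B

  # residual check on the dynamical (non-accumulator) components
  y <- ss
  y[c("P", "Bcap", "Aused")] <- 0
  dy <- drop(network$S %*% network$rate_fn(y))
  res <- max(abs(dy[c("VCAf", "VCAg", "VCAs", "Astar", "B")]))
  if (!is.finite(res) || res > atol * max(1, phi))
    stop("steady_state: fixed-point residual ", signif(res, 3),
         " exceeds tolerance", call. = FALSE)
  attr(ss, "phi") <- phi
  ss
}

#' Detect growth phases of a barbed-end trajectory
#'
#' Segments a barbed-end time course into the seeding phase (before the
#' density exceeds `seed_frac` of its maximum), the initial rapid-growth phase
#' (up to the time of maximal dB/dt, searched at or after the seeding end),
#' and the transient phase (until |dB/dt| first falls below `steady_frac` of
#' the peak growth rate). Thresholds are scale-free fractions.
#'
#' @param traj an `actin_trajectory`, or a list with `times` and `states$B`.
#' @param seed_frac seeding threshold as a fraction of max B (default 0.01).
#' @param steady_frac steady threshold as a fraction of peak |dB/dt| (0.01).
#' @return An object of class `growth_phases`: `t_seed_end <= t_initial_end <=
#'   t_transient_end` and `steady_reached`; `t_transient_end` is `NA` when the
#'   trajectory never settles inside the window.
#' @export
detect_phases <- function(traj, seed_frac = 0.01, steady_frac = 0.01) {
  t <- traj$times
  B <- traj$states$B
  if (length(t) < 3) stop("detect_phases: trajectory too short", call. = FALSE)
  Bmax <- max(B)
  if (Bmax <= 0) stop("detect_phases: no barbed ends ever form", call. = FALSE)

  i_seed <- which(B > seed_frac * Bmax)[1]
  if (is.na(i_seed)) i_seed <- length(t)
  dB <- diff(B) / diff(t)
  tm <- (t[-1] + t[-length(t)]) / 2
  win <- which(tm >= t[i_seed] - .Machine$double.eps)
  if (!length(win)) win <- length(dB)
  i_rapid <- win[which.max(dB[win])]
  t_initial <- max(tm[i_rapid], t[i_seed])

  peak_rate <- max(abs(dB[win]))
  later <- which(tm > tm[i_rapid] & abs(dB) < steady_frac * peak_rate)
  steady <- length(later) > 0
  structure(list(t_seed_end = t[i_seed],
                 t_initial_end = t_initial,
                 t_transient_end = if (steady) tm[later[1]] else NA_real_,
                 steady_reached = steady),
            class = "growth_phases")
}

#' @export
print.growth_phases <- function(x, ...) {
  cat(sprintf(
    "growth phases: seeding end %.3g s, rapid-growth end %.3g s, transient end %s, steady %s\n",
    x$t_seed_end, x$t_initial_end,
    if (is.na(x$t_transient_end)) "not reached" else sprintf("%.3g s", x$t_transient_end),
    x$steady_reached))
  invisible(x)
}
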