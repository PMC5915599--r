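## Solution-mode polymerization emulation (pyrene-like normalized curves) and
## tangent-method lag/rate extraction.

#' Simulate a bulk (solution) polymerization curve
#'
#' Runs the reaction network in solution mode -- VCA as a bulk species, no
#' membrane localization -- and reports the polymerized actin fraction
#' `P / A_tot` over time, the kinetic shape a pyrene fluorescence assay
#' tracks (linear reporter, no photophysics). Optional seeded Gaussian
#' observation noise emulates instrument noise.
#'
#' Profilin is not an explicit species: its roles (suppressing spontaneous
#' nucleation and pointed-end growth) are embodied by the absence of both
#' processes from the network; the argument is accepted for the record and
#' validated only.
#'
#' @param rates a [rate_params()].
#' @param actin_uM,vca_uM,arp_uM,profilin_uM,cp_nM assay concentrations
#'   (defaults: the study's 3 / 0.3 / 0.3 / 13.5 uM and 20 nM CP).
#' @param t_end end time, s (default 600).
#' @param dt output spacing, s.
#' @param noise_sd Gaussian observation noise on the normalized signal.
#' @param seed RNG seed for the noise (ignored when `noise_sd = 0`).
#' @return A `pyrene_curve`: `times` (s), `f_poly` (noisy signal, clipped to
#'   [0, 1]), `f_true` (noise-free), `noise_sd`, `seed`.
#' @export
#' @examples
#' pc <- simulate_bulk(rate_params(), cp_nM = 20, t_end = 300)
#' max(pc$f_poly)
simulate_bulk <- function(rates = rate_params(), actin_uM = 3, vca_uM = 0.3,
                          arp_uM = 0.3, profilin_uM = 13.5, cp_nM = 20,
                          t_end = 600, dt = 1, noise_sd = 0, seed = 1L) {
  if (min(actin_uM, vca_uM, arp_uM, profilin_uM, cp_nM, noise_sd) < 0)
    stop("simulate_bulk: concentrations must be >= 0", call. = FALSE)
  net <- build_network(rates, vesicle_geometry(), "solution")
  init <- initial_pool(net, actin_uM = actin_uM, vca_uM = vca_uM,
                       arp_uM = arp_uM, cp_nM = cp_nM)
  tg <- seq(0, t_end, by = dt)
  tr <- integrate_wellmixed(net, init, tg)
  # pyrene reports stacked F-actin; monomers held in not-yet-branched Arp2/3*
  # nuclei do not contribute to the signal
  f_true <- if (actin_uM > 0) {
    pmax(tr$states$P - tr$states$Astar, 0) / actin_uM
  } else rep(0, length(tg))
  f <- f_true
  if (noise_sd > 0) {
    set.seed(seed)
    f <- pmin(pmax(f_true + rnorm(length(f_true), sd = noise_sd), 0), 1)
  }
  structure(list(times = tg, f_poly = f, f_true = f_true,
                 noise_sd = noise_sd, seed = seed,
                 concentrations = c(actin_uM = actin_uM, vca_uM = vca_uM,
                                    arp_uM = arp_uM, profilin_uM = profilin_uM,
                                    cp_nM = cp_nM)),
            class = "pyrene_curve")
}

#' @export
print.pyrene_curve <- function(x, ...) {
  cat(sprintf("pyrene_curve: %d points to %g s, plateau %.3g, noise sd %g\n",
              length(x$times), max(x$times), max(x$f_poly), x$noise_sd))
  invisible(x)
}

#' Tangent-method lag time and maximal rate of a polymerization curve
#'
#' Classic tangent construction: the lag time is where the tangent at the
#' point of maximal slope intersects the baseline `f = 0`, and the maximal
#' rate is that slope. The curve is smoothed with a centred moving average of
#' `smooth_window` points before differentiation (`smooth_window = 1` leaves
#' it untouched; use an odd window of ~11 for noisy data).
#'
#' @param curve a [simulate_bulk()] curve, or any list with `times` and
#'   `f_poly`.
#' @param smooth_window odd moving-average window length (points).
#' @return A `lag_rate_result`: `t_lag_s` (clamped at 0), `max_rate_per_s`,
#'   `t_at_max_rate_s`, `method = "tangent"`, `smooth_window`.
#' @export
#' @examples
#' t <- seq(0, 400, 0.5)
#' logistic <- list(times = t, f_poly = 1 / (1 + exp(-0.05 * (t - 200))))
#' extract_lag(logistic)$t_lag_s  # = 200 - 2/0.05
extract_lag <- function(curve, smooth_window = 1) {
  t <- curve$times
  f <- curve$f_poly
  if (length(t) < 5) stop("extract_lag: curve too short", call. = FALSE)
  if (smooth_window %% 2 != 1 || smooth_window < 1)
    stop("extract_lag: smooth_window must be odd and >= 1", call. = FALSE)
  plateau <- max(f)
  if (plateau <= 0 || f[length(f)] < 0.5 * plateau)
    stop("extract_lag: curve does not reach half of its plateau ",
         "(insufficient curve)", call. = FALSE)
  if (smooth_window > 1) {
    fs <- as.numeric(stats::filter(f, rep(1 / smooth_window, smooth_window),
                                   sides = 2))
    keep <- !is.na(fs)
    t <- t[keep]; f <- fs[keep]
  }
  slope <- diff(f) / diff(t)
  i <- which.max(slope)
  tm <- (t[i] + t[i + 1]) / 2
  fm <- (f[i] + f[i + 1]) / 2
  s <- slope[i]
  if (s <= 0) stop("extract_lag: curve never rises", call. = FALSE)
  structure(list(t_lag_s = max(tm - fm / s, 0), max_rate_per_s = s,
                 t_at_max_rate_s = tm, method = "tangent",
                 smooth_window = smooth_window),
            class = "lag_rate_result")
}

#' @export
print.lag_rate_result <- function(x, ...) {
  cat(sprintf("lag (tangent method): %.3g s (%.3g min), max rate %.3g /s\n",
              x$t_lag_s, x$t_lag_s / 60, x$max_rate_per_s))
  invisible(x)
}
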