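#' Stochastic (Gillespie) simulation of the solution-mode network
#'
#' Runs exact stochastic realizations of the same reaction network that
#' [integrate_wellmixed()] integrates deterministically, at molecule-count
#' resolution in a small reaction volume. Serves as the independent oracle for
#' the ODE trajectories: at small copy numbers the ODE solution must lie
#' within a few standard errors of the ensemble mean.
#'
#' @param network a [build_network()] object in `"solution"` mode.
#' @param init named initial state in uM (from [initial_pool()]).
#' @param volume_um3 reaction volume, um^3 (sets copy numbers: 1 uM in 1 um^3
#'   is ~602 molecules).
#' @param t_grid output times (s), starting at 0.
#' @param n_runs number of realizations (default 500).
#' @param seed RNG seed (R's RNG; recorded in the result).
#' @return An `ssa_ensemble`: `times`, `mean` and `sd` matrices (times x
#'   species, concentration units uM), `n_runs`, `volume_um3`, `seed`, and the
#'   initial molecule counts `counts0`.
#' @export
ssa_wellmixed <- function(network, init, volume_um3, t_grid,
                          n_runs = 500, seed = 1L) {
  stopifnot(inherits(network, "reaction_network"))
  if (network$reservoir_mode != "solution")
    stop("ssa_wellmixed: solution-mode network required (all species volumetric)",
         call. = FALSE)
  if (volume_um3 <= 0) stop("ssa_wellmixed: volume must be > 0", call. = FALSE)
  nav <- .NA_UM * volume_um3
  y0 <- init[network$species]
  counts0 <- round(y0 * nav)
  set.seed(seed)
  raw <- ssa_run_cpp(as.numeric(counts0), unclass(network$params), nav,
                     as.numeric(t_grid), as.integer(n_runs))
  arr <- array(raw, dim = c(n_runs, length(t_grid), length(network$species)),
               dimnames = list(NULL, NULL, network$species))
  mean_c <- apply(arr, c(2, 3), mean) / nav
  sd_c <- apply(arr, c(2, 3), sd) / nav
  structure(list(times = t_grid, mean = mean_c, sd = sd_c, n_runs = n_runs,
                 volume_um3 = volume_um3, seed = seed, counts0 = counts0),
            class = "ssa_ensemble")
}

#' @export
print.ssa_ensemble <- function(x, ...) {
  cat(sprintf("ssa_ensemble: %d runs, %d molecules initially, %d output times (seed %d)\n",
              x$n_runs, sum(x$counts0), length(x$times), x$seed))
  invisible(x)
}
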