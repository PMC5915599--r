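## Shared fixtures, built once per session. Everything is generated in code;
## the calibrated default runs are reused across test files to stay within
## the suite's time budget.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# default-calibration single-domain run (the study conditions)
std_domain <- function(cp_nM, n_cells = 128) {
  cached(sprintf("dom_%d_%d", cp_nM, n_cells),
         simulate_domain(cp_nM, grid = radial_grid(n_cells = n_cells)))
}

# default-calibration bulk pyrene curve
std_curve <- function(cp_nM) {
  cached(sprintf("bulk_%d", cp_nM),
         simulate_bulk(cp_nM = cp_nM, t_end = 900, dt = 1))
}

std_surrogate <- function() {
  cached("surrogate",
         build_surrogate(cp_grid = c(40, 60, 120), seeds_grid = c(1, 2, 4, 8)))
}

# finite-reservoir well-mixed trajectory at default rates
std_wellmixed <- function(cp_nM, mode = "finite", t_end = 300) {
  cached(sprintf("wm_%s_%d_%d", mode, cp_nM, t_end), {
    net <- build_network(rate_params(), vesicle_geometry(), mode)
    integrate_wellmixed(net, initial_pool(net, cp_nM = cp_nM),
                        seq(0, t_end, 0.5))
  })
}

# hand-built spatial_trajectory for classifier edge cases
synthetic_spatial <- function(profile_fn, times = seq(0, 10, 2),
                              n_cells = 64) {
  grid <- radial_grid(r_max_um = 3, n_cells = n_cells)
  B <- t(vapply(times, function(t) profile_fn(grid$r, t),
                numeric(n_cells)))
  structure(list(times = times, fields = list(B = B), grid = grid),
            class = "spatial_trajectory")
}
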