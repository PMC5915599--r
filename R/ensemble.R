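## Synthetic vesicle-ensemble generator and morphology summary layer.

#' Mean number of nucleation seeds per vesicle at a given CP
#'
#' CP slows single-filament growth but favours repeated nucleation, so the
#' number of membrane nucleation sites rises with CP. Calibrated linear form:
#' ~1.5 expected seeds at 40 nM and ~10 at 120 nM, floored at 0.2.
#'
#' @param cp_nM CP concentration, nM (vectorized).
#' @return Poisson mean(s).
#' @export
lambda_seeds <- function(cp_nM) {
  pmax(0.106 * cp_nM - 2.75, 0.2)
}

#' Sample a synthetic vesicle population
#'
#' Draws vesicle radii uniformly over the encapsulation range, per-vesicle CP
#' concentrations with multiplicative lognormal noise around the nominal
#' value (encapsulation variability), and CP-dependent Poisson seed counts.
#' Per-vesicle RNG seeds are derived deterministically from `master_seed`, so
#' the whole population (and everything simulated from it) is reproducible.
#'
#' @param n number of vesicles.
#' @param cp_nM nominal CP concentration, nM (recycled over vesicles).
#' @param radius_range_um radius range, um (default c(10, 25)).
#' @param cp_sdlog lognormal sdlog of the CP noise (default 0.15).
#' @param lambda_fn function mapping CP (nM) to the Poisson seed mean
#'   (default [lambda_seeds()]).
#' @param master_seed integer master seed.
#' @return A `vesicle_specs` data.frame: `vesicle`, `cp_nominal_nM`,
#'   `radius_um`, `cp_actual_nM`, `n_seeds`, `rng_seed`.
#' @export
#' @examples
#' sample_vesicles(5, cp_nM = 40, master_seed = 7)
sample_vesicles <- function(n, cp_nM = 80, radius_range_um = c(10, 25),
                            cp_sdlog = 0.15, lambda_fn = lambda_seeds,
                            master_seed = 1L) {
  if (n < 0) stop("sample_vesicles: n must be >= 0", call. = FALSE)
  if (length(radius_range_um) != 2 || any(radius_range_um <= 0) ||
      radius_range_um[1] > radius_range_um[2])
    stop("sample_vesicles: invalid radius_range_um", call. = FALSE)
  if (cp_sdlog < 0) stop("sample_vesicles: cp_sdlog must be >= 0", call. = FALSE)
  if (any(cp_nM < 0)) stop("sample_vesicles: cp_nM must be >= 0", call. = FALSE)
  cp_nominal <- rep_len(cp_nM, max(n, 1))[seq_len(n)]
  set.seed(master_seed)
  radius <- runif(n, radius_range_um[1], radius_range_um[2])
  cp_actual <- cp_nominal * rlnorm(n, meanlog = -cp_sdlog^2 / 2, sdlog = cp_sdlog)
  lam <- lambda_fn(cp_actual)
  if (any(!is.finite(lam)) || any(lam < 0))
    stop("sample_vesicles: lambda_fn returned an invalid Poisson mean",
         call. = FALSE)
  n_seeds <- rpois(n, lam)
  rng_seed <- if (n > 0) sample.int(.Machine$integer.max, n) else integer()
  structure(data.frame(vesicle = seq_len(n), cp_nominal_nM = cp_nominal,
                       radius_um = radius, cp_actual_nM = cp_actual,
                       n_seeds = n_seeds, rng_seed = rng_seed),
            master_seed = master_seed, class = c("vesicle_specs", "data.frame"))
}

.MORPH_LABELS <- c("protrusion", "concave", "flat", "cortex", "volume_network")

.label_one_vesicle <- function(cp_actual, n_seeds, radius_um,
                               mode, surrogate, cortex_seed_threshold,
                               volume_cp_nM, ...) {
  if (cp_actual >= volume_cp_nM) return("volume_network")
  if (n_seeds >= cortex_seed_threshold) return("cortex")
  if (n_seeds == 0) return("flat")
  if (mode == "surrogate") {
    i <- which.min(abs(surrogate$cp_nM - cp_actual) / cp_actual +
                     abs(surrogate$n_seeds - n_seeds) /
                       pmax(surrogate$n_seeds, 1))
    return(surrogate$label[i])
  }
  dm <- domain_morphology(cp_actual, n_domains = n_seeds,
                          geometry = vesicle_geometry(R_vesicle_um = radius_um),
                          ...)
  dm$morphology$label
}

#' Precompute a surrogate label table
#'
#' Runs the full spatial + ratchet pipeline over a grid of (CP, seed count)
#' conditions at the reference vesicle geometry and stores the resulting
#' morphology labels. [run_ensemble()] in `"surrogate"` mode labels each
#' vesicle by nearest grid point, which makes desk-scale ensembles cheap.
#'
#' @param cp_grid CP concentrations, nM.
#' @param seeds_grid domain counts.
#' @param geometry reference [vesicle_geometry()] (radius variability is
#'   collapsed onto this reference in surrogate mode).
#' @param ... passed to [domain_morphology()].
#' @return A `surrogate_table` data.frame: `cp_nM`, `n_seeds`, `label`.
#' @export
build_surrogate <- function(cp_grid = c(40, 60, 80, 120),
                            seeds_grid = c(1, 2, 4, 8),
                            geometry = vesicle_geometry(), ...) {
  grid <- expand.grid(cp_nM = cp_grid, n_seeds = seeds_grid)
  grid$label <- vapply(seq_len(nrow(grid)), function(i) {
    dm <- domain_morphology(grid$cp_nM[i], n_domains = grid$n_seeds[i],
                            geometry = geometry, ...)
    dm$morphology$label
  }, character(1))
  structure(grid, class = c("surrogate_table", "data.frame"))
}

#' Run (or look up) the morphology outcome of a vesicle ensemble
#'
#' Assigns exactly one morphology label to every vesicle: vesicles whose
#' actual CP exceeds `volume_cp_nM` form volume-spanning networks (capping
#' suppresses membrane growth so far that bulk nucleation wins); vesicles
#' whose seed count reaches `cortex_seed_threshold` are densely packed with
#' domains and form a closed cortex; vesicles without any seed stay bare
#' (flat); the rest are labelled by the single-domain pipeline with the
#' vesicle's pools shared across its `n_seeds` domains, either by a full
#' spatial simulation per vesicle or by lookup in a precomputed
#' [build_surrogate()] table.
#'
#' @param specs a [sample_vesicles()] data.frame.
#' @param mode `"surrogate"` (requires `surrogate`) or `"full_spatial"`.
#' @param surrogate a [build_surrogate()] table.
#' @param cortex_seed_threshold seed count at which domains pack into a
#'   cortex (default 12).
#' @param volume_cp_nM CP (nM) above which volume-spanning networks dominate
#'   (default 150, between the studied 120 and 180 nM extremes).
#' @param ... passed to [domain_morphology()] in full-spatial mode.
#' @return A `morphology_stats` object: the specs with a `label` column,
#'   per-condition count table, and the number of failed simulations
#'   (excluded from fractions).
#' @export
run_ensemble <- function(specs, mode = c("surrogate", "full_spatial"),
                         surrogate = NULL, cortex_seed_threshold = 12,
                         volume_cp_nM = 150, ...) {
  stopifnot(inherits(specs, "vesicle_specs") || is.data.frame(specs))
  mode <- match.arg(mode)
  if (mode == "surrogate" && is.null(surrogate))
    stop("run_ensemble: surrogate mode needs a build_surrogate() table",
         call. = FALSE)
  labels <- rep(NA_character_, nrow(specs))
  for (i in seq_len(nrow(specs))) {
    labels[i] <- tryCatch(
      .label_one_vesicle(specs$cp_actual_nM[i], specs$n_seeds[i],
                         specs$radius_um[i], mode, surrogate,
                         cortex_seed_threshold, volume_cp_nM, ...),
      error = function(e) NA_character_)
  }
  specs$label <- labels
  ok <- !is.na(labels)
  counts <- table(condition_nM = specs$cp_nominal_nM[ok],
                  label = factor(labels[ok], levels = .MORPH_LABELS))
  structure(list(specs = specs, counts = counts, n_failed = sum(!ok),
                 mode = mode),
            class = "morphology_stats")
}

#' @export
print.morphology_stats <- function(x, ...) {
  cat(sprintf("morphology_stats: %d vesicles (%s mode), %d failed\n",
              nrow(x$specs), x$mode, x$n_failed))
  print(x$counts)
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x successes.
#' @param n trials (> 0).
#' @param conf confidence level (default 0.95).
#' @return Named vector `c(lower, upper)` (vectorized over `x`, `n`).
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (any(n <= 0)) stop("wilson_ci: n must be > 0", call. = FALSE)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  cbind(lower = pmax(centre - half, 0), upper = pmin(centre + half, 1))
}

#' Summarize ensemble morphology fractions
#'
#' Tidy per-condition morphology fractions with Wilson confidence intervals.
#'
#' @param stats a [run_ensemble()] result.
#' @param conf confidence level for the Wilson intervals.
#' @return A data.frame: `condition_nM`, `label`, `count`, `total`,
#'   `fraction`, `ci_lower`, `ci_upper`.
#' @export
summarize_morphology <- function(stats, conf = 0.95) {
  stopifnot(inherits(stats, "morphology_stats"))
  counts <- stats$counts
  if (!length(counts) || sum(counts) == 0)
    stop("summarize_morphology: empty ensemble", call. = FALSE)
  df <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(df) <- c("condition_nM", "label", "count")
  totals <- tapply(df$count, df$condition_nM, sum)
  df$total <- as.integer(totals[as.character(df$condition_nM)])
  df$fraction <- df$count / df$total
  ci <- wilson_ci(df$count, df$total, conf)
  df$ci_lower <- ci[, "lower"]
  df$ci_upper <- ci[, "upper"]
  df$condition_nM <- as.numeric(as.character(df$condition_nM))
  df[order(df$condition_nM), ]
}
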