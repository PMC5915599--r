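## Reaction network construction: species, stoichiometry and rate laws for the
## membrane-localized (finite/infinite reservoir) and solution-mode systems.

.SPECIES <- c("G", "P", "Arp", "CPf", "VCAf", "VCAg", "VCAs",
              "Astar", "B", "Bcap", "Aused")

.REACTIONS <- c("vca_g_binding", "arp_activation", "seeding", "branching",
                "elongation", "capping", "vca_regeneration")

#' Build the branching/capping reaction network
#'
#' Assembles the seven-reaction network of membrane-localized dendritic actin
#' assembly: VCA + G -> VCA.G; VCA.G + Arp -> Arp* (+ spent VCA); Arp* -> B
#' (seeding); Arp* + B -> 2B (branching, monomer-dependent); barbed-end
#' elongation consuming G at `k_elong * (G - c_crit) * B`; B + CP -> B_capped;
#' and slow VCA regeneration. Species are split between bulk concentrations
#' (uM: `G`, `P`, `Arp`, `CPf`) and membrane areal densities (um^-2: `VCAf`,
#' `VCAg`, `VCAs`, `Astar`, `B`, `Bcap`), coupled through the vesicle
#' area-to-volume ratio. `Aused` is a bookkeeping accumulator of Arp2/3*
#' consumed into branches, used by the conservation checks.
#'
#' @param params a [rate_params()] object.
#' @param geometry a [vesicle_geometry()] object (ignored in solution mode,
#'   where every species is volumetric and the conversion factor is 1).
#' @param reservoir_mode `"finite"` (bulk pools deplete), `"infinite"` (bulk
#'   `G`, `CPf`, `Arp` held constant), or `"solution"` (bulk-assay mode: VCA is
#'   a bulk species, everything in uM).
#' @return An object of class `reaction_network`: species table with units,
#'   stoichiometry matrix `S` (species x reactions), rate-law closure, matter
#'   matrix for conservation accounting, and the conversion factor.
#' @export
#' @examples
#' net <- build_network(rate_params(), vesicle_geometry(), "infinite")
#' net$S[, "branching"]
build_network <- function(params = rate_params(),
                          geometry = vesicle_geometry(),
                          reservoir_mode = c("finite", "infinite", "solution")) {
  if (!inherits(params, "rate_params")) params <- do.call(rate_params, params)
  reservoir_mode <- match.arg(reservoir_mode)
  if (!inherits(geometry, "vesicle_geometry"))
    stop("build_network: 'geometry' must be a vesicle_geometry object",
         call. = FALSE)

  conv <- if (reservoir_mode == "solution") 1 else geometry$conv_uM_per_um2
  bulk <- c("G", "P", "Arp", "CPf")
  units <- setNames(rep("um^-2", length(.SPECIES)), .SPECIES)
  units[bulk] <- "uM"
  if (reservoir_mode == "solution") units[] <- "uM"

  S <- matrix(0, nrow = length(.SPECIES), ncol = length(.REACTIONS),
              dimnames = list(.SPECIES, .REACTIONS))
  S["G", "vca_g_binding"] <- -conv
  S["VCAf", "vca_g_binding"] <- -1
  S["VCAg", "vca_g_binding"] <- 1
  # activation hands the VCA-bound monomer to the nascent nucleus (counted in P)
  S["Arp", "arp_activation"] <- -conv
  S["VCAg", "arp_activation"] <- -1
  S["VCAs", "arp_activation"] <- 1
  S["Astar", "arp_activation"] <- 1
  S["P", "arp_activation"] <- conv
  S["Astar", "seeding"] <- -1
  S["B", "seeding"] <- 1
  S["Aused", "seeding"] <- 1
  S["Astar", "branching"] <- -1
  S["B", "branching"] <- 1
  S["Aused", "branching"] <- 1
  S["G", "elongation"] <- -conv
  S["P", "elongation"] <- conv
  S["CPf", "capping"] <- -conv
  S["B", "capping"] <- -1
  S["Bcap", "capping"] <- 1
  S["VCAs", "vca_regeneration"] <- -1
  S["VCAf", "vca_regeneration"] <- 1

  if (reservoir_mode == "infinite")
    S[c("G", "Arp", "CPf"), ] <- 0

  # actin / CP / VCA / Arp content of each species, in bulk-concentration
  # equivalents; columns of t(matter) %*% S are zero for conserved moieties
  matter <- matrix(0, nrow = length(.SPECIES), ncol = 4,
                   dimnames = list(.SPECIES, c("actin", "cp", "vca", "arp")))
  matter[c("G", "P"), "actin"] <- 1
  matter["VCAg", "actin"] <- conv
  matter["CPf", "cp"] <- 1
  matter["Bcap", "cp"] <- conv
  matter[c("VCAf", "VCAg", "VCAs"), "vca"] <- conv
  matter["Arp", "arp"] <- 1
  matter[c("Astar", "Aused"), "arp"] <- conv
  if (reservoir_mode == "solution") {
    matter["VCAg", "actin"] <- 1
    matter["Bcap", "cp"] <- 1
    matter[c("VCAf", "VCAg", "VCAs"), "vca"] <- 1
    matter[c("Astar", "Aused"), "arp"] <- 1
  }

  p <- params
  solution <- reservoir_mode == "solution"
  kb <- if (solution) p$k_branch_bulk else p$k_branch
  rate_fn <- function(y) {
    y <- pmax(y, 0)
    gd <- max(y[["G"]] - p$c_crit, 0)
    r5 <- p$k_elong * (y[["G"]] - p$c_crit) * y[["B"]]
    if (y[["P"]] <= 0) r5 <- max(r5, 0)  # no depolymerization without filaments
    # membrane: branches form where nascent mother filaments concentrate,
    # proxied by the barbed-end density; solution: mothers are bulk F-actin
    # (polymer excluding monomers still held in unbranched Arp2/3* nuclei)
    mother <- if (solution) max(y[["P"]] - y[["Astar"]], 0) else y[["B"]]
    c(vca_g_binding = p$k_bind_VG * y[["G"]] * y[["VCAf"]],
      arp_activation = p$k_act * y[["Arp"]] * y[["VCAg"]],
      seeding = p$k_seed * y[["Astar"]],
      branching = kb * gd * y[["Astar"]] * mother,
      elongation = r5,
      capping = p$k_cap * y[["CPf"]] * y[["B"]],
      vca_regeneration = p$k_regen * y[["VCAs"]])
  }

  structure(list(params = p, geometry = geometry,
                 reservoir_mode = reservoir_mode,
                 species = .SPECIES, units = units, bulk_species = bulk,
                 S = S, matter = matter, conv = conv, rate_fn = rate_fn),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Branched actin reaction network (%s reservoir)\n", x$reservoir_mode))
  cat(sprintf("  %d species, %d reactions; bulk<->membrane conversion %.4g uM per um^-2\n",
              length(x$species), length(.REACTIONS), x$conv))
  invisible(x)
}

#' Initial pool state
#'
#' Builds the initial state for [integrate_wellmixed()]: all VCA membrane-bound
#' and free, all Arp2/3 inactive in the bulk, monomer pool in solution, no
#' barbed ends unless `B0` is given. In membrane modes the VCA amount is the
#' encapsulated bulk concentration spread over the vesicle membrane; in
#' solution mode VCA stays volumetric.
#'
#' @param network a [build_network()] object.
#' @param actin_uM total actin, uM (default 3, the study's concentration).
#' @param vca_uM total VCA, uM (default 0.3).
#' @param arp_uM total Arp2/3 complex, uM (default 0.3).
#' @param cp_nM total capping protein, nM (the experimental dial, 20-180).
#' @param B0 initial free barbed-end density (um^-2, or uM in solution mode).
#' @return Named state vector over the network species.
#' @export
initial_pool <- function(network, actin_uM = 3, vca_uM = 0.3, arp_uM = 0.3,
                         cp_nM = 80, B0 = 0) {
  stopifnot(inherits(network, "reaction_network"))
  if (min(actin_uM, vca_uM, arp_uM, cp_nM, B0) < 0)
    stop("initial_pool: concentrations must be >= 0", call. = FALSE)
  vca0 <- if (network$reservoir_mode == "solution") vca_uM
          else vca_uM / network$conv
  y <- setNames(numeric(length(network$species)), network$species)
  y["G"] <- actin_uM
  y["Arp"] <- arp_uM
  y["CPf"] <- cp_nM * 1e-3
  y["VCAf"] <- vca0
  y["B"] <- B0
  y
}

#' Conserved-moiety totals of a state
#'
#' Returns the actin, CP, VCA and Arp2/3 totals (in bulk-concentration
#' equivalents, uM) implied by a state vector; used by the conservation
#' invariant checks.
#'
#' @param network a [build_network()] object.
#' @param y named state vector.
#' @return Named numeric vector `c(actin, cp, vca, arp)` in uM equivalents.
#' @export
pool_totals <- function(network, y) {
  drop(crossprod(network$matter, y[network$species]))
}
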