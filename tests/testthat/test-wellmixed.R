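test_that("finite-pool trajectories close all conservation laws", {
  for (cp in c(40, 120)) {
    tr <- std_wellmixed(cp)
    expect_lt(conservation_error(tr), 1e-6)
    expect_true(all(as.matrix(tr$states) >= 0))
  }
})

test_that("without actin nothing polymerizes and no ends form", {
  net <- build_network(rate_params(), vesicle_geometry(), "finite")
  tr <- integrate_wellmixed(net, initial_pool(net, actin_uM = 0, cp_nM = 80),
                            seq(0, 100, 1))
  expect_true(all(tr$states$B == 0))
  expect_true(all(tr$states$P == 0))
})

test_that("without capping the monomer pool is consumed to c_crit", {
  p <- rate_params()
  geo <- vesicle_geometry()
  net <- build_network(p, geo, "finite")
  tr <- integrate_wellmixed(net, initial_pool(net, cp_nM = 0),
                            seq(0, 1500, 2))
  expect_true(all(diff(tr$states$B) >= -1e-9))  # no capping sink
  # final polymer: total actin minus the critical concentration minus the
  # monomers locked in membrane VCA.G complexes (all VCA ends G-loaded when
  # the Arp2/3 pool is exhausted)
  vca_locked <- tail(tr$states$VCAg, 1) * geo$conv_uM_per_um2
  expect_equal(tail(tr$states$P, 1), 3 - p$c_crit - vca_locked,
               tolerance = 1e-3)
  expect_equal(tail(tr$states$G, 1), p$c_crit, tolerance = 1e-2)
})

test_that("steady-state barbed ends fall and Arp2/3* rises with CP", {
  net <- build_network(rate_params(), vesicle_geometry(), "infinite")
  cps <- c(40, 60, 80, 100, 120)
  ss <- vapply(cps, function(cp)
    steady_state(net, initial_pool(net, cp_nM = cp))[c("B", "Astar")],
    numeric(2))
  expect_true(all(diff(ss["B", ]) < 0))
  expect_true(all(diff(ss["Astar", ]) > 0))
})

test_that("closed-form fixed point matches the long-time integration", {
  net <- build_network(rate_params(), vesicle_geometry(), "infinite")
  for (cp in c(40, 120)) {
    init <- initial_pool(net, cp_nM = cp)
    ss <- steady_state(net, init)
    # 10x the slowest timescale (VCA regeneration, 1/k_regen = 25 s, and the
    # capping relaxation 1/(k_cap CP)): 600 s is ample
    tr <- integrate_wellmixed(net, init, seq(0, 600, 1))
    fin <- tr$states[nrow(tr$states), ]
    for (spn in c("B", "Astar", "VCAf", "VCAg", "VCAs"))
      expect_equal(fin[[spn]], ss[[spn]], tolerance = 1e-4,
                   label = sprintf("%s at %d nM", spn, cp))
  }
})

test_that("the barbed-end subsystem is absorbing without a seeding path", {
  net <- build_network(rate_params(k_seed = 0), vesicle_geometry(), "infinite")
  init <- initial_pool(net, cp_nM = 80)
  expect_warning(ss <- steady_state(net, init), "absorbing")
  expect_identical(ss[["B"]], 0)
  # and the dynamics agree: B stays at zero
  tr <- integrate_wellmixed(net, init, seq(0, 50, 1))
  expect_true(all(tr$states$B == 0))
})

test_that("steady state requires the infinite reservoir and capping", {
  netf <- build_network(rate_params(), vesicle_geometry(), "finite")
  expect_error(steady_state(netf, initial_pool(netf)), "infinite")
  neti <- build_network(rate_params(), vesicle_geometry(), "infinite")
  expect_error(steady_state(neti, initial_pool(neti, cp_nM = 0)),
               "unbounded")
})

test_that("seeding is delayed by CP: time to 5% of peak grows with CP", {
  lag5 <- vapply(c(40, 60, 80, 100, 120), function(cp) {
    tr <- std_wellmixed(cp)
    B <- tr$states$B
    tr$times[which(B >= 0.05 * max(B))[1]]
  }, numeric(1))
  expect_true(all(diff(lag5) > 0))
})

test_that("finite pools produce a transient barbed-end maximum", {
  for (cp in c(40, 80, 120)) {
    tr <- std_wellmixed(cp)
    B <- tr$states$B
    expect_lt(which.max(B), length(B))
    expect_gt(max(B), 1.05 * tail(B, 1))
  }
})

test_that("growth phases are ordered on every simulated trajectory", {
  for (cp in c(40, 80, 120)) {
    ph <- detect_phases(std_wellmixed(cp))
    expect_lte(0, ph$t_seed_end)
    expect_lte(ph$t_seed_end, ph$t_initial_end)
    if (ph$steady_reached) expect_lte(ph$t_initial_end, ph$t_transient_end)
  }
})

test_that("phase detection recovers known breakpoints of synthetic curves", {
  # saturating exponential: maximal growth rate at the origin, so the rapid
  # phase ends as soon as seeding does
  t <- seq(0, 50, 0.1)
  tau <- 5
  sat <- list(times = t, states = data.frame(B = 100 * (1 - exp(-t / tau))))
  ph <- detect_phases(sat)
  t_seed_expected <- -tau * log(1 - 0.01 * max(sat$states$B) / 100)
  expect_lt(abs(ph$t_seed_end - t_seed_expected), 0.11)
  expect_lt(abs(ph$t_initial_end - ph$t_seed_end), 0.11)
  expect_true(ph$steady_reached)

  # piecewise-linear curve with slopes 0.5 / 2 / 0.1 / 0 and breakpoints at
  # 10, 20, 30: seeding ends when B crosses 1% of max, the rapid phase is the
  # steep segment, the transient ends at the final plateau
  t2 <- seq(0, 40, 0.25)
  B2 <- approx(c(0, 10, 20, 30, 40), c(0, 5, 25, 28, 28), xout = t2)$y
  ph2 <- detect_phases(list(times = t2, states = data.frame(B = B2)))
  expect_lt(abs(ph2$t_seed_end - 0.01 * 28 / 0.5), 0.26)
  expect_lt(abs(ph2$t_initial_end - 10), 0.26)
  expect_lt(abs(ph2$t_transient_end - 30), 0.26)
})

test_that("degenerate trajectories are rejected by phase detection", {
  expect_error(detect_phases(list(times = c(0, 1, 2),
                                  states = data.frame(B = c(0, 0, 0)))),
               "no barbed ends")
})
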