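test_that("annular grids tile the patch exactly", {
  g <- radial_grid(2.5, 80)
  expect_equal(sum(g$area), pi * 2.5^2)
  expect_true(all(diff(g$r) > 0))
  expect_error(radial_grid(n_cells = 16), ">= 32")
})

test_that("without spreading mobility barbed ends stay in the seed disc", {
  sp <- spatial_params(alpha_spread = 1e-8)
  tr <- simulate_domain(80, n_domains = 1, sp = sp,
                        grid = radial_grid(n_cells = 64), t_end = 60)
  outside <- tr$grid$r > sp$seed_radius_um + 3 * tr$grid$dr
  expect_lt(max(tr$fields$B[, outside]), 1e-12)
})

test_that("without monomer there is no growth and no spreading", {
  tr <- simulate_domain(80, n_domains = 1, grid = radial_grid(n_cells = 64),
                        t_end = 60, actin_uM = 0)
  ib <- integrated_barbed_ends(tr)
  expect_true(all(diff(ib) <= 1e-9))        # capping is the only sink
  outside <- tr$grid$r > tr$sp$seed_radius_um + 3 * tr$grid$dr
  expect_equal(max(tr$fields$B[, outside]), 0)  # v_pol = 0 => D_B = 0
})

test_that("global conservation closes for the calibrated runs", {
  for (cp in c(40, 80, 120)) {
    tr <- std_domain(cp)
    expect_lt(spatial_conservation_error(tr), 1e-5)
  }
})

test_that("bulk pools only deplete once growth starts", {
  tr <- std_domain(40)
  expect_true(all(diff(tr$bulk$G) <= 1e-9))
  expect_true(all(diff(tr$bulk$CPf) <= 1e-9))
})

test_that("every CP condition shows a transient peak of total barbed ends", {
  for (cp in c(40, 80, 120)) {
    ib <- integrated_barbed_ends(std_domain(cp))
    expect_lt(which.max(ib), length(ib))
    expect_gt(max(ib), 1.05 * tail(ib, 1))
  }
})

test_that("the solution self-converges under grid refinement", {
  a <- std_domain(40, n_cells = 96)
  b <- std_domain(40, n_cells = 128)
  ia <- integrated_barbed_ends(a)
  ib <- integrated_barbed_ends(b)
  expect_lt(max(abs(ia - ib)) / max(ib), 0.01)
  ra <- attr(classify_pattern(a), "max_ratio")
  rb <- attr(classify_pattern(b), "max_ratio")
  expect_lt(abs(ra - rb) / rb, 0.01)
})

test_that("domain competition splits pool amounts, not concentrations", {
  pool <- bulk_pool(actin_uM = 3, cp_nM = 120)
  half <- domain_competition(pool, 2)
  expect_equal(half$conc, pool$conc)                    # concentrations kept
  expect_equal(pool_amounts(half), pool_amounts(pool) / 2)  # amounts halved
  expect_identical(domain_competition(pool, 1), pool)
  expect_error(domain_competition(pool, 0), ">= 1")
})

test_that("more competing domains leave fewer ends per domain", {
  fin <- vapply(c(1, 4, 10), function(N) {
    tr <- simulate_domain(80, n_domains = N, grid = radial_grid(n_cells = 64),
                          t_end = 160)
    tail(integrated_barbed_ends(tr), 1)
  }, numeric(1))
  expect_true(all(diff(fin) < 0))
})

test_that("profile classification handles the canonical shapes", {
  r <- seq(0.05, 2.95, length.out = 64)
  const <- structure(list(radii = r, density = rep(5, 64), time = 0),
                     class = "radial_profile")
  expect_identical(as.character(classify_profile(const)), "flat")
  expect_equal(attr(classify_profile(const), "rim_center_ratio"), 1)

  ring <- structure(list(radii = r, density = ifelse(r > 2, 10, 0), time = 0),
                    class = "radial_profile")
  expect_identical(as.character(classify_profile(ring)), "double_peaked")
  expect_gt(attr(classify_profile(ring), "rim_center_ratio"), 10)

  zero <- structure(list(radii = r, density = rep(0, 64), time = 0),
                    class = "radial_profile")
  expect_error(classify_profile(zero), "all-zero")
})

test_that("flatness time behaves on constructed trajectories", {
  # uniformly occupied from the start: flat at the first output time
  flat_tr <- synthetic_spatial(function(r, t) rep(3, length(r)))
  expect_equal(flatness_time(flat_tr), 0)

  # permanent ring: the disc inside the occupied radius contains the empty
  # centre, so the region never becomes uniform
  ring_tr <- synthetic_spatial(function(r, t) ifelse(r > 2, 10, 0))
  expect_true(is.na(flatness_time(ring_tr)))

  # domain that never spreads past half the patch
  blob_tr <- synthetic_spatial(function(r, t) ifelse(r < 0.5, 10, 0))
  expect_error(flatness_time(blob_tr), "never spreads")
})

test_that("negative densities beyond tolerance are rejected", {
  g <- radial_grid(n_cells = 64)
  init <- initial_field(g, cp_nM = 80)
  init$fields$B[1] <- -1
  expect_error(integrate_spatial(spatial_params(), rate_params(), init, g,
                                 t_out = c(0, 1)))
})
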