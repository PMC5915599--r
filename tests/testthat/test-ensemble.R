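test_that("vesicle sampling is reproducible and validates its inputs", {
  a <- sample_vesicles(25, cp_nM = 60, master_seed = 42)
  b <- sample_vesicles(25, cp_nM = 60, master_seed = 42)
  expect_identical(a, b)
  d <- sample_vesicles(25, cp_nM = 60, master_seed = 43)
  expect_false(identical(a$cp_actual_nM, d$cp_actual_nM))
  expect_identical(nrow(sample_vesicles(0)), 0L)
  expect_error(sample_vesicles(-1), "n must be")
  expect_error(sample_vesicles(5, radius_range_um = c(25, 10)), "radius")
  expect_error(sample_vesicles(5, lambda_fn = function(cp) -cp), "lambda")
})

test_that("sampled radii follow the encapsulation distribution", {
  sv <- sample_vesicles(10000, cp_nM = 80, master_seed = 11)
  ks <- suppressWarnings(ks.test(sv$radius_um, "punif", 10, 25))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(sv$radius_um >= 10 & sv$radius_um <= 25))
  expect_true(all(sv$cp_actual_nM > 0))
  expect_true(all(sv$n_seeds >= 0))
})

test_that("expected seed counts increase with CP", {
  expect_true(all(diff(lambda_seeds(c(20, 40, 80, 120, 180))) >= 0))
  means <- vapply(c(40, 80, 120), function(cp)
    mean(sample_vesicles(4000, cp_nM = cp, master_seed = 5)$n_seeds),
    numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("identical noise-free specs yield one identical label each", {
  specs <- structure(data.frame(vesicle = 1:6, cp_nominal_nM = 60,
                                radius_um = 15, cp_actual_nM = 60,
                                n_seeds = 2, rng_seed = 1:6),
                     class = c("vesicle_specs", "data.frame"))
  surr <- data.frame(cp_nM = 60, n_seeds = 2, label = "concave")
  st <- run_ensemble(specs, "surrogate", surr)
  expect_true(all(st$specs$label == "concave"))
  expect_identical(st$n_failed, 0L)
})

test_that("rule-based labels capture the packing and volume regimes", {
  specs <- structure(data.frame(vesicle = 1:3, cp_nominal_nM = c(120, 120, 160),
                                radius_um = 15, cp_actual_nM = c(120, 120, 160),
                                n_seeds = c(20, 0, 2), rng_seed = 1:3),
                     class = c("vesicle_specs", "data.frame"))
  surr <- data.frame(cp_nM = 120, n_seeds = 2, label = "concave")
  st <- run_ensemble(specs, "surrogate", surr)
  expect_identical(st$specs$label, c("cortex", "flat", "volume_network"))
})

test_that("protrusions dominate at low CP and vanish at high CP", {
  surr <- std_surrogate()
  fr <- vapply(c(40, 60, 120), function(cp) {
    sv <- sample_vesicles(60, cp_nM = cp, master_seed = 100 + cp)
    st <- run_ensemble(sv, "surrogate", surr)
    s <- summarize_morphology(st)
    s$fraction[s$label == "protrusion"]
  }, numeric(1))
  expect_gt(fr[1], fr[2])
  expect_gt(fr[2], fr[3])
  expect_gt(fr[1], 0.5)
})

test_that("protrusion vesicles carry fewer nucleation seeds", {
  surr <- std_surrogate()
  specs <- do.call(rbind, lapply(c(40, 60, 120), function(cp)
    sample_vesicles(60, cp_nM = cp, master_seed = 100 + cp)))
  class(specs) <- c("vesicle_specs", "data.frame")
  st <- run_ensemble(specs, "surrogate", surr)
  lab <- st$specs
  expect_true(all(!is.na(lab$label)))  # exclusivity: one label per vesicle
  m <- tapply(lab$n_seeds, lab$label, mean)
  expect_lt(m[["protrusion"]], m[["concave"]])
  expect_lt(m[["protrusion"]], m[["flat"]])
})

test_that("full-spatial labelling agrees with the surrogate at a grid point", {
  specs <- structure(data.frame(vesicle = 1L, cp_nominal_nM = 40,
                                radius_um = 10, cp_actual_nM = 40,
                                n_seeds = 1L, rng_seed = 1L),
                     class = c("vesicle_specs", "data.frame"))
  st <- run_ensemble(specs, "full_spatial",
                     grid = radial_grid(n_cells = 96), t_end = 160)
  expect_identical(st$specs$label, "protrusion")
})

test_that("morphology summaries report Wilson intervals correctly", {
  specs <- structure(data.frame(vesicle = 1:10, cp_nominal_nM = 40,
                                radius_um = 12, cp_actual_nM = 40,
                                n_seeds = 0, rng_seed = 1:10),
                     class = c("vesicle_specs", "data.frame"))
  specs$n_seeds <- 20  # all cortex
  st <- run_ensemble(specs, "surrogate",
                     data.frame(cp_nM = 40, n_seeds = 1, label = "flat"))
  s <- summarize_morphology(st)
  cortex <- s[s$label == "cortex", ]
  expect_equal(cortex$fraction, 1)
  expect_equal(cortex$ci_upper, 1)
  expect_lt(cortex$ci_lower, 1)
  # fractions mirror raw counts
  expect_equal(sum(s$fraction), 1)
})

test_that("Wilson intervals achieve nominal coverage on average (n = 20)", {
  # exact enumeration oracle: coverage of the interval under the true binomial
  ps <- seq(0.05, 0.95, 0.01)
  cov <- vapply(ps, function(p) {
    x <- 0:20
    ci <- wilson_ci(x, 20)
    sum(dbinom(x, 20, p)[ci[, "lower"] <= p & p <= ci[, "upper"]])
  }, numeric(1))
  expect_lt(abs(mean(cov) - 0.95), 0.01)
  expect_error(wilson_ci(1, 0), "n must be")
})
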