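test_that("the ratchet velocity law obeys its closed form and limits", {
  p <- ratchet_params()
  expect_equal(protrusion_velocity(0, p), 0)
  expect_equal(protrusion_velocity(1e12, p), p$v_free_nm_s, tolerance = 1e-9)
  # density at which the exponent equals ln 2 gives exactly half speed
  B_half <- p$F_mem * p$delta_nm * 1e-3 / (log(2) * p$kBT_pN_nm * 1e-3)
  expect_equal(protrusion_velocity(B_half, p), p$v_free_nm_s / 2)
  # strictly increasing and bounded by the unloaded speed
  B <- seq(1, 450, length.out = 200)
  v <- protrusion_velocity(B, p)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < p$v_free_nm_s))
  expect_error(protrusion_velocity(-1, p), ">= 0")
})

test_that("velocity profiles preserve density ordering and scaling law", {
  p <- ratchet_params()
  r <- seq(0.05, 2.95, length.out = 40)
  d <- 30 + 100 * r  # rim-heavy
  prof <- structure(list(radii = r, density = d, time = 0),
                    class = "radial_profile")
  vp <- velocity_profile(prof, p)
  expect_true(all(diff(vp$v) > 0))  # monotone map keeps the ordering
  # doubling the density everywhere halves the exponent pointwise
  prof2 <- prof; prof2$density <- 2 * d
  vp2 <- velocity_profile(prof2, p)
  x <- p$F_mem * p$delta_nm / (d * p$kBT_pN_nm)
  expect_equal(vp2$v / vp$v, exp(-x / 2) / exp(-x), tolerance = 1e-12)
})

test_that("velocity profiles map to the three deformation modes", {
  p <- ratchet_params()
  r <- seq(0.05, 2.95, length.out = 64)
  mk <- function(d) velocity_profile(
    structure(list(radii = r, density = d, time = 0),
              class = "radial_profile"), p)
  # uniform high density: homogeneous growth pushes a protrusion
  uni <- classify_morphology(mk(rep(250, 64)))
  expect_identical(uni$label, "protrusion")
  expect_lt(uni$rim_center_ratio, 1.5)
  # rim-peaked density: the rim outruns the centre, bending concavely
  rim <- classify_morphology(mk(ifelse(r > 2.2, 300, 60)))
  expect_identical(rim$label, "concave")
  expect_gt(rim$rim_center_ratio, 1.5)
  # near-zero density: nothing pushes
  expect_identical(classify_morphology(mk(rep(2, 64)))$label, "flat")
  # classification is invariant under uniform rescaling of radii
  rim10 <- mk(ifelse(r > 2.2, 300, 60))
  rim10$radii <- rim10$radii * 10
  expect_identical(classify_morphology(rim10)$label, "concave")
})

test_that("the displaced front reports centre curvature signs", {
  p <- ratchet_params()
  r <- seq(0.05, 2.95, length.out = 64)
  mk <- function(d) velocity_profile(
    structure(list(radii = r, density = d, time = 0),
              class = "radial_profile"), p)
  fs_flat <- front_shape(mk(rep(100, 64)), 10)
  expect_identical(fs_flat$center_curvature_sign, 0L)
  expect_equal(fs_flat$displacement,
               rep(protrusion_velocity(100, p) * 10, 64))
  # rim-dominant: centre left behind, concave (negative) front curvature
  fs_rim <- front_shape(mk(30 + 150 * r), 10)
  expect_identical(fs_rim$center_curvature_sign, -1L)
  # velocity linear in r: displacement linear, curvature below grid tolerance
  vp_lin <- mk(rep(1, 64)); vp_lin$v <- 5 + 2 * r
  fs_lin <- front_shape(vp_lin, 8)
  expect_equal(fs_lin$displacement, (5 + 2 * r) * 8)
  expect_identical(fs_lin$center_curvature_sign, 0L)
  expect_error(front_shape(vp_lin, 0), "> 0")
})

test_that("the mechanical floor is the 10%-speed density", {
  p <- ratchet_params()
  expect_equal(protrusion_velocity(mechanical_floor(p), p),
               0.1 * p$v_free_nm_s, tolerance = 1e-12)
})

test_that("calibrated runs map to the observed CP-dependent morphologies", {
  labels <- vapply(c(40, 80, 120), function(cp)
    domain_morphology(cp, traj = std_domain(cp))$morphology$label,
    character(1))
  expect_identical(labels, c("protrusion", "concave", "flat"))
})
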