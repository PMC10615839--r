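test_that("chord length matches the brute-force ray-sphere solver", {
  set.seed(42)
  for (i in 1:200) {
    r <- runif(1, 5, 15)
    a <- runif(1, 0, r * 0.999)
    al <- runif(1, 0, 89)
    g <- scan_geometry(r, a, 89.9)
    orc <- ray_sphere_oracle(r, a, al)
    expect_equal(chord_length(g, al), orc$chord_mm, tolerance = 1e-9)
    expect_equal(central_angle(g, al), orc$beta_half_deg, tolerance = 1e-9)
  }
})

test_that("chord length limits: central ray, centred pivot, monotonicity", {
  g <- scan_geometry(8.725, 6.125, 70)
  expect_equal(chord_length(g, 0), 8.725 + 6.125)
  g0 <- scan_geometry(8.725, 0, 70)
  expect_equal(chord_length(g0, c(0, 17, 55, 70)), rep(8.725, 4))
  al <- seq(0, 90, by = 0.5)
  expect_true(all(diff(chord_length(g, al)) <= 1e-12))
  # symmetric in the sign of alpha
  expect_equal(chord_length(g, -33), chord_length(g, 33))
})

test_that("central angle: pivot at centre, inscribed-angle doubling, monotone", {
  g0 <- scan_geometry(8.725, 0, 70)
  expect_equal(central_angle(g0, c(5, 40, 70)), c(5, 40, 70))
  gi <- scan_geometry(10, 10, 89)
  expect_equal(central_angle(gi, 45), 90)
  for (al in c(1, 10, 30, 60, 89))
    expect_equal(central_angle(gi, al), 2 * al, tolerance = 1e-9)
  g <- scan_geometry(8.725, 6.125, 70)
  al <- seq(1, 89, by = 1)
  expect_true(all(diff(central_angle(g, al)) > 0))
  # an anterior pivot always reaches beyond the centred-pivot baseline
  expect_true(all(central_angle(g, al) > al))
})

test_that("pivot angle solver inverts central_angle to 1e-9 degree", {
  set.seed(7)
  for (i in 1:50) {
    r <- runif(1, 6, 14)
    g <- scan_geometry(r, runif(1, 0, r * 0.99), 80)
    al <- runif(1, 0, 85)
    expect_equal(pivot_angle_for_central_angle(g, central_angle(g, al)), al,
                 tolerance = 1e-7)
  }
  g <- scan_geometry(12, 12, 80)
  expect_equal(pivot_angle_for_central_angle(g, 40), 20, tolerance = 1e-7)
  expect_equal(pivot_angle_for_central_angle(g, 0), 0)
  # the newborn geometry cannot reach the far side of the globe
  gn <- default_newborn_geometry()
  expect_error(pivot_angle_for_central_angle(gn, 179.9), "unreachable")
})

test_that("required imaging depth is zero for a centred pivot and grows with a and FOV", {
  expect_equal(unname(required_imaging_depth(scan_geometry(8.725, 0, 70))),
               c(0, 0))
  prev <- -1
  for (a in c(1, 3, 5, 6.125)) {
    d <- required_imaging_depth(scan_geometry(8.725, a, 70))[["geometric_mm"]]
    expect_gt(d, prev)
    prev <- d
  }
  prev <- -1
  for (am in c(10, 30, 50, 70)) {
    d <- required_imaging_depth(scan_geometry(8.725, 6.125, am))[["geometric_mm"]]
    expect_gt(d, prev)
    prev <- d
  }
  # grid-search oracle at the default geometry
  g <- scan_geometry(8.725, 6.125, 70, medium_index = 1.357)
  grid <- seq(0, 70, length.out = 20001)
  ref <- max(chord_length(g, 0) - chord_length(g, grid))
  d <- required_imaging_depth(g)
  expect_equal(d[["geometric_mm"]], ref, tolerance = 1e-10)
  expect_equal(d[["optical_mm"]], ref * 1.357, tolerance = 1e-10)
})

test_that("B-scan depth profile is symmetric and peaks at the required depth", {
  g <- scan_geometry(8.725, 6.125, 70, medium_index = 1.357)
  al <- seq(-70, 70, by = 0.5)
  prof <- bscan_depth_profile(g, al)
  expect_equal(prof, rev(prof))
  expect_equal(max(prof), required_imaging_depth(g)[["optical_mm"]])
  expect_equal(bscan_depth_profile(scan_geometry(8.725, 0, 70), al),
               rep(0, length(al)))
  expect_error(bscan_depth_profile(g, 80), "exceed")
})

test_that("vignetting limit: pivot on iris plane is unvignetted, centred pivot is arctangent", {
  g <- scan_geometry(8.725, 6.125, 70)
  expect_equal(vignetting_limit(g, 6.125, 3), 70)
  expect_equal(vignetting_limit(g, 2, 1e9), 70)
  g0 <- scan_geometry(8.725, 0, 70)
  expect_equal(vignetting_limit(g0, 6.125, 4), atan(4 / 6.125) * 180 / pi)
  expect_error(vignetting_limit(g, 6.125, -1), "positive")
})

test_that("phantom ring table maps central angles to verified pivot angles", {
  g <- default_newborn_geometry()
  rings <- phantom_ring_angles(12, 40, g)
  expect_equal(rings$central_angle_deg, rings$ring_index * 20)
  # forward check on the phantom geometry
  pg <- scan_geometry(12, g$pivot_offset_mm, g$pivot_half_angle_max_deg)
  expect_equal(central_angle(pg, rings$pivot_angle_deg),
               rings$central_angle_deg, tolerance = 1e-7)
  expect_true(length(attr(rings, "omitted_rings")) > 0)
  # pole ring is the identity
  r0 <- phantom_ring_angles(12, 40, g, include_pole = TRUE)
  expect_equal(r0$pivot_angle_deg[1], 0)
  # pivot on the phantom sphere halves the central angle
  gi <- scan_geometry(12, 12, 70)
  ri <- phantom_ring_angles(12, 40, gi)
  expect_equal(ri$pivot_angle_deg, ri$central_angle_deg / 2, tolerance = 1e-7)
  # unreachable interval leaves no rings
  none <- phantom_ring_angles(12, 500, g)
  expect_equal(nrow(none), 0)
})
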