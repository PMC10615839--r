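test_that("corneal apex is found at its configured depth", {
  sc <- narrow_scene(seed = 3, fov_deg = 10)
  pr <- tiny_protocol(nf = 48L, ns = 8L, nd = 512L)
  v <- generate_cornea_volume(sc, pr, reference_arm_position_mm = 0,
                              apex_opl_mm = 1.2)
  a <- detect_apex(v)
  expect_equal(a$depth_um, 1200, tolerance = v$depth_pixel_pitch_um)
  expect_equal(a$ascan, 24L, tolerance = 2)

  zero <- v
  zero$intensity[] <- 0
  zero$noise_floor <- 0
  expect_error(detect_apex(zero), "no corneal surface")
})

test_that("apex detection stays within two pixels under strong speckle", {
  sc_base <- narrow_scene(seed = 1, fov_deg = 10)
  pr <- tiny_protocol(nf = 48L, ns = 8L, nd = 512L)
  errs <- vapply(1:15, function(s) {
    sc <- narrow_scene(seed = s, fov_deg = 10,
                       speckle_mode = "multiplicative-exponential",
                       noise_floor = 0.01)  # ~20 dB below the surface band
    v <- generate_cornea_volume(sc, pr, 0, apex_opl_mm = 1.2)
    detect_apex(v)$depth_um - 1200
  }, numeric(1))
  expect_lt(max(abs(errs)), 2 * depth_pixel_pitch(pr))
})

test_that("foveal RPE depth is read at the designated A-scan and is local", {
  pr <- tiny_protocol(nf = 48L, ns = 16L, nd = 600L)
  sc <- narrow_scene(seed = 2, fov_deg = 10)
  v <- generate_retina_volume(sc, pr, fovea_opl_mm = 24, opl_factor = 1,
                              reference_arm_position_mm = 20)
  expect_equal(detect_fovea_rpe(v), 4000, tolerance = v$depth_pixel_pitch_um)
  # an off-axis lesion does not move the foveal reading
  scl <- narrow_scene(seed = 2, fov_deg = 10,
                      lesions = list(lesion(4, 0, 0.6, 0.5, 0.3)))
  vl <- generate_retina_volume(scl, pr, fovea_opl_mm = 24, opl_factor = 1,
                               reference_arm_position_mm = 20)
  expect_equal(detect_fovea_rpe(vl), detect_fovea_rpe(v),
               tolerance = v$depth_pixel_pitch_um / 2)
})

test_that("OPL assembles stage travel and in-image depths with fixed signs", {
  rec <- biometry_record(stage_cornea_mm = 0, stage_retina_mm = 23,
                         apex_depth_um = 500, fovea_depth_um = 1180)
  expect_equal(compute_opl(rec), 23.680)
  # in-image terms cancel when both surfaces sit at the same pixel
  rec2 <- biometry_record(5, 20, 700, 700, opl_factor = 2)
  expect_equal(compute_opl(rec2), 30)
  # degenerate record
  expect_error(compute_opl(biometry_record(5, 5, 700, 700)),
               "inconsistent")
})

test_that("axial length is OPL / n_avg and responds monotonically", {
  eye <- gullstrand_newborn()
  true_opl <- geometric_to_opl(17.45, eye)
  rec <- biometry_record(0, 23, 500, 500 + (true_opl - 23) * 1000)
  expect_equal(measure_axial_length(rec, eye), 17.45, tolerance = 1e-9)
  # the reported 22.14 mm eye, converted at the printed 3 d.p. index
  expect_equal(opl_to_geometric(30.04398, 1.357), 22.14, tolerance = 1e-6)
  # linear in OPL
  expect_equal(measure_axial_length(2 * true_opl, eye), 2 * 17.45,
               tolerance = 1e-9)
  opls <- seq(20, 33, by = 1)
  als <- vapply(opls, measure_axial_length, numeric(1))
  expect_true(all(diff(als) > 0))
  # decreasing in n_avg
  ns <- seq(1.30, 1.40, by = 0.01)
  als_n <- vapply(ns, function(n) opl_to_geometric(23.68, n), numeric(1))
  expect_true(all(diff(als_n) < 0))
})

test_that("noiseless pipeline recovers axial length within a depth pixel", {
  pitch_geo <- depth_pixel_pitch(scan_protocol(samples_per_ascan = 800L)) /
    1.357 / 1000
  for (al in c(16, 19.5, 24)) {
    pair <- simulate_biometry_pair(al, seed = 21)
    est <- measure_biometry_pair(pair)$axial_length_mm
    expect_lt(abs(est - al), pitch_geo)
  }
})

test_that("shifting both stage positions leaves the axial length unchanged", {
  p0 <- simulate_biometry_pair(18.2, seed = 13)
  p1 <- simulate_biometry_pair(18.2, seed = 13, stage_offset_mm = 7.3)
  expect_equal(measure_biometry_pair(p1)$axial_length_mm,
               measure_biometry_pair(p0)$axial_length_mm, tolerance = 1e-9)
})

test_that("recovery error grows with speckle level", {
  res <- al_recovery_experiment(true_al_grid_mm = 17.45,
                                noise_levels = c(0, 0.6), n_reps = 6,
                                seed = 31)
  expect_equal(nrow(res), 2)
  expect_gt(res$rmse_mm[res$noise_level == 0.6],
            res$rmse_mm[res$noise_level == 0])
  # monotone ordering of recovered lengths across a grid
  grid <- al_recovery_experiment(true_al_grid_mm = c(17, 18, 19),
                                 noise_levels = 0, seed = 33)
  expect_true(all(diff(grid$mean_estimate_mm) > 0))
})
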