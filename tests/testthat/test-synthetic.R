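test_that("identical scene, protocol and seed give bit-identical volumes", {
  pr <- tiny_protocol()
  sc <- narrow_scene(seed = 5, speckle_mode = "multiplicative-exponential",
                     noise_floor = 0.02)
  v1 <- generate_retina_volume(sc, pr)
  v2 <- generate_retina_volume(sc, pr)
  expect_identical(v1$intensity, v2$intensity)
  # a different seed changes the realisation
  sc2 <- narrow_scene(seed = 6, speckle_mode = "multiplicative-exponential",
                      noise_floor = 0.02)
  expect_false(identical(generate_retina_volume(sc2, pr)$intensity,
                         v1$intensity))
})

test_that("the generator leaves the global random state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_retina_volume(
    narrow_scene(seed = 9, speckle_mode = "multiplicative-exponential"),
    tiny_protocol()))
  expect_identical(.Random.seed, before)
})

test_that("a centred pivot renders a flat retina; otherwise the surface follows the chord profile", {
  eye <- gullstrand_newborn()
  g0 <- scan_geometry(8.725, 0, 10, average_refractive_index(eye))
  sc0 <- synthetic_scene(eye = eye, geom = g0, seed = 2)
  v0 <- generate_retina_volume(sc0, tiny_protocol())
  expect_lt(diff(range(v0$truth$surface_depth_um)), 1e-9)

  sc <- narrow_scene(seed = 2, fov_deg = 30)
  pr <- tiny_protocol(nf = 48L, ns = 3L, nd = 600L)
  v <- generate_retina_volume(sc, pr)
  mid <- 2L
  prof_um <- bscan_depth_profile(sc$geom, v$alpha_fast_deg) * 1000
  surf <- segment_surface(v, median_window = 1L)
  rendered <- surf$depth_um[mid, ]
  # retina referenced to the central A-scan must match the geometric profile
  expect_lt(max(abs((rendered[24] - rendered) - prof_um + prof_um[24])),
            v$depth_pixel_pitch_um)
})

test_that("multiplicative speckle preserves expected intensity", {
  pr <- tiny_protocol(nf = 128L, ns = 48L, nd = 400L)
  clean <- generate_retina_volume(narrow_scene(seed = 4), pr)
  spek <- generate_retina_volume(
    narrow_scene(seed = 4, speckle_mode = "multiplicative-exponential"), pr)
  on <- clean$intensity > 1e-4
  n <- sum(on)
  expect_gt(n, 5e4)
  ratio <- spek$intensity[on] / clean$intensity[on]
  # exponential(1) has unit mean and unit sd
  expect_lt(abs(mean(ratio) - 1), 3 / sqrt(n))
})

test_that("corneal apex depth tracks the reference arm exactly", {
  sc <- narrow_scene(seed = 3, fov_deg = 10)
  pr <- tiny_protocol(nf = 32L, ns = 8L, nd = 512L)
  v1 <- generate_cornea_volume(sc, pr, reference_arm_position_mm = -1,
                               apex_opl_mm = 0.5)
  v2 <- generate_cornea_volume(sc, pr, reference_arm_position_mm = -1.8,
                               apex_opl_mm = 0.5)
  expect_equal(v2$truth$apex_depth_um - v1$truth$apex_depth_um, 800)
  a1 <- detect_apex(v1)
  a2 <- detect_apex(v2)
  expect_equal(a2$depth_um - a1$depth_um, 800,
               tolerance = v1$depth_pixel_pitch_um)
  # double-pass stage doubles the shift
  v3 <- generate_cornea_volume(sc, pr, reference_arm_position_mm = -1.4,
                               opl_factor = 2, apex_opl_mm = 0.5)
  expect_equal(v3$truth$apex_depth_um, (0.5 + 2 * 1.4) * 1000)
  expect_identical(
    generate_cornea_volume(sc, pr, -1, apex_opl_mm = 0.5)$intensity,
    v1$intensity)
})

test_that("phantom volumes show every reachable ring in the en-face image", {
  g <- default_newborn_geometry()
  pr <- tiny_protocol(nf = 96L, ns = 96L, nd = 700L, depth_mm = 14)
  pv <- generate_phantom_volume(12, 40, 0.5, g, pr, seed = 4)
  rings <- pv$truth$rings
  expect_equal(nrow(rings), nrow(phantom_ring_angles(12, 40, g)))
  ef <- en_face_projection(pv, "max")
  mid <- 48L
  for (k in seq_len(nrow(rings))) {
    at <- which.min(abs(pv$alpha_fast_deg - rings$pivot_angle_deg[k]))
    off <- which.min(abs(pv$alpha_fast_deg -
                           (rings$pivot_angle_deg[k] + 7)))
    expect_gt(ef[mid, at], 1.5 * ef[mid, off])
  }
  # a ring interval beyond the reachable field leaves a blank phantom
  blank <- generate_phantom_volume(12, 500, 0.5, g, pr, seed = 4)
  expect_equal(nrow(blank$truth$rings), 0)
  expect_false(any(blank$truth$on_ring))
})

test_that("en-face projection reduces depth by mean or max", {
  pr <- tiny_protocol()
  v <- generate_retina_volume(narrow_scene(seed = 8), pr)
  em <- en_face_projection(v, "mean")
  ex <- en_face_projection(v, "max")
  expect_equal(dim(em), dim(v$intensity)[1:2])
  expect_true(all(ex >= em))
  expect_error(en_face_projection(v, "median"))
  const <- v
  const$intensity[] <- 2
  expect_true(all(en_face_projection(const, "mean") == 2))
  expect_true(all(en_face_projection(const, "max") == 2))
})

test_that("hill-climbing autofocus finds unimodal optima and boundary maxima", {
  hc <- autofocus_hill_climb(function(x) -(x - 3.2)^2, start = 0, step = 1,
                             lower = -10, upper = 10)
  expect_equal(hc$setting, 3.2, tolerance = 1e-2)
  # monotone metric runs to the boundary
  hb <- autofocus_hill_climb(function(x) x, start = 0, step = 1,
                             lower = -5, upper = 5)
  expect_equal(hb$setting, 5, tolerance = 1e-2)
  expect_error(autofocus_hill_climb(function(x) NaN, 0, 1), "non-finite")
})

test_that("autofocus on a synthetic defocus stack matches exhaustive search", {
  # en-face brightness of a defocus model: sharp peak at the true focus
  true_focus <- 1.7
  metric <- function(setting) {
    blur <- 1 + (setting - true_focus)^2
    # brightness falls as the spot blurs
    10 / blur + 0.5
  }
  grid <- seq(-5, 5, by = 0.001)
  best_grid <- grid[which.max(vapply(grid, metric, numeric(1)))]
  hc <- autofocus_hill_climb(metric, start = -4, step = 1.5,
                             lower = -5, upper = 5)
  expect_equal(hc$setting, best_grid, tolerance = 5e-3)
})

test_that("retina outside the depth window triggers a warning, mismatched scenes an error", {
  # full 140-degree field cannot fit a 6 mm optical window
  sc <- synthetic_scene(seed = 1)
  expect_warning(generate_retina_volume(sc, tiny_protocol(nf = 48L, ns = 24L)),
                 "depth window")
  expect_error(synthetic_scene(seed = 1, speckle_mode = "gaussian"))
  expect_error(synthetic_scene(), "seed")
  expect_error(lesion(10, 0, 1, 2, 0.5), "length_mm >= width_mm")
  expect_error(lesion(10, 0, 2, 1, -0.5), "positive")
})
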