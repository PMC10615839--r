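# Shared noiseless scene: three caps across the field on the newborn globe.
make_lesion_volume <- function(nf = 160L, ns = 160L, nd = 1000L,
                               lesions = list(lesion(20, 0, 6.37, 3.05, 1.41),
                                              lesion(60, 120, 5.2, 4.04, 1.08)),
                               seed = 3) {
  sc <- synthetic_scene(lesions = lesions, seed = seed)
  pr <- scan_protocol(n_ascans_per_bscan = nf, n_bscans = ns,
                      samples_per_ascan = nd, imaging_depth_mm = 12)
  generate_retina_volume(sc, pr)
}

test_that("surface segmentation matches the generator within one depth pixel", {
  sc <- narrow_scene(seed = 2, fov_deg = 30)
  pr <- tiny_protocol(nf = 64L, ns = 24L, nd = 600L)
  v <- generate_retina_volume(sc, pr)
  surf <- segment_surface(v, median_window = 1L)
  expect_true(all(surf$valid))
  expect_lt(max(abs(surf$depth_um - v$truth$surface_depth_um)),
            v$depth_pixel_pitch_um)
  # flat scene: constant map
  g0 <- scan_geometry(8.725, 0, 10, 1.357)
  v0 <- generate_retina_volume(synthetic_scene(geom = g0, seed = 1), pr)
  s0 <- segment_surface(v0)
  expect_lt(diff(range(s0$depth_um)), v0$depth_pixel_pitch_um)
  # an empty volume fails segmentation
  v$intensity[] <- 0
  expect_error(segment_surface(v), "segmentation failed")
})

test_that("scan conversion places a clean retina on the sphere and round-trips", {
  sc <- narrow_scene(seed = 2, fov_deg = 40)
  pr <- tiny_protocol(nf = 48L, ns = 24L, nd = 600L)
  v <- generate_retina_volume(sc, pr)
  surf <- segment_surface(v, median_window = 1L)
  pts <- scan_convert(surf)
  radii <- sqrt(pts$x^2 + pts$y^2 + pts$z^2)
  expect_lt(max(abs(radii - sc$geom$radius_mm)),
            v$depth_pixel_pitch_um / 1000 / 1.357 * 1.5)
  # centred pivot, zero elevation: all points exactly at radius r
  g0 <- scan_geometry(8.725, 0, 10, 1.357)
  v0 <- generate_retina_volume(synthetic_scene(geom = g0, seed = 1), pr)
  s0 <- segment_surface(v0, median_window = 1L)
  p0 <- scan_convert(s0)
  expect_lt(max(abs(sqrt(p0$x^2 + p0$y^2 + p0$z^2) - 8.725)),
            v0$depth_pixel_pitch_um / 1000)
  # inverse mapping round-trips to machine precision
  fc <- fan_coordinates(pts, surf$geom, surf$zero_delay_opl_mm)
  ns <- length(surf$alpha_slow_deg)
  AF <- rep(surf$alpha_fast_deg, each = ns)
  AS <- rep(surf$alpha_slow_deg, times = length(surf$alpha_fast_deg))
  expect_lt(max(abs(fc$alpha_fast_deg - AF)), 1e-9)
  expect_lt(max(abs(fc$alpha_slow_deg - AS)), 1e-9)
  expect_lt(max(abs(fc$depth_um - as.vector(surf$depth_um))), 1e-6)
})

test_that("sphere fitting is exact on clean spheres and robust to lesions and noise", {
  set.seed(9)
  u <- matrix(rnorm(3000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  ctr <- c(1, -2, 0.5)
  pts <- data.frame(x = 8.725 * u[, 1] + ctr[1],
                    y = 8.725 * u[, 2] + ctr[2],
                    z = 8.725 * u[, 3] + ctr[3])
  f <- fit_sphere(pts)
  expect_equal(f$radius, 8.725, tolerance = 1e-9)
  expect_equal(f$center, ctr, tolerance = 1e-8)
  expect_lt(f$rms_mm, 1e-9)

  # 10% of points elevated inward by 1 mm: robust fit ignores them
  lespts <- pts
  ei <- seq_len(100)
  lespts[ei, ] <- sweep(as.matrix(lespts[ei, ]) , 2, ctr) * (7.725 / 8.725)
  lespts[ei, ] <- sweep(lespts[ei, ], 2, ctr, `+`)
  fr <- fit_sphere(lespts)
  expect_lt(abs(fr$radius - 8.725), 0.05)

  # gaussian radial noise, 20 um sigma: radius recovered to 0.02 mm
  errs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    r_noisy <- 8.725 + rnorm(nrow(u), 0, 0.02)
    pn <- data.frame(x = r_noisy * u[, 1], y = r_noisy * u[, 2],
                     z = r_noisy * u[, 3])
    fit_sphere(pn)$radius - 8.725
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.02)

  # degenerate inputs
  flat <- data.frame(x = runif(50), y = runif(50), z = 0)
  expect_error(fit_sphere(flat), "coplanar")
  expect_error(fit_sphere(pts[1:5, ]), "at least 10")
})

test_that("elevation is near zero off-lesion and reaches the cap height", {
  v <- make_lesion_volume(nf = 150L, ns = 150L, nd = 900L,
                          lesions = list(lesion(30, 45, 5, 3.5, 1.2)))
  out <- measure_volume_lesions(v, min_height_mm = 0.1, min_area_mm2 = 1,
                                median_window = 3L)
  off <- out$elevation$valid & out$labels[cbind(out$elevation$slow,
                                                out$elevation$fast)] == 0L
  expect_lt(abs(stats::median(out$elevation$elevation_mm[off])), 5e-3)
  expect_lt(abs(out$measurements$height_mm - 1.2), 0.02)
})

test_that("lesion detection counts disjoint components and merges overlaps", {
  four <- list(lesion(15, 0, 2.5, 2, 0.8), lesion(15, 180, 2.5, 2, 0.8),
               lesion(55, 90, 3, 2.5, 1), lesion(55, 270, 3, 2.5, 1))
  v4 <- make_lesion_volume(nf = 120L, ns = 120L, nd = 800L, lesions = four)
  o4 <- measure_volume_lesions(v4, min_height_mm = 0.1, min_area_mm2 = 0.5)
  expect_equal(nrow(o4$measurements), 4)

  # empty scene
  v0 <- make_lesion_volume(nf = 64L, ns = 64L, nd = 800L, lesions = list())
  o0 <- measure_volume_lesions(v0, min_height_mm = 0.1, min_area_mm2 = 0.5)
  expect_null(o0$measurements)
  expect_true(all(o0$labels == 0L))

  # two heavily overlapping caps form one component
  two <- list(lesion(20, 0, 3, 2.5, 0.9), lesion(24, 0, 3, 2.5, 0.9))
  v2 <- make_lesion_volume(nf = 120L, ns = 120L, nd = 800L, lesions = two)
  o2 <- measure_volume_lesions(v2, min_height_mm = 0.1, min_area_mm2 = 0.5)
  expect_equal(nrow(o2$measurements), 1)
})

test_that("a circular cap measures equal length and width; arc exceeds chord", {
  v <- make_lesion_volume(nf = 140L, ns = 140L, nd = 900L,
                          lesions = list(lesion(25, 0, 4, 4 - 1e-9, 1.0)))
  arc <- measure_volume_lesions(v, min_height_mm = 0.08, min_area_mm2 = 1)
  m <- arc$measurements
  expect_equal(m$length_mm, m$width_mm, tolerance = 0.05)
  expect_equal(m$length_mm, 4, tolerance = 0.05 * 4)
  expect_equal(m$height_mm, 1.0, tolerance = 2 * v$depth_pixel_pitch_um / 1000)
  chord <- measure_volume_lesions(v, min_height_mm = 0.08, min_area_mm2 = 1,
                                  mode = "chord")
  expect_lt(chord$measurements$length_mm, m$length_mm)
})

test_that("measurements are stable under a 90-degree azimuthal rotation", {
  mk <- function(az) {
    v <- make_lesion_volume(nf = 170L, ns = 170L, nd = 1000L,
                            lesions = list(lesion(30, az, 5.5, 3.2, 1.1)))
    measure_volume_lesions(v, min_height_mm = 0.1, min_area_mm2 = 1,
                           median_window = 3L)$measurements
  }
  m0 <- mk(0)
  m90 <- mk(90)
  expect_lt(abs(m90$length_mm / m0$length_mm - 1), 0.025)
  expect_lt(abs(m90$width_mm / m0$width_mm - 1), 0.025)
  expect_lt(abs(m90$height_mm - m0$height_mm), 0.01)
  expect_equal(m90$azimuth_deg - m0$azimuth_deg, 90, tolerance = 1)
})
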