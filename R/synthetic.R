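# Seeded synthetic fan-beam OCT volumes: layered reflectivity on a spherical
# retina sampled by a pivot scanner, with lesions, speckle and roll-off.

#' Define a lesion on the retinal sphere
#'
#' An ellipsoidal-cap elevation on the spherical retina: elevation falls
#' from `height_mm` at the centre to zero along an ellipse with geodesic
#' semi-axes `length_mm/2` and `width_mm/2` on the sphere surface. Lesions
#' elevate inward (toward the pivot), as intraocular tumors do.
#'
#' @param center_central_angle_deg Central angle of the lesion centre from
#'   the posterior pole, degrees.
#' @param azimuth_deg Azimuth of the lesion centre, degrees.
#' @param length_mm,width_mm Geodesic extents along the cap's principal
#'   axes, mm; `length_mm >= width_mm > 0`.
#' @param height_mm Maximum elevation normal to the sphere, mm; positive.
#' @param orientation_deg Rotation of the length axis away from the local
#'   meridian, degrees (default 0).
#' @return An object of class `oct_lesion`.
#' @export
lesion <- function(center_central_angle_deg, azimuth_deg = 0,
                   length_mm, width_mm, height_mm, orientation_deg = 0) {
  if (!(length_mm >= width_mm) || width_mm <= 0)
    stop("need length_mm >= width_mm > 0", call. = FALSE)
  if (height_mm <= 0) stop("'height_mm' must be positive", call. = FALSE)
  structure(list(center_central_angle_deg = center_central_angle_deg,
                 azimuth_deg = azimuth_deg,
                 length_mm = length_mm, width_mm = width_mm,
                 height_mm = height_mm,
                 orientation_deg = orientation_deg),
            class = "oct_lesion")
}

#' Define a synthetic OCT scene
#'
#' Everything the volume generator needs besides the scan protocol: the
#' schematic eye, the scan geometry, the axial layer stack riding on the
#' retinal surface, lesions, and the noise model. The layer stack is given
#' as depth offsets (um, optical) below the rendered retinal surface; the
#' default stack puts the brightest band (the RPE, the layer all axial
#' measurements here reference) at offset zero with a dimmer choroid
#' beneath.
#'
#' @param eye A `schematic_eye`.
#' @param geom A `scan_geometry`.
#' @param layers `data.frame(name, offset_um, reflectivity)`; offsets are
#'   optical um below the retinal surface, reflectivities non-negative.
#' @param lesions List of [lesion()] objects (may be empty).
#' @param speckle_mode `"none"` or `"multiplicative-exponential"` (fully
#'   developed speckle: unit-mean exponential multiplicative noise).
#' @param rolloff_db_per_mm Sensitivity roll-off with optical depth,
#'   dB/mm; non-negative.
#' @param noise_floor Additive background level, arbitrary units.
#' @param axial_psf_sigma_um Gaussian axial point-spread sigma used to
#'   render layers, um (optical).
#' @param seed Integer seed; mandatory. The generator never touches the
#'   global random state.
#' @return An object of class `oct_scene`.
#' @export
synthetic_scene <- function(eye = gullstrand_newborn(),
                            geom = default_newborn_geometry(eye),
                            layers = default_layer_stack(),
                            lesions = list(),
                            speckle_mode = c("none", "multiplicative-exponential"),
                            rolloff_db_per_mm = 0,
                            noise_floor = 0,
                            axial_psf_sigma_um = 3,
                            seed) {
  speckle_mode <- match.arg(speckle_mode)
  if (missing(seed) || !is.finite(seed))
    stop("'seed' is mandatory for a synthetic scene", call. = FALSE)
  stopifnot(inherits(eye, "schematic_eye"), inherits(geom, "scan_geometry"),
            is.data.frame(layers),
            all(c("name", "offset_um", "reflectivity") %in% names(layers)),
            all(layers$reflectivity >= 0), rolloff_db_per_mm >= 0,
            noise_floor >= 0, axial_psf_sigma_um > 0)
  if (length(lesions) &&
      !all(vapply(lesions, inherits, logical(1), "oct_lesion")))
    stop("'lesions' must be a list of oct_lesion objects", call. = FALSE)
  structure(list(eye = eye, geom = geom, layers = layers, lesions = lesions,
                 speckle_mode = speckle_mode,
                 rolloff_db_per_mm = rolloff_db_per_mm,
                 noise_floor = noise_floor,
                 axial_psf_sigma_um = axial_psf_sigma_um,
                 seed = as.integer(seed)),
            class = "oct_scene")
}

#' Default retinal layer stack for synthetic volumes
#'
#' Bright RPE band at the rendered surface (offset 0) and a dimmer choroid
#' 50 um (optical) beneath.
#'
#' @return `data.frame(name, offset_um, reflectivity)`.
#' @export
default_layer_stack <- function() {
  data.frame(name = c("RPE", "choroid"),
             offset_um = c(0, 50),
             reflectivity = c(1.0, 0.4))
}

# Evaluate with a private RNG stream; global .Random.seed is untouched.
with_local_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Unit ray direction for fast/slow pivot angles (degrees): two orthogonal
# rotations about the common pivot; alpha = 0 points at the posterior pole.
ray_direction <- function(alpha_fast_deg, alpha_slow_deg) {
  af <- deg2rad(alpha_fast_deg); as_ <- deg2rad(alpha_slow_deg)
  cbind(sin(af), cos(af) * sin(as_), -cos(af) * cos(as_))
}

# Chord from pivot (0,0,a) along unit direction D to sphere |X| = radius.
chord_to_radius <- function(a, radius, Dz) {
  # t^2 + 2 t a Dz + a^2 - radius^2 = 0, take the far (positive) root
  disc <- (a * Dz)^2 - (a^2 - radius^2)
  disc[disc < 0] <- NA_real_
  -a * Dz + sqrt(disc)
}

# Summed lesion elevation (mm) at unit sphere positions U (n x 3).
lesion_elevation <- function(lesions, U, sphere_radius) {
  e <- numeric(nrow(U))
  for (ls in lesions) {
    bc <- deg2rad(ls$center_central_angle_deg)
    ph <- deg2rad(ls$azimuth_deg)
    cvec <- c(sin(bc) * cos(ph), sin(bc) * sin(ph), -cos(bc))
    e_mer <- c(cos(bc) * cos(ph), cos(bc) * sin(ph), sin(bc))
    e_az <- c(-sin(ph), cos(ph), 0)
    o <- deg2rad(ls$orientation_deg)
    e1 <- cos(o) * e_mer + sin(o) * e_az
    e2 <- -sin(o) * e_mer + cos(o) * e_az
    cosps <- pmin(1, pmax(-1, U %*% cvec))
    psi <- acos(cosps)
    V <- U - cosps %*% t(cvec)
    vn <- sqrt(rowSums(V^2))
    scl <- ifelse(vn > 0, sphere_radius * psi / vn, 0)
    s1 <- scl * (V %*% e1)
    s2 <- scl * (V %*% e2)
    q <- 1 - (2 * s1 / ls$length_mm)^2 - (2 * s2 / ls$width_mm)^2
    e <- e + ls$height_mm * sqrt(pmax(0, q))
  }
  e
}

# Surface chord lengths for all rays of a scan grid, lesion-aware.
# Returns list(t_mm, U, alpha_fast, alpha_slow) over the pixel grid
# (slow index varies fastest, matching dim c(n_slow, n_fast)).
surface_chords <- function(geom, lesions, alpha_fast_deg, alpha_slow_deg,
                           sphere_radius = geom$radius_mm) {
  nf <- length(alpha_fast_deg); ns <- length(alpha_slow_deg)
  AF <- rep(alpha_fast_deg, each = ns)
  AS <- rep(alpha_slow_deg, times = nf)
  D <- ray_direction(AF, AS)
  a <- geom$pivot_offset_mm
  t0 <- chord_to_radius(a, sphere_radius, D[, 3])
  if (length(lesions)) {
    # ray-cast the elevated surface |x| = R - e(x/|x|): bisection between
    # the chords to the maximally elevated sphere and to the base sphere
    # (f(t) = |x(t)| - R + e is <= 0 at the lower end, = e >= 0 at t0)
    hmax <- sum(vapply(lesions, `[[`, numeric(1), "height_mm"))
    t_lo <- chord_to_radius(a, sphere_radius - hmax, D[, 3])
    na <- !is.finite(t_lo)          # ray misses the maximally shrunk sphere
    t_lo[na] <- pmax(0, -a * D[na, 3])
    t_hi <- t0
    f_at <- function(t) {
      X <- cbind(t * D[, 1], t * D[, 2], a + t * D[, 3])
      nrm <- sqrt(rowSums(X^2))
      U <- X / nrm
      nrm - sphere_radius + lesion_elevation(lesions, U, sphere_radius)
    }
    for (it in 1:45) {
      t_mid <- (t_lo + t_hi) / 2
      pos <- f_at(t_mid) > 0
      t_hi[pos] <- t_mid[pos]
      t_lo[!pos] <- t_mid[!pos]
    }
    t0 <- (t_lo + t_hi) / 2
  }
  X <- cbind(t0 * D[, 1], t0 * D[, 2], a + t0 * D[, 3])
  U <- X / sqrt(rowSums(X^2))
  list(t_mm = t0, U = U, alpha_fast = AF, alpha_slow = AS)
}

# Sparse samples of a Gaussian axial band over the (npix x ndepth) grid:
# returns linear indices and values; callers accumulate them into a
# locally owned intensity vector (avoids copying large volumes).
band_samples <- function(npix, ndepth, depth_um, amplitude, pitch_um,
                         sigma_um, rolloff_db_per_mm) {
  ctr_px <- depth_um / pitch_um + 0.5      # pixel k centre at (k - 0.5)*pitch
  k0 <- round(ctr_px)
  halfw <- max(1L, ceiling(4 * sigma_um / pitch_um))
  idx_all <- val_all <- vector("list", 2L * halfw + 1L)
  for (off in (-halfw):halfw) {
    kk <- k0 + off
    ok <- which(is.finite(kk) & kk >= 1 & kk <= ndepth & is.finite(depth_um))
    if (!length(ok)) next
    zk <- (kk[ok] - 0.5) * pitch_um
    val <- amplitude[ok] * exp(-((zk - depth_um[ok])^2) / (2 * sigma_um^2))
    if (rolloff_db_per_mm > 0)
      val <- val * 10^(-rolloff_db_per_mm * zk / 1000 / 10)
    idx_all[[off + halfw + 1L]] <- ok + (kk[ok] - 1) * npix
    val_all[[off + halfw + 1L]] <- val
  }
  list(idx = unlist(idx_all), val = unlist(val_all))
}

fan_volume <- function(intensity, kind, alpha_fast_deg, alpha_slow_deg,
                       depth_pixel_pitch_um, reference_arm_position_mm,
                       opl_factor, zero_delay_opl_mm, geom, noise_floor,
                       seed, truth = list()) {
  stopifnot(length(dim(intensity)) == 3L, all(intensity >= 0))
  structure(list(intensity = intensity, kind = kind,
                 alpha_fast_deg = alpha_fast_deg,
                 alpha_slow_deg = alpha_slow_deg,
                 depth_pixel_pitch_um = depth_pixel_pitch_um,
                 reference_arm_position_mm = reference_arm_position_mm,
                 opl_factor = opl_factor,
                 zero_delay_opl_mm = zero_delay_opl_mm,
                 geom = geom, noise_floor = noise_floor,
                 seed = as.integer(seed), truth = truth),
            class = "fan_volume")
}

#' @export
print.fan_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "Fan-beam OCT volume (%s): %d B-scans x %d A-scans x %d depth samples\n",
    x$kind, d[1], d[2], d[3]))
  cat(sprintf("  depth pitch %.3g um (optical), reference arm at %.4g mm, seed %d\n",
              x$depth_pixel_pitch_um, x$reference_arm_position_mm, x$seed))
  invisible(x)
}

finalize_volume <- function(I, scene) {
  if (scene$speckle_mode == "multiplicative-exponential")
    I <- I * stats::rexp(length(I))
  if (scene$noise_floor > 0)
    I <- I + scene$noise_floor * stats::rexp(length(I))
  I
}

#' Generate a synthetic fan-beam retina volume
#'
#' Renders the scene's spherical retina (plus lesion elevations) as seen by
#' a pivot scanner running the given protocol. Each A-scan places the
#' retinal surface at the optical depth implied by the ray's chord length
#' and the reference-arm setting, draws the layer stack beneath it along
#' the ray, applies sensitivity roll-off and (optionally) speckle. The
#' volume is indexed (B-scan/slow angle, A-scan/fast angle, depth sample).
#'
#' Depth bookkeeping: a point at chord `t` from the pivot appears at
#' optical depth `t * n - z0` where `z0` is the zero-delay optical path
#' set by the reference arm. Either pass `fovea_opl_mm` (optical distance
#' of the central retinal surface from the session's corneal-apex
#' reference; the stage position then determines the in-image depth, as in
#' a real biometry session) or let the generator centre the retina in the
#' depth window.
#'
#' @param scene An `oct_scene`.
#' @param protocol A `scan_protocol`; sets the grid dimensions and the
#'   depth pixel pitch.
#' @param reference_arm_position_mm Stage encoder position recorded with
#'   the volume.
#' @param opl_factor Stage-travel to optical-path multiplier (1 for a
#'   stage calibrated in optical path, 2 for double-pass).
#' @param fovea_opl_mm Optional optical path from the corneal-apex
#'   reference to the central retinal surface; ties the in-image depth to
#'   the stage position for biometry simulations.
#' @param central_surface_depth_um Optional explicit in-image depth of the
#'   central retinal surface (um optical); overrides the automatic
#'   placement when `fovea_opl_mm` is absent.
#' @return A `fan_volume` of kind `"retina"`. Ground truth (per-pixel
#'   surface depth, lesion table, foveal pixel) is kept in `$truth`.
#' @export
generate_retina_volume <- function(scene, protocol,
                                   reference_arm_position_mm = 0,
                                   opl_factor = 1,
                                   fovea_opl_mm = NULL,
                                   central_surface_depth_um = NULL) {
  stopifnot(inherits(scene, "oct_scene"), inherits(protocol, "scan_protocol"))
  geom <- scene$geom
  n <- geom$medium_index
  nf <- protocol$n_ascans_per_bscan
  ns <- protocol$n_bscans
  nd <- protocol$samples_per_ascan
  pitch <- depth_pixel_pitch(protocol)
  sigma <- max(scene$axial_psf_sigma_um, 0.7 * pitch)  # keep the band resolvable
  amax <- geom$pivot_half_angle_max_deg
  af <- if (nf > 1) seq(-amax, amax, length.out = nf) else 0
  as_ <- if (ns > 1) seq(-amax, amax, length.out = ns) else 0

  sc <- surface_chords(geom, scene$lesions, af, as_)
  L0 <- chord_length(geom, 0)
  depth_window_um <- nd * pitch
  max_layer <- max(scene$layers$offset_um) + 4 * sigma

  if (!is.null(fovea_opl_mm)) {
    central_mm <- fovea_opl_mm - opl_factor * reference_arm_position_mm
  } else if (!is.null(central_surface_depth_um)) {
    central_mm <- central_surface_depth_um / 1000
  } else {
    span_um <- (L0 - min(sc$t_mm, na.rm = TRUE)) * n * 1000
    central_mm <- min(depth_window_um - max_layer - 4 * sigma,
                      span_um + 200) / 1000
  }
  z0 <- L0 * n - central_mm
  surf_um <- (sc$t_mm * n - z0) * 1000

  if (any(!is.finite(surf_um)) || any(surf_um < 0, na.rm = TRUE) ||
      any(surf_um + max_layer > depth_window_um, na.rm = TRUE))
    warning("part of the retina falls outside the depth window; ",
            "those A-scans are left empty (increase imaging_depth_mm ",
            "or move the pivot toward the eye centre)", call. = FALSE)

  npix <- ns * nf
  I <- numeric(npix * nd)
  for (i in seq_len(nrow(scene$layers))) {
    b <- band_samples(npix, nd, surf_um + scene$layers$offset_um[i],
                      rep(scene$layers$reflectivity[i], npix), pitch,
                      sigma, scene$rolloff_db_per_mm)
    I[b$idx] <- I[b$idx] + b$val
  }
  I <- with_local_rng(scene$seed, finalize_volume(I, scene))
  dim(I) <- c(ns, nf, nd)

  fan_volume(I, "retina", af, as_, pitch, reference_arm_position_mm,
             opl_factor, z0, geom, scene$noise_floor, scene$seed,
             truth = list(
               surface_depth_um = matrix(surf_um, nrow = ns),
               chord_mm = matrix(sc$t_mm, nrow = ns),
               fovea_index = c(slow = (ns + 1) %/% 2, fast = (nf + 1) %/% 2),
               lesions = scene$lesions,
               sphere_radius_mm = geom$radius_mm))
}

#' Generate a synthetic cornea volume
#'
#' Single bright corneal surface whose apex depth is fixed by the
#' reference-arm position: apex optical depth
#' `(apex_opl_mm - opl_factor * reference_arm_position_mm)`. Away from the
#' apex the surface recedes quadratically with scan angle, so the apex is
#' the minimum-depth A-scan. This is the P1 arm of an axial-length
#' measurement.
#'
#' @inheritParams generate_retina_volume
#' @param apex_opl_mm Optical path from the session reference to the
#'   corneal apex (default 0: the apex defines the reference).
#' @param curvature_um_per_deg2 Quadratic recession of the corneal surface
#'   with scan angle, um/deg^2.
#' @param reflectivity Surface reflectivity, arbitrary units.
#' @return A `fan_volume` of kind `"cornea"`.
#' @export
generate_cornea_volume <- function(scene, protocol,
                                   reference_arm_position_mm = 0,
                                   opl_factor = 1,
                                   apex_opl_mm = 0,
                                   curvature_um_per_deg2 = 0.8,
                                   reflectivity = 1) {
  stopifnot(inherits(scene, "oct_scene"), inherits(protocol, "scan_protocol"))
  nf <- protocol$n_ascans_per_bscan
  ns <- protocol$n_bscans
  nd <- protocol$samples_per_ascan
  pitch <- depth_pixel_pitch(protocol)
  amax <- scene$geom$pivot_half_angle_max_deg
  af <- if (nf > 1) seq(-amax, amax, length.out = nf) else 0
  as_ <- if (ns > 1) seq(-amax, amax, length.out = ns) else 0
  AF <- rep(af, each = ns)
  AS <- rep(as_, times = nf)

  apex_um <- (apex_opl_mm - opl_factor * reference_arm_position_mm) * 1000
  surf_um <- apex_um + curvature_um_per_deg2 * (AF^2 + AS^2)
  if (apex_um < 0 || apex_um > nd * pitch)
    warning("corneal apex falls outside the depth window", call. = FALSE)
  surf_um[surf_um < 0 | surf_um > nd * pitch] <- NA_real_

  npix <- ns * nf
  I <- numeric(npix * nd)
  b <- band_samples(npix, nd, surf_um, rep(reflectivity, npix), pitch,
                    max(scene$axial_psf_sigma_um, 0.7 * pitch),
                    scene$rolloff_db_per_mm)
  I[b$idx] <- I[b$idx] + b$val
  I <- with_local_rng(scene$seed + 1L, finalize_volume(I, scene))
  dim(I) <- c(ns, nf, nd)
  fan_volume(I, "cornea", af, as_, pitch, reference_arm_position_mm,
             opl_factor, opl_factor * reference_arm_position_mm,
             scene$geom, scene$noise_floor, scene$seed,
             truth = list(apex_depth_um = apex_um,
                          surface_depth_um = matrix(surf_um, nrow = ns)))
}

#' Generate a synthetic phantom-eye volume
#'
#' Spherical phantom carrying extruded circular rings at a fixed angular
#' interval measured from the phantom centre, used for FOV calibration.
#' Ring regions are elevated by `ring_height_mm` and rendered brighter
#' than the base surface, so the en-face projection shows the ring pattern
#' at the pivot angles predicted by [phantom_ring_angles()].
#'
#' @param phantom_radius_mm Phantom sphere radius, mm.
#' @param ring_interval_deg Ring spacing in central angle, degrees.
#' @param ring_height_mm Extrusion height of each ring, mm.
#' @param geom A `scan_geometry` (pivot placement reused; radius replaced
#'   by the phantom's).
#' @param protocol A `scan_protocol`.
#' @param ring_width_deg Angular width of each ring, degrees.
#' @param seed Integer seed.
#' @param noise_floor,speckle_mode,axial_psf_sigma_um As in
#'   [synthetic_scene()].
#' @return A `fan_volume` of kind `"phantom"`.
#' @export
generate_phantom_volume <- function(phantom_radius_mm, ring_interval_deg,
                                    ring_height_mm, geom, protocol,
                                    ring_width_deg = 4, seed,
                                    noise_floor = 0,
                                    speckle_mode = "none",
                                    axial_psf_sigma_um = 3) {
  stopifnot(inherits(geom, "scan_geometry"), inherits(protocol, "scan_protocol"))
  pg <- scan_geometry(phantom_radius_mm,
                      min(geom$pivot_offset_mm, phantom_radius_mm),
                      geom$pivot_half_angle_max_deg, geom$medium_index)
  rings <- phantom_ring_angles(phantom_radius_mm, ring_interval_deg, geom)
  nf <- protocol$n_ascans_per_bscan
  ns <- protocol$n_bscans
  nd <- protocol$samples_per_ascan
  pitch <- depth_pixel_pitch(protocol)
  amax <- pg$pivot_half_angle_max_deg
  af <- if (nf > 1) seq(-amax, amax, length.out = nf) else 0
  as_ <- if (ns > 1) seq(-amax, amax, length.out = ns) else 0

  sc <- surface_chords(pg, list(), af, as_)
  beta <- rad2deg(acos(pmin(1, pmax(-1, -sc$U[, 3]))))
  on_ring <- rep(FALSE, length(beta))
  for (b in rings$central_angle_deg)
    on_ring <- on_ring | abs(beta - b) <= ring_width_deg / 2
  t_mm <- sc$t_mm
  t_mm[on_ring] <- chord_to_radius(pg$pivot_offset_mm,
                                   phantom_radius_mm - ring_height_mm,
                                   ray_direction(sc$alpha_fast,
                                                 sc$alpha_slow)[, 3])[on_ring]
  n <- pg$medium_index
  L0 <- chord_length(pg, 0)
  span_um <- (L0 - min(t_mm, na.rm = TRUE)) * n * 1000
  central_mm <- min(nd * pitch - 4 * axial_psf_sigma_um, span_um + 200) / 1000
  z0 <- L0 * n - central_mm
  surf_um <- (t_mm * n - z0) * 1000
  surf_um[surf_um < 0 | surf_um > nd * pitch] <- NA_real_

  npix <- ns * nf
  refl <- ifelse(on_ring, 2, 0.8)
  I <- numeric(npix * nd)
  b <- band_samples(npix, nd, surf_um, refl, pitch,
                    max(axial_psf_sigma_um, 0.7 * pitch), 0)
  I[b$idx] <- I[b$idx] + b$val
  I <- with_local_rng(seed, {
    if (speckle_mode == "multiplicative-exponential")
      I <- I * stats::rexp(length(I))
    if (noise_floor > 0) I <- I + noise_floor * stats::rexp(length(I))
    I
  })
  dim(I) <- c(ns, nf, nd)
  fan_volume(I, "phantom", af, as_, pitch, 0, 1, z0, pg, noise_floor, seed,
             truth = list(rings = rings, on_ring = matrix(on_ring, nrow = ns),
                          surface_depth_um = matrix(surf_um, nrow = ns)))
}

#' En-face projection of a fan-beam volume
#'
#' Collapses the depth axis by mean or max, yielding a 2-D image in scan
#' angle coordinates (rows: slow/B-scan angle, columns: fast angle).
#'
#' @param vol A `fan_volume`.
#' @param method `"mean"` or `"max"`.
#' @return Matrix of dimension (n_bscans, n_ascans_per_bscan).
#' @export
en_face_projection <- function(vol, method = c("mean", "max")) {
  stopifnot(inherits(vol, "fan_volume"))
  method <- match.arg(method)
  d <- dim(vol$intensity)
  m <- matrix(vol$intensity, nrow = d[1] * d[2])
  out <- if (method == "mean") rowMeans(m) else m[cbind(seq_len(nrow(m)), max.col(m))]
  matrix(out, nrow = d[1], ncol = d[2])
}

#' Hill-climbing autofocus search
#'
#' Classic one-dimensional hill climb used for en-face-brightness
#' autofocus: step the focus setting in the improving direction, reverse
#' and halve the step on a downturn, stop when the step falls below
#' `tol` or after `max_iter` metric evaluations. For a unimodal metric the
#' returned setting is within the final step of the argmax.
#'
#' @param metric Function of one numeric argument (the focus setting)
#'   returning a finite scalar figure of merit (e.g. mean en-face
#'   brightness).
#' @param start Starting setting.
#' @param step Initial step size.
#' @param lower,upper Bounds of the admissible setting interval.
#' @param max_iter Maximum number of metric evaluations.
#' @param tol Terminal step size.
#' @return List with `setting`, `value` and `n_eval`.
#' @export
autofocus_hill_climb <- function(metric, start, step, lower = -Inf,
                                 upper = Inf, max_iter = 200L,
                                 tol = step / 1024) {
  stopifnot(is.function(metric), step > 0, start >= lower, start <= upper)
  eval_at <- function(x) {
    v <- metric(x)
    if (!is.finite(v)) stop("autofocus metric returned a non-finite value at ",
                            format(x), call. = FALSE)
    v
  }
  x <- start
  fx <- eval_at(x)
  n_eval <- 1L
  dir <- 1
  while (step >= tol && n_eval < max_iter) {
    xn <- min(upper, max(lower, x + dir * step))
    if (xn == x) { dir <- -dir; step <- step / 2; next }
    fn <- eval_at(xn)
    n_eval <- n_eval + 1L
    if (fn > fx) {
      x <- xn; fx <- fn
    } else {
      dir <- -dir
      step <- step / 2
    }
  }
  list(setting = x, value = fx, n_eval = n_eval)
}
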