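# Axial-length biometry: surface detection in cornea/retina volumes, OPL
# assembly from reference-arm stage positions, OPL -> GL conversion.

# Default detection threshold: 6 dB above the noise floor, or 5% of the
# volume maximum when the scene is noiseless.
detection_threshold <- function(vol) {
  if (vol$noise_floor > 0) vol$noise_floor * 10^(6 / 10)
  else 0.05 * max(vol$intensity)
}

# Per-A-scan surface depth (um, optical) with sub-pixel centroid refinement.
# m: (npix x ndepth) intensity matrix. mode "first": first band above
# threshold; "brightest": global per-A-scan maximum.
surface_depths_matrix <- function(m, pitch_um, threshold,
                                  mode = c("brightest", "first"),
                                  refine_halfwidth = 3L) {
  mode <- match.arg(mode)
  nd <- ncol(m)
  if (mode == "brightest") {
    k <- max.col(m, ties.method = "first")
  } else {
    # two consecutive supra-threshold samples: a lone speckle spike above
    # threshold must not trigger a surface
    mask <- m > threshold
    mask2 <- mask[, seq_len(nd - 1L), drop = FALSE] &
      mask[, 1L + seq_len(nd - 1L), drop = FALSE]
    k_first <- max.col(mask2, ties.method = "first")
    k_first[rowSums(mask2) == 0] <- NA_integer_
    # local peak just after the first crossing
    k <- k_first
    ok <- which(!is.na(k_first))
    if (length(ok)) {
      width <- 2L * refine_halfwidth
      cand <- pmin(outer(k_first[ok], 0:width, `+`), nd)
      vals <- matrix(m[cbind(rep(ok, width + 1L), as.vector(cand))],
                     nrow = length(ok))
      k[ok] <- cand[cbind(seq_along(ok), max.col(vals, ties.method = "first"))]
    }
  }
  peak_val <- m[cbind(seq_len(nrow(m)), ifelse(is.na(k), 1L, k))]
  valid <- !is.na(k) & peak_val > threshold
  # Gaussian (log-parabolic) sub-pixel interpolation of the peak; exact for
  # a noiseless Gaussian band whatever its width relative to the pitch
  ks <- ifelse(is.na(k), 2L, pmin(pmax(k, 2L), nd - 1L))
  i <- seq_len(nrow(m))
  v0 <- m[cbind(i, ks - 1L)]; v1 <- m[cbind(i, ks)]; v2 <- m[cbind(i, ks + 1L)]
  eps <- 1e-12 * max(m)
  l0 <- log(pmax(v0, eps)); l1 <- log(pmax(v1, eps)); l2 <- log(pmax(v2, eps))
  den <- l0 - 2 * l1 + l2
  frac <- ifelse(is.finite(den) & den < 0, 0.5 * (l0 - l2) / den, 0)
  frac[abs(frac) > 1] <- 0
  depth <- (ks + frac - 0.5) * pitch_um
  depth[!valid] <- NA_real_
  depth
}

#' Construct a biometry record
#'
#' Pairs the reference-arm stage positions recorded with the cornea (P1)
#' and retina (P2) volumes with the in-image surface depths measured in
#' each, from which the optical path length of the eye is assembled.
#'
#' @param stage_cornea_mm Stage encoder position P1 at the cornea
#'   acquisition, mm.
#' @param stage_retina_mm Stage encoder position P2 at the retina
#'   acquisition, mm.
#' @param apex_depth_um In-image optical depth of the corneal apex in the
#'   P1 volume, um.
#' @param fovea_depth_um In-image optical depth of the foveal RPE in the
#'   P2 volume, um.
#' @param opl_factor Stage-travel to optical-path multiplier (default 1;
#'   use 2 for a double-pass reference arm).
#' @param lens_offset_mm Fixed optical-path offset of the contact-lens
#'   assembly, mm, added to the OPL (default 0).
#' @return An object of class `biometry_record`.
#' @export
biometry_record <- function(stage_cornea_mm, stage_retina_mm,
                            apex_depth_um, fovea_depth_um,
                            opl_factor = 1, lens_offset_mm = 0) {
  stopifnot(is.finite(stage_cornea_mm), is.finite(stage_retina_mm),
            is.finite(apex_depth_um), is.finite(fovea_depth_um),
            opl_factor > 0)
  structure(list(stage_cornea_mm = stage_cornea_mm,
                 stage_retina_mm = stage_retina_mm,
                 apex_depth_um = apex_depth_um,
                 fovea_depth_um = fovea_depth_um,
                 opl_factor = opl_factor,
                 lens_offset_mm = lens_offset_mm),
            class = "biometry_record")
}

#' Detect the corneal apex in a cornea volume
#'
#' Per-A-scan surface depth by thresholded peak detection (the corneal
#' surface is the single dominant reflector in the P1 volume) refined to
#' sub-pixel, median-smoothed over 5 A-scans along the fast axis of the
#' central B-scan; the apex is the minimum-depth A-scan.
#'
#' @param vol A `fan_volume` of kind `"cornea"`.
#' @param threshold Detection threshold; default 6 dB above the volume's
#'   noise floor (5% of the maximum for noiseless volumes).
#' @return List with `ascan` (fast index on the central B-scan) and
#'   `depth_um`.
#' @export
detect_apex <- function(vol, threshold = detection_threshold(vol)) {
  stopifnot(inherits(vol, "fan_volume"))
  d <- dim(vol$intensity)
  central <- (d[1] + 1L) %/% 2L
  m <- matrix(vol$intensity[central, , ], nrow = d[2])
  depth <- surface_depths_matrix(m, vol$depth_pixel_pitch_um, threshold,
                                 mode = "brightest")
  if (all(is.na(depth)))
    stop("no corneal surface found above the detection threshold",
         call. = FALSE)
  if (sum(!is.na(depth)) >= 5) {
    sm <- depth
    sm[!is.na(depth)] <- stats::runmed(depth[!is.na(depth)], 5)
    depth <- sm
  }
  i <- which.min(depth)
  list(ascan = i, depth_um = depth[i])
}

#' Detect the foveal RPE depth in a retina volume
#'
#' Brightest-layer depth (the RPE is the most reflective band) at the
#' designated foveal A-scan, taken as the median over a small angular
#' neighbourhood to suppress speckle.
#'
#' @param vol A `fan_volume` of kind `"retina"`.
#' @param fovea_index Integer pair `c(slow, fast)`; defaults to the
#'   volume's recorded foveal pixel, or the central A-scan.
#' @param halfwidth Half-width of the median neighbourhood in pixels
#'   (default 2, i.e. a 5 x 5 window).
#' @param threshold Detection threshold as in [detect_apex()].
#' @return Foveal RPE depth in um (optical).
#' @export
detect_fovea_rpe <- function(vol, fovea_index = NULL, halfwidth = 2L,
                             threshold = detection_threshold(vol)) {
  stopifnot(inherits(vol, "fan_volume"))
  d <- dim(vol$intensity)
  if (is.null(fovea_index))
    fovea_index <- if (!is.null(vol$truth$fovea_index)) vol$truth$fovea_index
                   else c((d[1] + 1L) %/% 2L, (d[2] + 1L) %/% 2L)
  is_ <- max(1L, fovea_index[1] - halfwidth):min(d[1], fovea_index[1] + halfwidth)
  if_ <- max(1L, fovea_index[2] - halfwidth):min(d[2], fovea_index[2] + halfwidth)
  sub <- vol$intensity[is_, if_, , drop = FALSE]
  m <- matrix(sub, nrow = length(is_) * length(if_))
  depth <- surface_depths_matrix(m, vol$depth_pixel_pitch_um, threshold,
                                 mode = "brightest")
  if (all(is.na(depth)))
    stop("no retinal layer found above the detection threshold", call. = FALSE)
  stats::median(depth, na.rm = TRUE)
}

#' Assemble the optical path length of the eye
#'
#' `OPL = opl_factor * (P2 - P1) + (fovea_depth - apex_depth) + lens_offset`:
#' the reference-arm travel between the cornea and retina acquisitions plus
#' the in-image depth difference of the two surfaces. Positive for
#' posterior-directed stage travel; a non-positive result indicates an
#' inconsistent record.
#'
#' @param rec A [biometry_record()].
#' @return Optical path length in mm.
#' @export
compute_opl <- function(rec) {
  stopifnot(inherits(rec, "biometry_record"))
  opl <- rec$opl_factor * (rec$stage_retina_mm - rec$stage_cornea_mm) +
    (rec$fovea_depth_um - rec$apex_depth_um) / 1000 + rec$lens_offset_mm
  if (!is.finite(opl) || opl <= 0)
    stop("inconsistent biometry record: computed OPL is not positive",
         call. = FALSE)
  opl
}

#' Axial length from a biometry record
#'
#' Converts the assembled optical path length to geometric axial length by
#' the eye's average refractive index: `AL = OPL / n_avg`.
#'
#' @param rec A [biometry_record()], or a single OPL value in mm.
#' @param eye A `schematic_eye` supplying `n_avg` (default the newborn
#'   preset).
#' @return Axial length in mm.
#' @export
#' @examples
#' rec <- biometry_record(0, 23.18, 500, 1000)
#' measure_axial_length(rec)  # ~17.45 for the newborn eye
measure_axial_length <- function(rec, eye = gullstrand_newborn()) {
  opl <- if (inherits(rec, "biometry_record")) compute_opl(rec) else rec
  opl_to_geometric(opl, average_refractive_index(eye))
}

#' Simulate a paired cornea/retina biometry acquisition
#'
#' Builds an eye of the requested axial length (newborn proportions scaled
#' uniformly), simulates the cornea volume at stage position P1 and the
#' retina volume at P2 with consistent optical-path bookkeeping, and
#' returns the volumes together with the ground truth.
#'
#' @param true_al_mm Ground-truth axial length, mm.
#' @param seed Integer seed.
#' @param opl_factor Stage calibration passed through to the generator.
#' @param stage_offset_mm Offset added to both stage positions (the
#'   pipeline must be invariant to it).
#' @param noise_floor,speckle Noise settings for both volumes.
#' @param samples_per_ascan,imaging_depth_mm Depth sampling of both
#'   volumes.
#' @param n_ascans,n_bscans Transverse sampling of both volumes.
#' @param fov_deg Full pivot FOV used for the biometry scans, degrees. A
#'   narrow scan centred on the fovea is used (default 10) so that the
#'   retinal depth curvature across the foveal median window stays well
#'   below a depth pixel.
#' @return List with `cornea`, `retina` (fan volumes), `stage_cornea_mm`,
#'   `stage_retina_mm`, `opl_factor`, `true_al_mm`, `true_opl_mm`, `eye`.
#' @export
simulate_biometry_pair <- function(true_al_mm, seed, opl_factor = 1,
                                   stage_offset_mm = 0,
                                   noise_floor = 0, speckle = FALSE,
                                   samples_per_ascan = 800L,
                                   imaging_depth_mm = 6,
                                   n_ascans = 64L, n_bscans = 16L,
                                   fov_deg = 10) {
  scale <- true_al_mm / 17.45
  eye <- gullstrand_newborn(scale = scale)
  r <- total_axial_length(eye) / 2
  geom <- scan_geometry(r, r - 2.6 * scale, fov_deg / 2,
                        medium_index = average_refractive_index(eye))
  protocol <- scan_protocol(n_ascans_per_bscan = n_ascans, n_bscans = n_bscans,
                            samples_per_ascan = samples_per_ascan,
                            imaging_depth_mm = imaging_depth_mm)
  scene <- synthetic_scene(eye = eye, geom = geom,
                           speckle_mode = if (speckle)
                             "multiplicative-exponential" else "none",
                           noise_floor = noise_floor, seed = seed)
  opl_true <- geometric_to_opl(true_al_mm, eye)
  # session optical-path origin: 0.5 mm before the apex, shifted with the
  # stage offset so the rendered images are identical under the offset
  apex_opl <- 0.5 + opl_factor * stage_offset_mm
  fovea_opl <- apex_opl + opl_true
  p1 <- stage_offset_mm
  central_target <- 0.75 * imaging_depth_mm  # park the fovea 75% into window
  p2 <- (fovea_opl - central_target) / opl_factor
  cornea <- generate_cornea_volume(scene, protocol,
                                   reference_arm_position_mm = p1,
                                   opl_factor = opl_factor,
                                   apex_opl_mm = apex_opl)
  retina <- generate_retina_volume(scene, protocol,
                                   reference_arm_position_mm = p2,
                                   opl_factor = opl_factor,
                                   fovea_opl_mm = fovea_opl)
  list(cornea = cornea, retina = retina,
       stage_cornea_mm = p1, stage_retina_mm = p2,
       opl_factor = opl_factor, true_al_mm = true_al_mm,
       true_opl_mm = opl_true, eye = eye)
}

#' Run the full biometry pipeline on a simulated pair
#'
#' Detects the corneal apex and foveal RPE, assembles the OPL from the
#' stage positions and converts to axial length.
#'
#' @param pair Output of [simulate_biometry_pair()], or any list with the
#'   same fields.
#' @return List with `record` (the [biometry_record()]), `opl_mm` and
#'   `axial_length_mm`.
#' @export
measure_biometry_pair <- function(pair) {
  apex <- detect_apex(pair$cornea)
  fov <- detect_fovea_rpe(pair$retina)
  rec <- biometry_record(pair$stage_cornea_mm, pair$stage_retina_mm,
                         apex$depth_um, fov, opl_factor = pair$opl_factor)
  opl <- compute_opl(rec)
  list(record = rec, opl_mm = opl,
       axial_length_mm = measure_axial_length(rec, pair$eye))
}

#' Axial-length parameter-recovery experiment
#'
#' For each true axial length and noise level, simulates paired
#' cornea/retina acquisitions, runs the full detection and conversion
#' pipeline, and summarises recovery accuracy. Deterministic given `seed`.
#'
#' @param true_al_grid_mm Vector of ground-truth axial lengths, mm.
#' @param noise_levels Vector of noise-floor levels; 0 means noiseless,
#'   positive values also switch on multiplicative speckle.
#' @param n_reps Replicates per condition.
#' @param seed Integer seed.
#' @param ... Further arguments to [simulate_biometry_pair()].
#' @return `data.frame(true_al_mm, noise_level, n_reps, mean_estimate_mm,
#'   bias_mm, rmse_mm)`.
#' @export
al_recovery_experiment <- function(true_al_grid_mm = seq(16, 24, by = 2),
                                   noise_levels = 0, n_reps = 1L, seed,
                                   ...) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  rows <- list()
  k <- 0L
  for (nl in noise_levels) {
    for (al in true_al_grid_mm) {
      est <- vapply(seq_len(n_reps), function(rep) {
        k <<- k + 1L
        pair <- simulate_biometry_pair(
          al, seed = seed + k, noise_floor = nl, speckle = nl > 0, ...)
        measure_biometry_pair(pair)$axial_length_mm
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        true_al_mm = al, noise_level = nl, n_reps = n_reps,
        mean_estimate_mm = mean(est), bias_mm = mean(est) - al,
        rmse_mm = sqrt(mean((est - al)^2)))
    }
  }
  do.call(rbind, rows)
}
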