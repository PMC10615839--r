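#' Spherical-eye scan geometry
#'
#' Represents the ideal-sphere model of the globe used by a pivot-scanned
#' wide-field OCT system. The eye is a sphere of radius `radius_mm` centred
#' at C; the scan beam rotates about a pivot point P located
#' `pivot_offset_mm` anterior of C on the visual axis. A ray leaving P at
#' half-angle `alpha` from the posterior direction intersects the retina at
#' chord length `L(alpha) = a*cos(alpha) + sqrt(r^2 - a^2*sin(alpha)^2)`.
#'
#' Two field-of-view conventions coexist in wide-field imaging: the pivot
#' convention (full angle swept about P, the convention used for the scanner
#' itself) and the eye-centre convention (angle subtended at C, used by
#' scanning-laser ophthalmoscopes and fundus cameras). This object carries
#' everything needed to convert between them.
#'
#' @param radius_mm Sphere radius r in mm; positive.
#' @param pivot_offset_mm Distance a of the pivot anterior of the centre, mm;
#'   `0 <= a <= r`. `a = 0` places the pivot at the eye centre; larger values
#'   move it toward the iris plane, `a = r` onto the globe itself (the
#'   inscribed-angle limit where the central angle is exactly twice the
#'   pivot angle).
#' @param pivot_half_angle_max_deg Maximum scan half-angle about the pivot,
#'   degrees, in (0, 90). The full pivot-referenced FOV is twice this.
#' @param medium_index Refractive index used to convert geometric depth to
#'   the optical depth seen in the OCT image (default 1.357, the
#'   newborn-eye average).
#' @return An object of class `scan_geometry`.
#' @export
#' @examples
#' g <- scan_geometry(8.725, 6.125, 70)
#' chord_length(g, 0)   # a + r
#' central_angle(g, 70) # centre-referenced half-FOV at full deflection
scan_geometry <- function(radius_mm, pivot_offset_mm, pivot_half_angle_max_deg,
                          medium_index = 1.357) {
  radius_mm <- as.numeric(radius_mm)
  pivot_offset_mm <- as.numeric(pivot_offset_mm)
  pivot_half_angle_max_deg <- as.numeric(pivot_half_angle_max_deg)
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("'radius_mm' must be positive", call. = FALSE)
  if (!is.finite(pivot_offset_mm) || pivot_offset_mm < 0 ||
      pivot_offset_mm > radius_mm)
    stop("'pivot_offset_mm' must satisfy 0 <= a <= radius", call. = FALSE)
  if (!is.finite(pivot_half_angle_max_deg) || pivot_half_angle_max_deg <= 0 ||
      pivot_half_angle_max_deg >= 90)
    stop("'pivot_half_angle_max_deg' must lie in (0, 90)", call. = FALSE)
  if (!is.finite(medium_index) || medium_index < 1)
    stop("'medium_index' must be >= 1", call. = FALSE)
  structure(list(radius_mm = radius_mm,
                 pivot_offset_mm = pivot_offset_mm,
                 pivot_half_angle_max_deg = pivot_half_angle_max_deg,
                 medium_index = medium_index),
            class = "scan_geometry")
}

#' Default newborn scan geometry
#'
#' Sphere radius is half the axial length of the supplied schematic eye and
#' the pivot sits on the iris plane, i.e. `a = r - (CT + ACD)`. For the
#' newborn preset this gives r = 8.725 mm and a = 6.125 mm. Pivoting on the
#' iris plane is the placement that avoids iris vignetting at large scan
#' angles and so maximises the transverse FOV.
#'
#' @param eye A `schematic_eye` (default [gullstrand_newborn()]).
#' @param fov_deg Full pivot-referenced FOV in degrees (default 140).
#' @return A `scan_geometry`.
#' @export
default_newborn_geometry <- function(eye = gullstrand_newborn(), fov_deg = 140) {
  r <- total_axial_length(eye) / 2
  nm <- vapply(eye$segments, `[[`, character(1), "name")
  d <- seg_thicknesses(eye)
  anterior <- sum(d[nm %in% c("CT", "ACD")])
  scan_geometry(r, r - anterior, fov_deg / 2,
                medium_index = average_refractive_index(eye))
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "Scan geometry: r = %.4g mm, pivot offset a = %.4g mm, alpha_max = %.4g deg (FOV %.4g deg), n = %.4g\n",
    x$radius_mm, x$pivot_offset_mm, x$pivot_half_angle_max_deg,
    2 * x$pivot_half_angle_max_deg, x$medium_index))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Chord length from the scanning pivot to the retina
#'
#' Distance along the ray from the pivot P to its intersection with the
#' retinal sphere, `L(alpha) = a*cos(alpha) + sqrt(r^2 - a^2*sin(alpha)^2)`.
#' `L(0) = a + r`; for `a > 0`, L decreases monotonically with `|alpha|` on
#' [0, 90] degrees, which is why the peripheral retina appears shallower
#' than the posterior pole in a pivot-scanned B-scan.
#'
#' @param geom A `scan_geometry`.
#' @param alpha_deg Pivot half-angle(s) in degrees, `|alpha| <= 180`.
#' @return Chord length(s) in mm.
#' @export
chord_length <- function(geom, alpha_deg) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (any(abs(alpha_deg) > 180)) stop("|alpha| must be <= 180 deg", call. = FALSE)
  a <- geom$pivot_offset_mm
  r <- geom$radius_mm
  al <- deg2rad(alpha_deg)
  a * cos(al) + sqrt(r^2 - a^2 * sin(al)^2)
}

#' Eye-centre angle reached at a given pivot half-angle
#'
#' Converts the scanner's pivot half-angle `alpha` into the angle `beta/2`
#' subtended at the eye centre between the posterior pole and the retinal
#' point struck by the ray: `beta_half = acos((L*cos(alpha) - a) / r)`.
#' With the pivot at the centre the two angles coincide; an anterior pivot
#' always reaches a larger centre-referenced angle (for `a = r` the
#' inscribed-angle theorem gives exactly `beta_half = 2*alpha`), which is
#' how a 140-degree pivot FOV covers well past the equator of the globe.
#'
#' @inheritParams chord_length
#' @return Central half-angle(s) in degrees.
#' @export
central_angle <- function(geom, alpha_deg) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (any(abs(alpha_deg) > 180)) stop("|alpha| must be <= 180 deg", call. = FALSE)
  a <- geom$pivot_offset_mm
  r <- geom$radius_mm
  al <- deg2rad(abs(alpha_deg))
  L <- chord_length(geom, alpha_deg)
  ca <- (L * cos(al) - a) / r
  rad2deg(acos(pmin(1, pmax(-1, ca))))
}

#' Pivot half-angle needed to reach a given eye-centre angle
#'
#' Inverse of [central_angle()], solved by bisection to 1e-9 degree. Used to
#' predict at which scanner angles the rings of a calibration phantom will
#' appear.
#'
#' @param geom A `scan_geometry`.
#' @param beta_half_deg Target central half-angle(s), degrees; must not
#'   exceed the largest central angle reachable at a 90-degree pivot
#'   half-angle.
#' @return Pivot half-angle(s) in degrees.
#' @export
pivot_angle_for_central_angle <- function(geom, beta_half_deg) {
  stopifnot(inherits(geom, "scan_geometry"))
  beta_max <- central_angle(geom, 90)
  vapply(beta_half_deg, function(bh) {
    if (bh < 0 || bh > beta_max + 1e-12)
      stop(sprintf(
        "central half-angle %.6g deg is unreachable; maximum is %.6g deg",
        bh, beta_max), call. = FALSE)
    if (bh == 0) return(0)
    lo <- 0; hi <- 90
    while (hi - lo > 1e-9) {
      mid <- (lo + hi) / 2
      if (central_angle(geom, mid) < bh) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Imaging depth required to hold the curved retina in one scan
#'
#' In a pivot-scanned system the posterior pole lies a full chord `a + r`
#' from the pivot while the most peripheral ray is shorter, so the retina
#' sweeps through a depth range of `max(L(0) - L(alpha))` over the scanned
#' angles. The OCT window must cover this range (in optical units, i.e.
#' multiplied by the medium index) or the peripheral retina aliases.
#' The range is zero when the pivot sits at the eye centre.
#'
#' @param geom A `scan_geometry`.
#' @return Named numeric vector `c(geometric_mm = , optical_mm = )`.
#' @export
required_imaging_depth <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  al <- seq(0, geom$pivot_half_angle_max_deg, length.out = 2001L)
  g <- max(chord_length(geom, 0) - chord_length(geom, al))
  c(geometric_mm = g, optical_mm = g * geom$medium_index)
}

#' Depth profile the retina traces across a B-scan
#'
#' Per-angle optical depth of the retinal surface referenced to the central
#' A-scan: `(L(0) - L(alpha)) * n`. Symmetric in `alpha`; identically zero
#' when the pivot is at the eye centre.
#'
#' @param geom A `scan_geometry`.
#' @param alpha_deg Vector of pivot half-angles, degrees, within the
#'   geometry's maximum.
#' @return Optical depths in mm, same length as `alpha_deg`.
#' @export
bscan_depth_profile <- function(geom, alpha_deg) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (any(abs(alpha_deg) > geom$pivot_half_angle_max_deg + 1e-9))
    stop("angles exceed the geometry's maximum half-angle", call. = FALSE)
  (chord_length(geom, 0) - chord_length(geom, alpha_deg)) * geom$medium_index
}

#' Largest scan angle that clears the pupil
#'
#' The beam pivots about P; at the iris plane (a given distance anterior of
#' the eye centre) it is displaced laterally by `|a - z_iris| * tan(alpha)`.
#' Rays displaced beyond the pupil radius are clipped by the iris
#' (vignetting). When the pivot lies on the iris plane every ray passes
#' through the pupil centre and the full scan range is available — the
#' motivation for contact probes that fix the pivot there.
#'
#' @param geom A `scan_geometry`.
#' @param iris_plane_offset_mm Axial distance of the iris plane anterior of
#'   the eye centre, mm.
#' @param pupil_radius_mm Pupil radius, mm; positive.
#' @return Largest unvignetted pivot half-angle in degrees (capped at the
#'   geometry's maximum).
#' @export
vignetting_limit <- function(geom, iris_plane_offset_mm, pupil_radius_mm) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (!is.finite(pupil_radius_mm) || pupil_radius_mm <= 0)
    stop("'pupil_radius_mm' must be positive", call. = FALSE)
  lever <- abs(geom$pivot_offset_mm - iris_plane_offset_mm)
  if (lever < 1e-12) return(geom$pivot_half_angle_max_deg)
  lim <- rad2deg(atan(pupil_radius_mm / lever))
  min(lim, geom$pivot_half_angle_max_deg)
}

#' Ring positions of a calibration phantom eye
#'
#' A phantom eye for FOV calibration carries concentric rings spaced at a
#' fixed angular interval measured from the phantom centre. This maps each
#' ring's central angle to the pivot half-angle at which the scanner will
#' cross it, using the supplied geometry (same pivot placement, phantom
#' radius). Rings beyond the reachable range are listed in the
#' `"omitted_rings"` attribute.
#'
#' @param phantom_radius_mm Phantom sphere radius, mm (the reference phantom
#'   is 12 mm).
#' @param ring_interval_deg Angular interval between adjacent rings measured
#'   from the centre, degrees (reference phantom: 40).
#' @param geom A `scan_geometry` whose pivot placement is reused; its radius
#'   is replaced by the phantom radius.
#' @param include_pole Include the degenerate ring at the pole
#'   (central angle 0). Default `FALSE`.
#' @return `data.frame(ring_index, central_angle_deg, pivot_angle_deg)` with
#'   attribute `omitted_rings` (central angles that cannot be reached).
#' @export
phantom_ring_angles <- function(phantom_radius_mm, ring_interval_deg, geom,
                                include_pole = FALSE) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (!is.finite(ring_interval_deg) || ring_interval_deg <= 0)
    stop("'ring_interval_deg' must be positive", call. = FALSE)
  pg <- scan_geometry(phantom_radius_mm,
                      min(geom$pivot_offset_mm, phantom_radius_mm),
                      geom$pivot_half_angle_max_deg,
                      geom$medium_index)
  k0 <- if (include_pole) 0L else 1L
  half <- ring_interval_deg / 2
  kmax <- floor(180 / half)
  ks <- if (kmax >= k0) seq.int(k0, kmax) else integer(0)
  betas <- ks * half
  beta_reach <- central_angle(pg, pg$pivot_half_angle_max_deg)
  keep <- betas <= beta_reach + 1e-9
  out <- data.frame(
    ring_index = ks[keep],
    central_angle_deg = betas[keep],
    pivot_angle_deg = if (any(keep))
      pivot_angle_for_central_angle(pg, betas[keep]) else numeric(0)
  )
  attr(out, "omitted_rings") <- betas[!keep & betas <= 180]
  out
}
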