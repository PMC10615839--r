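#' Swept-source OCT scan protocol
#'
#' Bundle of laser and scan-pattern parameters from which timing,
#' resolution and depth-range figures are derived. Defaults describe a
#' 400 kHz swept source at 1060 nm with ~70 nm (6 dB) bandwidth running the
#' high-resolution acquisition pattern (800 A-scans x 780 B-scans).
#'
#' @param ascan_rate_hz A-scan (sweep) rate, Hz.
#' @param n_ascans_per_bscan A-scans per B-scan.
#' @param n_bscans B-scans per volume.
#' @param samples_per_ascan Digitizer samples per A-scan spectrum.
#' @param center_wavelength_nm Centre wavelength lambda0, nm.
#' @param bandwidth_nm Spectral bandwidth (6 dB), nm; must be below the
#'   centre wavelength.
#' @param duty_cycle Fraction of the sweep period carrying signal, in (0, 1].
#' @param sampling_rate_hz Digitizer sampling rate, Hz (metadata; checked
#'   for consistency with the sweep timing when supplied).
#' @param beam_diameter_pupil_mm 1/e^2 beam diameter on the pupil plane, mm.
#' @param output_power_mw Output power at the probe, mW (metadata).
#' @param imaging_depth_mm Axial imaging window in air, mm; sets the depth
#'   pixel pitch `imaging_depth_mm * 1000 / samples_per_ascan` (um/pixel,
#'   optical).
#' @return An object of class `scan_protocol`.
#' @export
#' @examples
#' p <- scan_protocol()
#' volume_acquisition_time(p)   # 1.56 s
#' volume_rate(alignment_protocol())  # 10 Hz
scan_protocol <- function(ascan_rate_hz = 400e3,
                          n_ascans_per_bscan = 800L,
                          n_bscans = 780L,
                          samples_per_ascan = 2048L,
                          center_wavelength_nm = 1060,
                          bandwidth_nm = 70,
                          duty_cycle = 0.5,
                          sampling_rate_hz = 1720e6,
                          beam_diameter_pupil_mm = 0.36,
                          output_power_mw = 1.68,
                          imaging_depth_mm = 6) {
  stopifnot(ascan_rate_hz > 0, n_ascans_per_bscan >= 1, n_bscans >= 1,
            samples_per_ascan >= 1, center_wavelength_nm > 0,
            bandwidth_nm > 0, bandwidth_nm < center_wavelength_nm,
            duty_cycle > 0, duty_cycle <= 1, imaging_depth_mm > 0)
  if (!is.null(sampling_rate_hz) &&
      samples_per_ascan / sampling_rate_hz > duty_cycle / ascan_rate_hz + 1e-15)
    stop("inconsistent protocol: sampling the spectrum takes longer than ",
         "the active part of the sweep", call. = FALSE)
  structure(list(ascan_rate_hz = ascan_rate_hz,
                 n_ascans_per_bscan = as.integer(n_ascans_per_bscan),
                 n_bscans = as.integer(n_bscans),
                 samples_per_ascan = as.integer(samples_per_ascan),
                 center_wavelength_nm = center_wavelength_nm,
                 bandwidth_nm = bandwidth_nm,
                 duty_cycle = duty_cycle,
                 sampling_rate_hz = sampling_rate_hz,
                 beam_diameter_pupil_mm = beam_diameter_pupil_mm,
                 output_power_mw = output_power_mw,
                 imaging_depth_mm = imaging_depth_mm),
            class = "scan_protocol")
}

#' High-speed alignment protocol preset
#'
#' 400 A-scans per B-scan, 100 B-scans per volume at 400 kHz: a 10 Hz
#' volume rate used for live alignment before switching to the
#' high-resolution pattern.
#'
#' @param ... Overrides passed to [scan_protocol()].
#' @return A `scan_protocol`.
#' @export
alignment_protocol <- function(...) {
  scan_protocol(n_ascans_per_bscan = 400L, n_bscans = 100L, ...)
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf(
    "Scan protocol: %d x %d A-scans at %.4g kHz (%.3g s/volume), %d samples/A-scan\n",
    x$n_ascans_per_bscan, x$n_bscans, x$ascan_rate_hz / 1e3,
    volume_acquisition_time(x), x$samples_per_ascan))
  cat(sprintf("  lambda0 = %.4g nm, bandwidth = %.4g nm, depth window %.4g mm (air)\n",
              x$center_wavelength_nm, x$bandwidth_nm, x$imaging_depth_mm))
  invisible(x)
}

#' Volume acquisition time
#'
#' `n_ascans_per_bscan * n_bscans / ascan_rate`, seconds.
#'
#' @param p A `scan_protocol`.
#' @return Seconds per volume.
#' @export
volume_acquisition_time <- function(p) {
  stopifnot(inherits(p, "scan_protocol"))
  p$n_ascans_per_bscan * p$n_bscans / p$ascan_rate_hz
}

#' Volume rate
#'
#' Reciprocal of [volume_acquisition_time()], Hz.
#'
#' @param p A `scan_protocol`.
#' @return Volumes per second.
#' @export
volume_rate <- function(p) 1 / volume_acquisition_time(p)

#' Axial resolution of a Gaussian-spectrum OCT source
#'
#' Full-width-half-maximum axial resolution
#' `(2 ln 2 / pi) * lambda0^2 / bandwidth / n`, reported in micrometres.
#' For 1060 nm and 70 nm bandwidth in air this evaluates to about 7.08 um.
#'
#' @param center_wavelength_nm Centre wavelength, nm. A `scan_protocol` may
#'   be given instead, in which case its wavelength and bandwidth are used.
#' @param bandwidth_nm Spectral bandwidth (FWHM), nm.
#' @param medium_index Refractive index of the medium (1 for air).
#' @return Axial resolution in um.
#' @export
axial_resolution <- function(center_wavelength_nm, bandwidth_nm = NULL,
                             medium_index = 1) {
  if (inherits(center_wavelength_nm, "scan_protocol")) {
    p <- center_wavelength_nm
    if (is.null(bandwidth_nm)) bandwidth_nm <- p$bandwidth_nm
    center_wavelength_nm <- p$center_wavelength_nm
  }
  stopifnot(bandwidth_nm > 0, bandwidth_nm < center_wavelength_nm,
            medium_index >= 1)
  (2 * log(2) / pi) * center_wavelength_nm^2 / bandwidth_nm / medium_index / 1e3
}

#' Sampling-limited imaging depth
#'
#' Depth window set by spectral sampling density:
#' `lambda0^2 * samples / (4 * sweep_range)`, in mm (air). Note the sweep
#' range here is the full swept wavelength span, which generally exceeds
#' the 6 dB bandwidth.
#'
#' @param center_wavelength_nm Centre wavelength, nm.
#' @param sweep_range_nm Full swept wavelength range, nm.
#' @param samples Samples per A-scan spectrum.
#' @return Imaging depth in mm.
#' @export
sampling_imaging_depth <- function(center_wavelength_nm, sweep_range_nm,
                                   samples) {
  stopifnot(sweep_range_nm > 0, samples >= 1)
  center_wavelength_nm^2 * samples / (4 * sweep_range_nm) / 1e6
}

#' Diffraction-limited focal spot diameter on the retina
#'
#' Gaussian-beam 1/e^2 focal diameter
#' `4 * (lambda0 / n) * f / (pi * D)`, in micrometres, for beam diameter D
#' at the pupil and focal length f (approximately the axial length for an
#' emmetropic eye). This is the standard Gaussian focusing formula; vendor
#' or ray-traced figures computed under other conventions can differ by a
#' few percent.
#'
#' @param center_wavelength_nm Centre wavelength, nm.
#' @param beam_diameter_pupil_mm 1/e^2 beam diameter at the pupil, mm.
#' @param focal_length_mm Effective focal length, mm.
#' @param medium_index Refractive index of the image space (vitreous ~1.336).
#' @return Spot diameter (1/e^2) in um.
#' @export
focal_spot_diameter <- function(center_wavelength_nm, beam_diameter_pupil_mm,
                                focal_length_mm, medium_index = 1) {
  stopifnot(center_wavelength_nm > 0, beam_diameter_pupil_mm > 0,
            focal_length_mm > 0, medium_index >= 1)
  4 * (center_wavelength_nm / medium_index) * focal_length_mm /
    (pi * beam_diameter_pupil_mm) / 1e3
}

#' Depth pixel pitch of a protocol
#'
#' Optical depth per pixel, `imaging_depth_mm * 1000 / samples_per_ascan`,
#' in um.
#'
#' @param p A `scan_protocol`.
#' @return um (optical path) per depth pixel.
#' @export
depth_pixel_pitch <- function(p) {
  stopifnot(inherits(p, "scan_protocol"))
  p$imaging_depth_mm * 1000 / p$samples_per_ascan
}

#' Report all derived protocol quantities
#'
#' Convenience summary used by the pipeline runner: evaluates every
#' closed-form calculator on a protocol.
#'
#' @param p A `scan_protocol`.
#' @return A one-row `data.frame` of derived quantities.
#' @export
protocol_report <- function(p) {
  stopifnot(inherits(p, "scan_protocol"))
  data.frame(
    volume_acquisition_time_s = volume_acquisition_time(p),
    volume_rate_hz = volume_rate(p),
    axial_resolution_air_um = axial_resolution(p),
    depth_pixel_pitch_um = depth_pixel_pitch(p),
    imaging_depth_mm = p$imaging_depth_mm
  )
}
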