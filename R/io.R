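# Volume readers/writers (multi-page TIFF or NIfTI plus a JSON metadata
# sidecar), YAML/JSON configuration, and the pipeline runner binding the
# modules together.

SIDECAR_SCHEMA_VERSION <- 1L

sidecar_path <- function(path) paste0(path, ".json")

volume_metadata <- function(vol) {
  list(schema_version = SIDECAR_SCHEMA_VERSION,
       kind = vol$kind,
       dims = dim(vol$intensity),
       alpha_fast_deg = vol$alpha_fast_deg,
       alpha_slow_deg = vol$alpha_slow_deg,
       depth_pixel_pitch_um_optical = vol$depth_pixel_pitch_um,
       reference_arm_position_mm = vol$reference_arm_position_mm,
       opl_factor = vol$opl_factor,
       zero_delay_opl_mm = vol$zero_delay_opl_mm,
       geom = list(radius_mm = vol$geom$radius_mm,
                   pivot_offset_mm = vol$geom$pivot_offset_mm,
                   pivot_half_angle_max_deg = vol$geom$pivot_half_angle_max_deg,
                   medium_index = vol$geom$medium_index),
       noise_floor = vol$noise_floor,
       seed = vol$seed)
}

#' Write a fan-beam volume to disk
#'
#' Intensity goes to a multi-page TIFF (one 32-bit-float page per B-scan,
#' intensities scaled to the unit interval with the scale recorded in the
#' sidecar) or to a NIfTI file (64-bit float, lossless); all `fan_volume`
#' metadata goes to a JSON sidecar at `<path>.json`. Simulation ground
#' truth (`$truth`) is deliberately not serialised — it is not acquisition
#' metadata.
#'
#' @param vol A `fan_volume`.
#' @param path Output path; extension `.tif`/`.tiff` selects the TIFF
#'   backend, `.nii`/`.nii.gz` the NIfTI backend.
#' @return `path`, invisibly.
#' @export
write_fan_volume <- function(vol, path) {
  stopifnot(inherits(vol, "fan_volume"))
  meta <- volume_metadata(vol)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    d <- dim(vol$intensity)
    scale <- max(vol$intensity, 1e-300)
    pages <- lapply(seq_len(d[1]), function(i)
      matrix(vol$intensity[i, , ] / scale, nrow = d[2]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
    meta$backend <- "tiff"
    meta$intensity_scale <- scale
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(vol$intensity, datatype = "double"),
                       path, datatype = "double")
    meta$backend <- "nifti"
  } else {
    stop("unsupported volume extension (use .tif/.tiff or .nii/.nii.gz): ",
         path, call. = FALSE)
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fan-beam volume written by [write_fan_volume()]
#'
#' @param path Path to the TIFF or NIfTI volume; the JSON sidecar
#'   `<path>.json` must sit next to it.
#' @return A `fan_volume`.
#' @export
read_fan_volume <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing metadata sidecar: ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || is.null(meta$dims) ||
      is.null(meta$backend))
    stop("corrupted or incomplete sidecar: ", sc, call. = FALSE)
  dims <- as.integer(meta$dims)
  if (identical(meta$backend, "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != dims[1])
      stop("volume/sidecar shape mismatch in ", path, call. = FALSE)
    I <- array(0, dims)
    for (i in seq_along(pages)) I[i, , ] <- pages[[i]] * meta$intensity_scale
  } else if (identical(meta$backend, "nifti")) {
    I <- array(as.numeric(RNifti::readNifti(path)), dim = dims)
  } else stop("unknown backend in sidecar: ", meta$backend, call. = FALSE)
  if (!identical(dim(I), dims))
    stop("volume/sidecar shape mismatch in ", path, call. = FALSE)
  geom <- scan_geometry(meta$geom$radius_mm, meta$geom$pivot_offset_mm,
                        meta$geom$pivot_half_angle_max_deg,
                        meta$geom$medium_index)
  fan_volume(I, meta$kind, as.numeric(meta$alpha_fast_deg),
             as.numeric(meta$alpha_slow_deg),
             meta$depth_pixel_pitch_um_optical,
             meta$reference_arm_position_mm, meta$opl_factor,
             meta$zero_delay_opl_mm, geom, meta$noise_floor, meta$seed)
}

#' Read a YAML or JSON configuration file
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return The parsed list.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json: ", path, call. = FALSE)
}

config_eye <- function(cfg) {
  if (is.null(cfg$eye) || identical(cfg$eye, "gullstrand_newborn"))
    return(gullstrand_newborn())
  if (is.character(cfg$eye)) stop("unknown eye preset: ", cfg$eye, call. = FALSE)
  schematic_eye(lapply(cfg$eye, function(s)
    ocular_segment(s$name, s$thickness_mm, s$index)))
}

config_geometry <- function(cfg, eye) {
  g <- cfg$geometry
  if (is.null(g)) return(default_newborn_geometry(eye))
  r <- if (!is.null(g$radius_mm)) g$radius_mm else total_axial_length(eye) / 2
  fov <- if (!is.null(g$fov_deg)) g$fov_deg else 140
  n <- if (!is.null(g$medium_index)) g$medium_index
       else average_refractive_index(eye)
  a <- if (isTRUE(g$pivot_at_iris)) {
    nm <- vapply(eye$segments, `[[`, character(1), "name")
    r - sum(seg_thicknesses(eye)[nm %in% c("CT", "ACD")])
  } else if (!is.null(g$pivot_offset_mm)) g$pivot_offset_mm else 0
  scan_geometry(r, a, fov / 2, medium_index = n)
}

config_protocol <- function(cfg) {
  p <- cfg$protocol
  if (is.null(p)) return(scan_protocol())
  do.call(scan_protocol, p)
}

config_scene <- function(cfg, eye, geom) {
  s <- if (is.null(cfg$scene)) list() else cfg$scene
  lesions <- list()
  if (!is.null(s$lesions))
    lesions <- lapply(s$lesions, function(l) do.call(lesion, l))
  layers <- if (!is.null(s$layers))
    do.call(rbind, lapply(s$layers, as.data.frame)) else default_layer_stack()
  synthetic_scene(
    eye = eye, geom = geom, layers = layers, lesions = lesions,
    speckle_mode = if (!is.null(s$speckle_mode)) s$speckle_mode else "none",
    rolloff_db_per_mm = if (!is.null(s$rolloff_db_per_mm))
      s$rolloff_db_per_mm else 0,
    noise_floor = if (!is.null(s$noise_floor)) s$noise_floor else 0,
    seed = if (!is.null(s$seed)) s$seed else cfg$seed)
}

#' Run a pipeline command from a configuration
#'
#' Programmatic entry point tying the modules together. Commands:
#' \describe{
#'   \item{simulate}{Generate a synthetic retina volume from the scene
#'     block and write it (with sidecar) to the output directory.}
#'   \item{biometry}{Measure axial length. Either reads `volumes$cornea`
#'     and `volumes$retina` paths, or simulates a pair when
#'     `biometry$true_al_mm` is given. Writes `biometry.json`.}
#'   \item{morphometry}{Lesion morphometry of a retina volume (path in
#'     `volumes$retina`, otherwise simulated from the scene). Writes
#'     `morphometry.csv`.}
#'   \item{calibrate-fov}{Phantom ring calibration table. Writes
#'     `fov_calibration.csv`.}
#'   \item{protocol-report}{Derived protocol quantities. Writes
#'     `protocol_report.csv`.}
#' }
#' All outputs are deterministic given the config seed.
#'
#' @param config A configuration list or a path to a YAML/JSON file.
#'   Recognised blocks: `eye`, `geometry`, `protocol`, `scene`,
#'   `biometry`, `phantom`, `volumes`, `seed`, `output_dir`.
#' @param command One of the commands above.
#' @param output_dir Output directory (default from config, else tempdir).
#' @return List of computed results (also written to files), invisibly
#'   where large.
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "biometry", "morphometry",
                                     "calibrate-fov", "protocol-report"),
                         output_dir = NULL) {
  command <- match.arg(command)
  cfg <- if (is.character(config)) read_config_file(config) else config
  if (!is.list(cfg)) stop("invalid configuration", call. = FALSE)
  out <- output_dir %||% cfg$output_dir %||% tempfile("panoct-run-")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  eye <- config_eye(cfg)
  geom <- config_geometry(cfg, eye)
  protocol <- config_protocol(cfg)

  if (command == "protocol-report") {
    rep <- protocol_report(protocol)
    utils::write.csv(rep, file.path(out, "protocol_report.csv"),
                     row.names = FALSE)
    return(rep)
  }

  if (command == "calibrate-fov") {
    ph <- cfg$phantom %||% list()
    rings <- phantom_ring_angles(ph$radius_mm %||% 12,
                                 ph$ring_interval_deg %||% 40, geom)
    utils::write.csv(rings, file.path(out, "fov_calibration.csv"),
                     row.names = FALSE)
    return(rings)
  }

  if (command == "simulate") {
    if (is.null(cfg$seed) && is.null(cfg$scene$seed))
      stop("a seed is mandatory for simulation", call. = FALSE)
    scene <- config_scene(cfg, eye, geom)
    vol <- generate_retina_volume(scene, protocol)
    path <- file.path(out, cfg$volume_file %||% "retina.nii")
    write_fan_volume(vol, path)
    return(invisible(list(volume = vol, path = path)))
  }

  if (command == "biometry") {
    b <- cfg$biometry %||% list()
    if (!is.null(cfg$volumes$cornea) && !is.null(cfg$volumes$retina)) {
      cornea <- read_fan_volume(cfg$volumes$cornea)
      retina <- read_fan_volume(cfg$volumes$retina)
      pair <- list(cornea = cornea, retina = retina,
                   stage_cornea_mm = cornea$reference_arm_position_mm,
                   stage_retina_mm = retina$reference_arm_position_mm,
                   opl_factor = cornea$opl_factor, eye = eye)
    } else if (!is.null(b$true_al_mm)) {
      if (is.null(cfg$seed)) stop("a seed is mandatory", call. = FALSE)
      pair <- simulate_biometry_pair(b$true_al_mm, seed = cfg$seed,
                                     opl_factor = b$opl_factor %||% 1)
      eye <- pair$eye
    } else stop("biometry needs volume paths or biometry$true_al_mm",
                call. = FALSE)
    res <- measure_biometry_pair(pair)
    report <- list(stage_cornea_mm = pair$stage_cornea_mm,
                   stage_retina_mm = pair$stage_retina_mm,
                   apex_depth_um = res$record$apex_depth_um,
                   fovea_depth_um = res$record$fovea_depth_um,
                   opl_factor = res$record$opl_factor,
                   opl_mm = res$opl_mm,
                   n_avg = average_refractive_index(eye),
                   axial_length_mm = res$axial_length_mm)
    jsonlite::write_json(report, file.path(out, "biometry.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(report)
  }

  # morphometry
  if (!is.null(cfg$volumes$retina)) {
    vol <- read_fan_volume(cfg$volumes$retina)
  } else {
    if (is.null(cfg$seed) && is.null(cfg$scene$seed))
      stop("a seed is mandatory for simulation", call. = FALSE)
    scene <- config_scene(cfg, eye, geom)
    vol <- generate_retina_volume(scene, protocol)
  }
  m <- cfg$morphometry %||% list()
  res <- measure_volume_lesions(vol,
                                min_height_mm = m$min_height_mm %||% 0.1,
                                min_area_mm2 = m$min_area_mm2 %||% 0.5,
                                mode = m$mode %||% "arc")
  tab <- res$measurements
  if (is.null(tab)) tab <- data.frame()
  utils::write.csv(tab, file.path(out, "morphometry.csv"), row.names = FALSE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
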