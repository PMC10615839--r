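#' Construct an ocular segment
#'
#' One axial segment of a schematic eye: a slab of given thickness and
#' refractive index crossed by the imaging beam along the visual axis.
#'
#' @param name Segment label. Conventional labels are `"CT"` (corneal
#'   thickness), `"ACD"` (anterior chamber depth), `"LT"` (lens thickness),
#'   `"VCD"` (vitreous chamber depth) and `"RT"` (retinal thickness), but any
#'   non-empty string is accepted.
#' @param thickness_mm Axial thickness in millimetres; must be positive.
#' @param index Group refractive index; must lie in (1, 2).
#' @return An object of class `ocular_segment`.
#' @export
#' @examples
#' ocular_segment("CT", 0.75, 1.377)
ocular_segment <- function(name, thickness_mm, index) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string", call. = FALSE)
  thickness_mm <- as.numeric(thickness_mm)
  index <- as.numeric(index)
  if (!is.finite(thickness_mm) || thickness_mm <= 0)
    stop("segment thickness must be positive", call. = FALSE)
  if (!is.finite(index) || index <= 1 || index >= 2)
    stop("refractive index must lie strictly between 1 and 2", call. = FALSE)
  structure(list(name = name, thickness_mm = thickness_mm, index = index),
            class = "ocular_segment")
}

#' Construct a schematic eye from ordered ocular segments
#'
#' A schematic eye is an ordered anterior-to-posterior list of ocular
#' segments. It determines the axial length (sum of thicknesses) and the
#' thickness-weighted average refractive index used to convert optical path
#' length to geometric length.
#'
#' @param segments List of [ocular_segment()] objects, anterior first.
#' @return An object of class `schematic_eye`.
#' @seealso [gullstrand_newborn()] for the built-in newborn preset,
#'   [average_refractive_index()], [total_axial_length()].
#' @export
schematic_eye <- function(segments) {
  if (!is.list(segments) || length(segments) == 0L)
    stop("'segments' must be a non-empty list of ocular segments", call. = FALSE)
  ok <- vapply(segments, inherits, logical(1), what = "ocular_segment")
  if (!all(ok))
    stop("all elements of 'segments' must be ocular_segment objects", call. = FALSE)
  structure(list(segments = segments), class = "schematic_eye")
}

#' Gullstrand schematic eye of the newborn infant
#'
#' Built-in preset with the five ocular segments of the newborn Gullstrand
#' reduced eye: cornea (0.75 mm, n = 1.377), anterior chamber (1.85 mm,
#' n = 1.336), lens (3.7 mm, n = 1.43), vitreous chamber (11.0 mm,
#' n = 1.334) and retina (0.15 mm, n = 1.346). Total axial length 17.45 mm,
#' average index 1.357 (3 d.p.).
#'
#' @param scale Optional uniform scale factor applied to all segment
#'   thicknesses (indices unchanged), e.g. to emulate an eye of a different
#'   axial length while keeping newborn proportions. Default 1.
#' @return A `schematic_eye`.
#' @export
#' @examples
#' eye <- gullstrand_newborn()
#' average_refractive_index(eye)  # 1.357 to 3 decimals
#' total_axial_length(eye)        # 17.45 mm
gullstrand_newborn <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale), scale > 0)
  schematic_eye(list(
    ocular_segment("CT",  0.75 * scale, 1.377),
    ocular_segment("ACD", 1.85 * scale, 1.336),
    ocular_segment("LT",  3.70 * scale, 1.430),
    ocular_segment("VCD", 11.0 * scale, 1.334),
    ocular_segment("RT",  0.15 * scale, 1.346)
  ))
}

#' @export
print.schematic_eye <- function(x, ...) {
  cat("Schematic eye:", length(x$segments), "segments\n")
  df <- data.frame(
    segment = vapply(x$segments, `[[`, character(1), "name"),
    thickness_mm = vapply(x$segments, `[[`, numeric(1), "thickness_mm"),
    index = vapply(x$segments, `[[`, numeric(1), "index")
  )
  print(df, row.names = FALSE)
  cat(sprintf("axial length: %.4g mm   n_avg: %.4f\n",
              total_axial_length(x), average_refractive_index(x)))
  invisible(x)
}

seg_thicknesses <- function(eye) vapply(eye$segments, `[[`, numeric(1), "thickness_mm")
seg_indices <- function(eye) vapply(eye$segments, `[[`, numeric(1), "index")

#' Thickness-weighted average refractive index of a schematic eye
#'
#' Computes `n_avg = sum(n_i * d_i) / sum(d_i)` over the ocular segments.
#' This is the conversion factor between optical path length measured by OCT
#' and the geometric axial length of the eye.
#'
#' @param eye A `schematic_eye`.
#' @return Average refractive index (dimensionless, full precision).
#' @export
average_refractive_index <- function(eye) {
  stopifnot(inherits(eye, "schematic_eye"))
  d <- seg_thicknesses(eye)
  n <- seg_indices(eye)
  sum(n * d) / sum(d)
}

#' Total axial length of a schematic eye
#'
#' Sum of segment thicknesses, anterior corneal surface to the posterior
#' boundary of the last segment. With the retinal segment included the
#' length is referenced to the retinal pigment epithelium; set
#' `include_retina = FALSE` for an inner-limiting-membrane-referenced length
#' (the ocular-ultrasound convention).
#'
#' @param eye A `schematic_eye`.
#' @param include_retina Include the `"RT"` segment, if present (default
#'   `TRUE`).
#' @return Axial length in mm.
#' @export
total_axial_length <- function(eye, include_retina = TRUE) {
  stopifnot(inherits(eye, "schematic_eye"))
  d <- seg_thicknesses(eye)
  if (!include_retina) {
    nm <- vapply(eye$segments, `[[`, character(1), "name")
    d <- d[nm != "RT"]
  }
  sum(d)
}

#' Convert optical path length to geometric length
#'
#' OCT interferometry measures optical path length (OPL); dividing by the
#' average refractive index of the traversed media yields geometric length
#' (GL): `GL = OPL / n_avg`.
#'
#' @param opl_mm Optical path length in mm; positive.
#' @param n_avg Average refractive index; must exceed 1. May also be a
#'   `schematic_eye`, in which case its average index is used.
#' @return Geometric length in mm.
#' @export
#' @examples
#' opl_to_geometric(23.68, 1.357)
opl_to_geometric <- function(opl_mm, n_avg) {
  if (inherits(n_avg, "schematic_eye")) n_avg <- average_refractive_index(n_avg)
  if (any(!is.finite(opl_mm)) || any(opl_mm <= 0))
    stop("'opl_mm' must be positive", call. = FALSE)
  if (!is.finite(n_avg) || n_avg <= 1)
    stop("'n_avg' must exceed 1", call. = FALSE)
  opl_mm / n_avg
}

#' Convert geometric length to optical path length
#'
#' Inverse of [opl_to_geometric()]: `OPL = GL * n_avg`.
#'
#' @param gl_mm Geometric length in mm; positive.
#' @inheritParams opl_to_geometric
#' @return Optical path length in mm.
#' @export
geometric_to_opl <- function(gl_mm, n_avg) {
  if (inherits(n_avg, "schematic_eye")) n_avg <- average_refractive_index(n_avg)
  if (any(!is.finite(gl_mm)) || any(gl_mm <= 0))
    stop("'gl_mm' must be positive", call. = FALSE)
  if (!is.finite(n_avg) || n_avg <= 1)
    stop("'n_avg' must exceed 1", call. = FALSE)
  gl_mm * n_avg
}

#' Read a schematic eye from a YAML or JSON description
#'
#' The file holds a list of segments, each with fields `name`,
#' `thickness_mm` and `index`, anterior first. A top-level key `segments`
#' wrapping that list is also accepted.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `schematic_eye`.
#' @export
read_schematic_eye <- function(path) {
  spec <- read_config_file(path)
  if (is.list(spec) && !is.data.frame(spec) && !is.null(spec$segments))
    spec <- spec$segments
  if (is.data.frame(spec))             # JSON arrays simplify to a data frame
    spec <- lapply(seq_len(nrow(spec)), function(i) as.list(spec[i, ]))
  if (length(spec) == 0L) stop("no segments found in ", path, call. = FALSE)
  schematic_eye(lapply(spec, function(s)
    ocular_segment(s$name, s$thickness_mm, s$index)))
}
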