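# Curvature-aware lesion morphometry: surface segmentation, fan-to-Cartesian
# scan conversion, robust sphere fitting, elevation mapping and geodesic
# length/width/height measurement.

#' Segment the retinal surface of a fan-beam volume
#'
#' Per-A-scan brightest-layer depth (the RPE band) refined to sub-pixel by
#' an intensity-weighted centroid, followed by a 5 x 5 median filter on the
#' angular grid. Pixels whose peak does not clear the detection threshold
#' are marked invalid.
#'
#' @param vol A `fan_volume` of kind `"retina"` or `"phantom"`.
#' @param median_window Odd window size of the 2-D median filter
#'   (default 5).
#' @param threshold Detection threshold; default 6 dB above the noise
#'   floor (5% of the maximum for noiseless volumes).
#' @param max_invalid_frac Error out when more than this fraction of
#'   pixels is invalid (default 0.5).
#' @return An object of class `surface_map`: `depth_um` and `valid`
#'   matrices (n_bscans x n_ascans) plus the scan metadata needed for
#'   conversion.
#' @export
segment_surface <- function(vol, median_window = 5L,
                            threshold = detection_threshold(vol),
                            max_invalid_frac = 0.5) {
  stopifnot(inherits(vol, "fan_volume"))
  d <- dim(vol$intensity)
  m <- matrix(vol$intensity, nrow = d[1] * d[2])
  depth <- surface_depths_matrix(m, vol$depth_pixel_pitch_um, threshold,
                                 mode = "brightest")
  depth <- matrix(depth, nrow = d[1])
  valid <- !is.na(depth)
  if (mean(!valid) > max_invalid_frac)
    stop(sprintf("surface segmentation failed: %.0f%% of A-scans below threshold",
                 100 * mean(!valid)), call. = FALSE)
  if (median_window > 1L) depth <- medfilt2(depth, median_window)
  structure(list(depth_um = depth, valid = valid & !is.na(depth),
                 alpha_fast_deg = vol$alpha_fast_deg,
                 alpha_slow_deg = vol$alpha_slow_deg,
                 zero_delay_opl_mm = vol$zero_delay_opl_mm,
                 geom = vol$geom,
                 depth_pixel_pitch_um = vol$depth_pixel_pitch_um),
            class = "surface_map")
}

# 2-D median filter with edge replication; NAs are median-ignored.
medfilt2 <- function(x, w = 5L) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(outer(seq_len(nr), (-h):h, `+`), 1L), nr)
  ci <- pmin(pmax(outer(seq_len(nc), (-h):h, `+`), 1L), nc)
  out <- x
  stack <- array(NA_real_, c(nr, nc, w * w))
  k <- 0L
  for (i in seq_len(w)) for (j in seq_len(w)) {
    k <- k + 1L
    stack[, , k] <- x[ri[, i], ci[, j]]
  }
  apply(stack, c(1, 2), stats::median, na.rm = TRUE)
}

#' Convert a segmented surface to a Cartesian point cloud
#'
#' Maps each (slow angle, fast angle, depth) sample to 3-D coordinates in
#' mm: the point lies on the ray `P + t * D(alpha_fast, alpha_slow)` at
#' chord `t = (depth + z0) / n`, where `z0` is the volume's zero-delay
#' optical path from the pivot and `n` the medium index. The eye centre C
#' is the origin and the pivot sits at `(0, 0, a)`.
#'
#' @param surface A `surface_map` (or anything with the same fields).
#' @param geom Optional `scan_geometry` override.
#' @param medium_index Optional medium-index override.
#' @return `data.frame(x, y, z, slow, fast, valid)`, one row per grid
#'   pixel (slow index varying fastest).
#' @export
scan_convert <- function(surface, geom = surface$geom,
                         medium_index = geom$medium_index) {
  depth_mm <- as.vector(surface$depth_um) / 1000
  ns <- length(surface$alpha_slow_deg)
  nf <- length(surface$alpha_fast_deg)
  AF <- rep(surface$alpha_fast_deg, each = ns)
  AS <- rep(surface$alpha_slow_deg, times = nf)
  D <- ray_direction(AF, AS)
  t_mm <- (depth_mm + surface$zero_delay_opl_mm) / medium_index
  data.frame(x = t_mm * D[, 1], y = t_mm * D[, 2],
             z = geom$pivot_offset_mm + t_mm * D[, 3],
             slow = rep(seq_len(ns), times = nf),
             fast = rep(seq_len(nf), each = ns),
             valid = as.vector(surface$valid))
}

#' Map Cartesian points back to fan-beam coordinates
#'
#' Inverse of [scan_convert()]: recovers the fast/slow pivot angles and
#' the optical depth of each point. Round-trips with [scan_convert()] to
#' machine precision.
#'
#' @param points Matrix or data frame with columns x, y, z (mm, eye-centre
#'   origin).
#' @param geom A `scan_geometry`.
#' @param zero_delay_opl_mm Zero-delay optical path of the target volume.
#' @param medium_index Medium index (defaults to the geometry's).
#' @return `data.frame(alpha_fast_deg, alpha_slow_deg, depth_um)`.
#' @export
fan_coordinates <- function(points, geom, zero_delay_opl_mm,
                            medium_index = geom$medium_index) {
  p <- as.matrix(points[, c("x", "y", "z"), drop = FALSE])
  rel <- cbind(p[, 1], p[, 2], p[, 3] - geom$pivot_offset_mm)
  t_mm <- sqrt(rowSums(rel^2))
  D <- rel / t_mm
  af <- asin(pmin(1, pmax(-1, D[, 1])))
  as_ <- atan2(D[, 2], -D[, 3])
  data.frame(alpha_fast_deg = rad2deg(af), alpha_slow_deg = rad2deg(as_),
             depth_um = (t_mm * medium_index - zero_delay_opl_mm) * 1000)
}

#' Least-squares sphere fit with robust reweighting
#'
#' Algebraic (linearised) least-squares sphere followed by geometric
#' refinement (Gauss-Newton on the centre; the radius is the weighted mean
#' distance). Two robust passes down-weight points whose residual exceeds
#' three times the median absolute deviation, so elevated lesion regions
#' do not bias the fitted globe.
#'
#' @param points Matrix or data frame with columns x, y, z (mm); rows with
#'   NA are dropped.
#' @param robust Apply the MAD-based reweighting passes (default TRUE).
#' @param weights Optional starting weights.
#' @return An object of class `sphere_fit`: `center` (xyz, mm), `radius`
#'   (mm), `rms_mm` (weighted RMS residual), `weights`.
#' @export
fit_sphere <- function(points, robust = TRUE, weights = NULL) {
  p <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  keep <- stats::complete.cases(p)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 10) stop("need at least 10 points to fit a sphere", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(p))
  sv <- svd(scale(p, scale = FALSE))$d
  if (sv[3] < 1e-9 * sv[1])
    stop("degenerate (coplanar) points: sphere fit is not identifiable",
         call. = FALSE)

  fit_once <- function(w) {
    A <- cbind(2 * p, 1)
    y <- rowSums(p^2)
    sw <- sqrt(w)
    b <- stats::lm.fit(A * sw, y * sw)$coefficients
    ctr <- b[1:3]
    r <- sqrt(b[4] + sum(ctr^2))
    # geometric refinement: Gauss-Newton on the centre
    for (it in 1:25) {
      dif <- sweep(p, 2, ctr)
      di <- sqrt(rowSums(dif^2))
      r <- sum(w * di) / sum(w)
      res <- di - r
      J <- -dif / di                       # d(di)/d(ctr)
      g <- crossprod(J, w * res)
      H <- crossprod(J * sqrt(w))
      step <- tryCatch(solve(H, g), error = function(e) g * 0)
      ctr <- ctr - as.vector(step)
      if (sqrt(sum(step^2)) < 1e-10) break
    }
    dif <- sweep(p, 2, ctr)
    di <- sqrt(rowSums(dif^2))
    r <- sum(w * di) / sum(w)
    list(center = ctr, radius = r, residuals = di - r, weights = w)
  }

  f <- fit_once(weights)
  if (robust) {
    for (pass in 1:2) {
      mad <- stats::mad(f$residuals)
      w <- if (mad > 0) as.numeric(abs(f$residuals) <= 3 * mad) else weights
      if (sum(w) < 10) break
      f <- fit_once(pmax(w, 1e-6))
    }
  }
  structure(list(center = unname(f$center), radius = unname(f$radius),
                 rms_mm = sqrt(sum(f$weights * f$residuals^2) / sum(f$weights)),
                 weights = f$weights, kept = keep),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("Sphere fit: centre (%.4g, %.4g, %.4g) mm, radius %.5g mm, RMS %.3g um\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms_mm * 1000))
  invisible(x)
}

#' Elevation of surface points above a fitted sphere
#'
#' Signed radial elevation `radius - |point - centre|`, positive toward
#' the pivot (inward), the direction intraocular lesions elevate. The
#' baseline retina maps to approximately zero.
#'
#' @param points Point cloud from [scan_convert()].
#' @param sphere A `sphere_fit`.
#' @return `data.frame` as `points` with an `elevation_mm` column.
#' @export
elevation_map <- function(points, sphere) {
  p <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  di <- sqrt(rowSums(sweep(p, 2, sphere$center)^2))
  out <- as.data.frame(points)
  out$elevation_mm <- sphere$radius - di
  out
}

# Log-map grid pixels (rows of elev, grid order) into the tangent plane at
# cdir with basis (e1, e2); returns n x 2 geodesic coordinates (mm).
logmap_pixels <- function(idx, elev, sphere, cdir, e1, e2) {
  p <- as.matrix(elev[idx, c("x", "y", "z")])
  rel <- sweep(p, 2, sphere$center)
  U <- rel / sqrt(rowSums(rel^2))
  cosps <- pmin(1, pmax(-1, U %*% cdir))
  psi <- acos(cosps)
  V <- U - cosps %*% t(cdir)
  vn <- sqrt(rowSums(V^2))
  scl <- ifelse(vn > 0, sphere$radius * psi / vn, 0)
  cbind(scl * (V %*% e1), scl * (V %*% e2))
}

# Sub-pixel boundary points of a thresholded footprint: for every
# inside/outside 4-neighbour pair, place a point where linear interpolation
# of the elevation crosses the threshold.
boundary_points <- function(footprint, elev, sphere, cdir, e1, e2,
                            threshold_mm, ns, nf) {
  emat <- matrix(NA_real_, ns, nf)
  emat[cbind(elev$slow, elev$fast)] <- elev$elevation_mm
  inside <- footprint > 0
  out <- matrix(numeric(0), ncol = 2)
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    ij <- which(inside, arr.ind = TRUE)
    nb <- cbind(ij[, 1] + d[1], ij[, 2] + d[2])
    ok <- nb[, 1] >= 1 & nb[, 1] <= ns & nb[, 2] >= 1 & nb[, 2] <= nf
    ij <- ij[ok, , drop = FALSE]; nb <- nb[ok, , drop = FALSE]
    e_in <- emat[ij]; e_out <- emat[nb]
    cross <- is.finite(e_out) & !inside[nb] & e_out < threshold_mm &
      e_in >= threshold_mm
    if (!any(cross)) next
    ij <- ij[cross, , drop = FALSE]; nb <- nb[cross, , drop = FALSE]
    e_in <- e_in[cross]; e_out <- e_out[cross]
    # crossing fraction: linear interpolation toward the outside pixel,
    # tightened by gradient extrapolation from the next pixel inward
    # (steep dome edges die off well inside the pixel gap)
    lam <- (e_in - threshold_mm) / (e_in - e_out)
    pv <- cbind(pmin(pmax(ij[, 1] - d[1], 1L), ns),
                pmin(pmax(ij[, 2] - d[2], 1L), nf))
    e_prev <- emat[pv]
    grad_ok <- is.finite(e_prev) & e_prev > e_in
    lam_ex <- ifelse(grad_ok, (e_in - threshold_mm) / (e_prev - e_in), lam)
    lam <- pmax(0, pmin(lam, lam_ex, 1))
    i_in <- ij[, 1] + (ij[, 2] - 1L) * ns
    i_out <- nb[, 1] + (nb[, 2] - 1L) * ns
    i_prev <- pv[, 1] + (pv[, 2] - 1L) * ns
    S_in <- logmap_pixels(i_in, elev, sphere, cdir, e1, e2)
    S_out <- logmap_pixels(i_out, elev, sphere, cdir, e1, e2)
    S_prev <- logmap_pixels(i_prev, elev, sphere, cdir, e1, e2)
    # at grazing incidence the first outside pixel can land far beyond an
    # elevated cap (its ray clears the cap and hits the sphere in the
    # shadow zone); trust the interior pixel spacing as the step scale
    d_out <- S_out - S_in
    n_out <- sqrt(rowSums(d_out^2))
    n_prev <- sqrt(rowSums((S_in - S_prev)^2))
    scale <- pmin(n_out, ifelse(n_prev > 0, n_prev, n_out))
    step <- d_out * ifelse(n_out > 0, scale / n_out, 0)
    out <- rbind(out, S_in + lam * step)
  }
  out
}

# 8-connected component labelling on a logical matrix (two-pass union-find).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j]) next
    nb <- integer(0)
    if (i > 1L && lab[i - 1L, j]) nb <- c(nb, lab[i - 1L, j])
    if (j > 1L) {
      if (lab[i, j - 1L]) nb <- c(nb, lab[i, j - 1L])
      if (lab[i - 1L, j - 1L] && i > 1L) nb <- c(nb, lab[i - 1L, j - 1L])
      if (i < nr && lab[i + 1L, j - 1L]) nb <- c(nb, lab[i + 1L, j - 1L])
    }
    if (!length(nb)) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else {
      roots <- vapply(unique(nb), find, integer(1))
      r0 <- min(roots)
      lab[i, j] <- r0
      for (r in roots) parent[r] <- r0
    }
  }
  if (nxt) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    nz <- lab > 0L
    lab[nz] <- relab[lab[nz]]
  }
  lab
}

# Per-pixel surface area (mm^2) of the scan grid mapped onto the fitted
# sphere, via central differences of the projected points.
pixel_areas <- function(points, sphere, ns, nf) {
  p <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  rel <- sweep(p, 2, sphere$center)
  di <- sqrt(rowSums(rel^2))
  proj <- sweep(rel * (sphere$radius / di), 2, sphere$center, `+`)
  X <- array(proj, c(ns, nf, 3))
  d_slow <- (X[pmin(seq_len(ns) + 1L, ns), , , drop = FALSE] -
             X[pmax(seq_len(ns) - 1L, 1L), , , drop = FALSE]) /
    rep(pmin(seq_len(ns) + 1L, ns) - pmax(seq_len(ns) - 1L, 1L), nf * 3)
  d_fast <- (X[, pmin(seq_len(nf) + 1L, nf), , drop = FALSE] -
             X[, pmax(seq_len(nf) - 1L, 1L), , drop = FALSE])
  steps <- pmin(seq_len(nf) + 1L, nf) - pmax(seq_len(nf) - 1L, 1L)
  d_fast <- d_fast / rep(rep(steps, each = ns), 3)
  cr1 <- d_slow[, , 2] * d_fast[, , 3] - d_slow[, , 3] * d_fast[, , 2]
  cr2 <- d_slow[, , 3] * d_fast[, , 1] - d_slow[, , 1] * d_fast[, , 3]
  cr3 <- d_slow[, , 1] * d_fast[, , 2] - d_slow[, , 2] * d_fast[, , 1]
  A <- sqrt(cr1^2 + cr2^2 + cr3^2)
  # cells bordering invalid pixels get the median finite area
  A[!is.finite(A)] <- stats::median(A[is.finite(A)])
  A
}

#' Detect elevated lesions on an elevation map
#'
#' Thresholds the elevation map, labels 8-connected components on the
#' angular grid, computes each component's on-sphere footprint area and
#' discards components smaller than `min_area_mm2`.
#'
#' @param elev Output of [elevation_map()] carrying `slow`, `fast`,
#'   `valid` and `elevation_mm` columns for a full scan grid.
#' @param sphere The `sphere_fit` used for the elevation map.
#' @param min_height_mm Elevation threshold, mm.
#' @param min_area_mm2 Minimum footprint area on the sphere, mm^2.
#' @return List with `labels` (n_slow x n_fast integer matrix, 0 =
#'   background) and `areas_mm2` (named vector per label).
#' @export
detect_lesions <- function(elev, sphere, min_height_mm = 0.1,
                           min_area_mm2 = 0.5) {
  ns <- max(elev$slow); nf <- max(elev$fast)
  emat <- matrix(NA_real_, ns, nf)
  emat[cbind(elev$slow, elev$fast)] <- elev$elevation_mm
  vmat <- matrix(FALSE, ns, nf)
  vmat[cbind(elev$slow, elev$fast)] <- elev$valid
  mask <- !is.na(emat) & vmat & emat > min_height_mm
  lab <- label_components(mask)
  if (!any(lab > 0L)) return(list(labels = lab, areas_mm2 = numeric(0)))
  area <- matrix(pixel_areas(elev, sphere, ns, nf), ns, nf)
  areas <- tapply(area[lab > 0L], lab[lab > 0L], sum)
  keep <- as.integer(names(areas)[areas >= min_area_mm2])
  lab[!(lab %in% keep)] <- 0L
  relab <- match(lab, sort(unique(lab[lab > 0L])))
  lab2 <- matrix(ifelse(is.na(relab), 0L, relab), ns, nf)
  list(labels = lab2,
       areas_mm2 = as.numeric(areas[as.character(sort(keep))]))
}

#' Measure a lesion's length, width and height on the fitted sphere
#'
#' Height is the maximum elevation inside the footprint. Length and width
#' are the extents of the footprint along the principal axes of its
#' area-weighted second-moment ellipse, measured as geodesic (great-circle
#' arc) distances on the fitted sphere via the log map at the footprint
#' centroid; `mode = "chord"` reports straight-line chords instead.
#'
#' @param footprint Logical or 0/1 matrix (n_slow x n_fast) selecting the
#'   lesion's pixels, e.g. `labels == k` from [detect_lesions()].
#' @param elev Output of [elevation_map()] for the same grid.
#' @param sphere The `sphere_fit`.
#' @param mode `"arc"` (default, along-surface) or `"chord"`.
#' @param boundary_elev_mm Elevation threshold that produced the
#'   footprint; when given, the footprint boundary is refined to
#'   sub-pixel accuracy by interpolating the threshold crossing between
#'   grid neighbours before extents are taken.
#' @return One-row `data.frame(length_mm, width_mm, height_mm,
#'   center_central_angle_deg, azimuth_deg, area_mm2)`.
#' @export
measure_lesion <- function(footprint, elev, sphere, mode = c("arc", "chord"),
                           boundary_elev_mm = NULL) {
  mode <- match.arg(mode)
  ns <- nrow(footprint); nf <- ncol(footprint)
  sel <- footprint[cbind(elev$slow, elev$fast)] > 0
  if (!any(sel)) stop("empty lesion footprint", call. = FALSE)
  pts <- as.matrix(elev[sel, c("x", "y", "z")])
  w <- pixel_areas(elev, sphere, ns, nf)[sel]
  height <- max(elev$elevation_mm[sel])

  rel <- sweep(pts, 2, sphere$center)
  U <- rel / sqrt(rowSums(rel^2))
  cdir <- colSums(U * w)
  cdir <- cdir / sqrt(sum(cdir^2))
  # tangent basis at the centroid
  ref <- if (abs(cdir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * cdir) * cdir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(cdir[2] * e1[3] - cdir[3] * e1[2],
          cdir[3] * e1[1] - cdir[1] * e1[3],
          cdir[1] * e1[2] - cdir[2] * e1[1])
  cosps <- pmin(1, pmax(-1, U %*% cdir))
  psi <- acos(cosps)
  V <- U - cosps %*% t(cdir)
  vn <- sqrt(rowSums(V^2))
  scl <- ifelse(vn > 0, sphere$radius * psi / vn, 0)
  S <- cbind(scl * (V %*% e1), scl * (V %*% e2))

  mu <- colSums(S * w) / sum(w)
  Sc <- sweep(S, 2, mu)
  M <- crossprod(Sc * sqrt(w)) / sum(w)
  ev <- eigen(M, symmetric = TRUE)
  proj <- Sc %*% ev$vectors
  # sub-pixel footprint boundary: interpolate the elevation threshold
  # crossing between footprint pixels and their outside grid neighbours
  if (!is.null(boundary_elev_mm)) {
    B <- boundary_points(footprint, elev, sphere, cdir, e1, e2,
                         boundary_elev_mm, ns, nf)
    if (nrow(B)) proj <- rbind(proj, sweep(B, 2, mu) %*% ev$vectors)
  }
  ext <- apply(proj, 2, function(s) diff(range(s)))
  len <- max(ext); wid <- min(ext)
  if (mode == "chord") {
    len <- 2 * sphere$radius * sin(min(len / (2 * sphere$radius), pi / 2))
    wid <- 2 * sphere$radius * sin(min(wid / (2 * sphere$radius), pi / 2))
  }
  # location in eye coordinates: central angle from posterior pole, azimuth
  beta <- rad2deg(acos(pmin(1, pmax(-1, -cdir[3]))))
  az <- rad2deg(atan2(cdir[2], cdir[1]))
  data.frame(length_mm = len, width_mm = wid, height_mm = height,
             center_central_angle_deg = beta, azimuth_deg = az,
             area_mm2 = sum(w))
}

#' Full lesion morphometry of a retina volume
#'
#' Runs segmentation, scan conversion, robust sphere fitting, elevation
#' mapping, lesion detection and per-lesion measurement; the end-to-end
#' tumor-size pipeline.
#'
#' @param vol A `fan_volume` of kind `"retina"`.
#' @param min_height_mm,min_area_mm2 Detection thresholds, see
#'   [detect_lesions()].
#' @param mode `"arc"` or `"chord"` extents, see [measure_lesion()].
#' @param median_window Median-filter window for segmentation. Detection
#'   and extents use this window; lesion heights are re-read from a
#'   lightly filtered (3 x 3) surface because a wide median erodes the
#'   apex of narrow lesions.
#' @return List with `measurements` (data.frame, one row per lesion,
#'   ordered by label), `sphere` (the `sphere_fit`), `labels`, `elevation`
#'   (the elevation data frame) and `surface`.
#' @export
measure_volume_lesions <- function(vol, min_height_mm = 0.1,
                                   min_area_mm2 = 0.5,
                                   mode = c("arc", "chord"),
                                   median_window = 5L) {
  mode <- match.arg(mode)
  surf <- segment_surface(vol, median_window = median_window)
  pts <- scan_convert(surf)
  fitpts <- pts[pts$valid, ]
  sph <- fit_sphere(fitpts)
  elev <- elevation_map(pts, sph)
  det <- detect_lesions(elev, sph, min_height_mm, min_area_mm2)
  meas <- NULL
  labs <- sort(unique(det$labels[det$labels > 0L]))
  if (length(labs)) {
    elev_h <- if (median_window > 3L) {
      surf3 <- segment_surface(vol, median_window = 3L)
      elevation_map(scan_convert(surf3), sph)
    } else elev
    meas <- do.call(rbind, lapply(labs, function(k) {
      m <- measure_lesion(det$labels == k, elev, sph, mode = mode,
                          boundary_elev_mm = min_height_mm)
      sel <- (det$labels == k)[cbind(elev_h$slow, elev_h$fast)] & elev_h$valid
      m$height_mm <- max(elev_h$elevation_mm[sel], na.rm = TRUE)
      cbind(data.frame(label = k), m)
    }))
  }
  list(measurements = meas, sphere = sph, labels = det$labels,
       elevation = elev, surface = surf)
}
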