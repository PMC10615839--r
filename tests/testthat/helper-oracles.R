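# Independent oracles and small fixture builders used across the suite.

# Brute-force ray-sphere intersection: pivot at (0, 0, a), ray at half-angle
# alpha from the posterior direction, sphere of radius r centred at the
# origin. Solves the quadratic with polyroot (independent of the package's
# closed form) and derives chord length and central angle from the hit
# point by plain vector geometry.
ray_sphere_oracle <- function(r, a, alpha_deg) {
  al <- alpha_deg * pi / 180
  P <- c(0, 0, a)
  D <- c(sin(al), 0, -cos(al))
  A <- sum(D * D)
  B <- 2 * sum(P * D)
  C <- sum(P * P) - r^2
  ts <- Re(polyroot(c(C, B, A)))
  t <- max(ts)                       # far intersection (the retina)
  X <- P + t * D
  cosb <- -X[3] / r                  # angle from the posterior pole at C
  list(chord_mm = t,
       beta_half_deg = acos(max(-1, min(1, cosb))) * 180 / pi)
}

# Small, fast protocol for generator tests.
tiny_protocol <- function(nf = 32L, ns = 12L, nd = 400L, depth_mm = 6) {
  scan_protocol(n_ascans_per_bscan = nf, n_bscans = ns,
                samples_per_ascan = nd, imaging_depth_mm = depth_mm)
}

# Narrow-field scene on the newborn eye.
narrow_scene <- function(seed, fov_deg = 20, lesions = list(), ...) {
  eye <- gullstrand_newborn()
  r <- total_axial_length(eye) / 2
  geom <- scan_geometry(r, r - 2.6, fov_deg / 2,
                        medium_index = average_refractive_index(eye))
  synthetic_scene(eye = eye, geom = geom, lesions = lesions, seed = seed, ...)
}
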