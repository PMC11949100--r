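# shared fixtures, all generated in code

# clean (jitter-free) centered phantom with a given invasion depth
clean_phantom <- function(size = 256L, d_frac = 0.75, R = 0.35 * size,
                          dir_deg = 180, pupil_frac = 0.32, seed = 1L) {
  generate_phantom(phantom_spec(
    height_px = size, width_px = size,
    cornea_radius_px = R, pupil_radius_px = pupil_frac * R,
    invasion_direction_deg = dir_deg,
    invasion_distance_px = d_frac * R,
    boundary_jitter_sd_px = 0, seed = seed))
}

# exact circle samples (n points, partial arc coverage)
circle_points <- function(cx, cy, r, n = 100, arc = c(0, 2 * pi)) {
  th <- seq(arc[1], arc[2], length.out = n)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# arc + chord point set: the idealised incomplete corneal contour, with
# a fraction `occ` of the circle replaced by its chord
arc_chord_points <- function(cx, cy, r, occ = 0.3, n = 400, noise = 0,
                             seed = 1L) {
  half <- occ * pi                      # occluded half-angle
  th <- seq(half, 2 * pi - half, length.out = round(n * (1 - occ)))
  arc <- cbind(cx + r * cos(th), cy + r * sin(th))
  d <- r * cos(half)
  hh <- r * sin(half)
  t <- seq(-hh, hh, length.out = round(n * occ))
  chord <- cbind(rep(cx + d, length(t)), cy + t)
  pts <- rbind(arc, chord)
  if (noise > 0) {
    set.seed(seed)
    pts <- pts + matrix(rnorm(length(pts), sd = noise), ncol = 2)
  }
  pts
}

expect_circle_close <- function(fit, cx, cy, r, tol) {
  expect_lt(sqrt(sum((fit$center - c(cx, cy))^2)), tol)
  expect_lt(abs(fit$radius - r), tol)
}
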