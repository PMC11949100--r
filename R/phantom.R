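# Synthetic anterior-segment phantoms
#
# A phantom is a label mask whose invasion geometry is known in closed
# form: a circular cornea of radius R, a pupil disc inside it, and a
# pterygium modelled as the circular cap {p : (p - c) . u >= d} of the
# cornea disc (u = unit invasion direction, d = distance from the corneal
# center to the lesion's leading edge) plus an "apron" continuing outside
# the limbus on the scleral side.  The cap model gives exact expressions
# for the invasion area fraction, the minimum center-to-contour distance
# and the invasion depth ratio, so every downstream measurement can be
# checked against analytic truth.

#' Specify a synthetic anterior-segment phantom
#'
#' @param height_px,width_px Image size in pixels.
#' @param cornea_center Numeric `(x, y)`, 0-based pixel coordinates of the
#'   corneal center.  Default: image center.
#' @param cornea_radius_px Corneal (limbal) radius R in pixels.
#' @param pupil_radius_px Pupil radius in pixels; the pupil disc must lie
#'   entirely inside the cornea disc.
#' @param pupil_offset_px Numeric `(dx, dy)` displacement of the pupil
#'   center from the corneal center.
#' @param invasion_direction_deg Direction the pterygium grows from, in
#'   degrees in `[0, 360)` (0 = from the +x side, measured in image
#'   coordinates with y pointing down).
#' @param invasion_distance_px Distance d from the corneal center to the
#'   pterygium leading edge; values `>= cornea_radius_px` mean no
#'   invasion.
#' @param apron_extent_px How far the pterygium extends beyond the limbus
#'   on the scleral side.
#' @param boundary_jitter_sd_px Standard deviation of the smooth boundary
#'   jitter applied to the limbus and the leading edge (0 = exact
#'   geometry).
#' @param seed Integer seed controlling the jitter; phantoms are fully
#'   deterministic given their spec.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(height_px = 512L, width_px = 512L,
                         cornea_center = c((width_px - 1) / 2,
                                           (height_px - 1) / 2),
                         cornea_radius_px = 0.35 * min(height_px, width_px),
                         pupil_radius_px = 0.32 * cornea_radius_px,
                         pupil_offset_px = c(0, 0),
                         invasion_direction_deg = 180,
                         invasion_distance_px = cornea_radius_px,
                         apron_extent_px = 0.15 * cornea_radius_px,
                         boundary_jitter_sd_px = 1.0,
                         seed = 1L) {
  spec <- list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    cornea_center = as.numeric(cornea_center),
    cornea_radius_px = as.numeric(cornea_radius_px),
    pupil_radius_px = as.numeric(pupil_radius_px),
    pupil_offset_px = as.numeric(pupil_offset_px),
    invasion_direction_deg = as.numeric(invasion_direction_deg) %% 360,
    invasion_distance_px = as.numeric(invasion_distance_px),
    apron_extent_px = as.numeric(apron_extent_px),
    boundary_jitter_sd_px = as.numeric(boundary_jitter_sd_px),
    seed = as.integer(seed))
  if (spec$height_px < 8L || spec$width_px < 8L)
    stop("phantom image must be at least 8x8 pixels", call. = FALSE)
  if (spec$cornea_radius_px <= 0 || spec$pupil_radius_px <= 0)
    stop("radii must be positive", call. = FALSE)
  if (spec$pupil_radius_px >= spec$cornea_radius_px)
    stop("pupil radius must be smaller than cornea radius", call. = FALSE)
  if (sqrt(sum(spec$pupil_offset_px^2)) + spec$pupil_radius_px >
      spec$cornea_radius_px)
    stop("pupil disc must lie entirely inside the cornea disc",
         call. = FALSE)
  if (spec$invasion_distance_px < 0)
    stop("invasion_distance_px must be non-negative", call. = FALSE)
  if (spec$apron_extent_px < 0 || spec$boundary_jitter_sd_px < 0)
    stop("apron extent and boundary jitter must be non-negative",
         call. = FALSE)
  structure(spec, class = "phantom_spec")
}

# area fraction of a disc of radius R cut off by a chord at distance d
# from the center (circular segment on the far side of the chord)
circular_cap_fraction <- function(d, R) {
  d <- pmin(pmax(d, 0), R)
  (R^2 * acos(d / R) - d * sqrt(pmax(R^2 - d^2, 0))) / (pi * R^2)
}

# smooth zero-mean noise with unit sd as a function of a phase variable
smooth_noise <- function(phi, n_harmonics = 6L) {
  a <- rnorm(n_harmonics); b <- rnorm(n_harmonics)
  z <- 0
  for (k in seq_len(n_harmonics))
    z <- z + a[k] * cos(k * phi) + b[k] * sin(k * phi)
  z / sqrt(n_harmonics)
}

#' Generate a phantom label mask with its analytic truth
#'
#' Rasterises the phantom described by `spec` into a label mask (codes as
#' in [ptery_classes()]; pterygium takes precedence over pupil and
#' cornea, so the visible cornea class has an incomplete contour whenever
#' the lesion invades) and computes the closed-form ground truth of the
#' invasion geometry.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements
#'   \describe{
#'     \item{mask}{Integer label matrix `height_px x width_px`.}
#'     \item{truth}{`phantom_truth` list: `alpha_cornea_analytic` (cap
#'       area fraction of the cornea disc), `d_min_true_px`, `beta_true`,
#'       `pupil_cover_fraction`, `pupil_covered_true`, plus the nominal
#'       center/radius of cornea and pupil.}
#'     \item{spec}{The input spec.}
#'   }
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height_px; W <- spec$width_px
  cx <- spec$cornea_center[1]; cy <- spec$cornea_center[2]
  R <- spec$cornea_radius_px
  X <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  Y <- matrix(rep(seq_len(H) - 1, times = W), H, W)
  dx <- X - cx; dy <- Y - cy
  rho <- sqrt(dx^2 + dy^2)
  theta <- spec$invasion_direction_deg * pi / 180
  ux <- cos(theta); uy <- sin(theta)
  s <- dx * ux + dy * uy           # along the invasion axis
  t <- -dx * uy + dy * ux          # tangential coordinate

  jit <- spec$boundary_jitter_sd_px
  if (jit > 0) {
    phi <- atan2(dy, dx)
    r_edge <- with_seed(spec$seed, {
      z1 <- smooth_noise(phi)
      z2 <- smooth_noise(pi * t / (1.5 * R), n_harmonics = 4L)
      list(limbus = R + jit * z1, lead = spec$invasion_distance_px + jit * z2)
    })
    limbus_r <- r_edge$limbus; lead_d <- r_edge$lead
  } else {
    limbus_r <- R; lead_d <- spec$invasion_distance_px
  }

  in_cornea <- rho <= limbus_r
  cap <- in_cornea & (s >= lead_d)
  apron <- !in_cornea & (s >= lead_d) & (rho <= limbus_r + spec$apron_extent_px)
  if (spec$invasion_distance_px >= R && jit == 0) { cap[] <- FALSE; apron[] <- FALSE }
  px <- cx + spec$pupil_offset_px[1]; py <- cy + spec$pupil_offset_px[2]
  in_pupil <- (X - px)^2 + (Y - py)^2 <= spec$pupil_radius_px^2

  codes <- ptery_classes()
  mask <- matrix(codes[["background"]], H, W)
  mask[in_cornea] <- codes[["cornea"]]
  mask[in_pupil & in_cornea] <- codes[["pupil"]]
  mask[cap | apron] <- codes[["pterygium"]]
  storage.mode(mask) <- "integer"

  d <- spec$invasion_distance_px
  invades <- d < R
  alpha <- if (invades) circular_cap_fraction(d, R) else 0
  d_min <- if (invades) d else R
  beta <- if (invades) (R - max(min(d, R), 0)) / (2 * R) else 0
  # signed distance from the pupil center to the leading-edge line,
  # positive when the line has not yet reached the pupil center
  h <- d - (spec$pupil_offset_px[1] * ux + spec$pupil_offset_px[2] * uy)
  rp <- spec$pupil_radius_px
  cover <- if (!invades) 0
           else if (h <= -rp) 1
           else if (h >= rp) 0
           else (rp^2 * acos(h / rp) - h * sqrt(rp^2 - h^2)) / (pi * rp^2)
  truth <- structure(list(
    alpha_cornea_analytic = alpha,
    d_min_true_px = d_min,
    beta_true = beta,
    pupil_cover_fraction = cover,
    pupil_covered_true = cover > 0.005,
    pupil_margin_px = h - rp,
    cornea_center = c(cx, cy), cornea_radius_px = R,
    pupil_center = c(px, py), pupil_radius_px = rp),
    class = "phantom_truth")
  list(mask = mask, truth = truth, spec = spec)
}

#' True clinical grade of a phantom for a given reference diameter
#'
#' Applies the clinical rule to the analytic truth: grade 3 when the cap
#' covers more than `epsilon_fraction` of the pupil disc, grade 2 when
#' the invasion depth `beta_true * reference_diameter_mm` exceeds 3 mm,
#' grade 1 otherwise.
#'
#' @param truth A `phantom_truth` (from [generate_phantom()]).
#' @param reference_diameter_mm Assumed adult corneal diameter in mm.
#' @param epsilon_fraction Pupil-coverage tolerance fraction.
#' @return Integer grade in `{1, 2, 3}`.
#' @export
phantom_grade <- function(truth, reference_diameter_mm = 11.5,
                          epsilon_fraction = 0.005) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (truth$pupil_cover_fraction > epsilon_fraction) return(3L)
  if (truth$beta_true * reference_diameter_mm > 3) return(2L)
  1L
}

#' Perturb a label mask to emulate segmentation error
#'
#' Two seed-deterministic corruptions: random label flips of a fraction
#' of all pixels (each flipped pixel receives one of the three other
#' classes uniformly), and a morphological erosion (`< 0`) or dilation
#' (`> 0`) of the pterygium region by a disc of the given radius.
#' Eroded pterygium pixels are re-labelled with the locally most common
#' non-pterygium class.
#'
#' @param mask Label matrix.
#' @param flip_fraction Fraction of pixels to flip, in `[0, 1)`.
#' @param boundary_erode_dilate_px Signed radius in pixels.
#' @param seed Integer seed.
#' @return Perturbed label matrix (same class vocabulary).
#' @export
perturb_mask <- function(mask, flip_fraction = 0,
                         boundary_erode_dilate_px = 0L, seed = 1L) {
  mask <- validate_mask(mask)
  if (flip_fraction < 0 || flip_fraction >= 1)
    stop("flip_fraction must be in [0, 1)", call. = FALSE)
  k <- as.integer(boundary_erode_dilate_px)
  codes <- ptery_classes()
  out <- mask
  if (k != 0L) {
    pt <- out == codes[["pterygium"]]
    morphed <- if (k > 0L) binary_dilate(pt, k) else binary_erode(pt, -k)
    if (k > 0L) {
      out[morphed] <- codes[["pterygium"]]
    } else {
      freed <- pt & !morphed
      if (any(freed)) out[freed] <- local_mode_class(out, freed,
                                                    codes[["pterygium"]])
    }
  }
  if (flip_fraction > 0) {
    out <- with_seed(seed, {
      n <- length(out)
      idx <- sample.int(n, size = round(flip_fraction * n))
      others <- vapply(out[idx], function(v)
        sample(setdiff(unname(codes), v), 1L), integer(1))
      out[idx] <- others
      out
    })
  }
  storage.mode(out) <- "integer"
  out
}

# binary dilation/erosion by a disc of radius k, via shifted copies
disc_offsets <- function(k) {
  g <- expand.grid(dy = -k:k, dx = -k:k)
  g[g$dy^2 + g$dx^2 <= k^2, , drop = FALSE]
}

shift_matrix <- function(m, dy, dx, fill = FALSE) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

binary_dilate <- function(m, k) {
  off <- disc_offsets(k)
  out <- m
  for (i in seq_len(nrow(off)))
    out <- out | shift_matrix(m, off$dy[i], off$dx[i], fill = FALSE)
  out
}

binary_erode <- function(m, k) {
  off <- disc_offsets(k)
  out <- m
  for (i in seq_len(nrow(off)))
    out <- out & shift_matrix(m, off$dy[i], off$dx[i], fill = FALSE)
  out
}

# for pixels in `sel`, the most common class != excluded in a 5x5 window
local_mode_class <- function(mask, sel, excluded) {
  codes <- setdiff(unname(ptery_classes()), excluded)
  counts <- matrix(0L, sum(sel), length(codes))
  off <- expand.grid(dy = -2:2, dx = -2:2)
  for (j in seq_along(codes)) {
    acc <- matrix(0L, nrow(mask), ncol(mask))
    is_c <- mask == codes[j]
    for (i in seq_len(nrow(off)))
      acc <- acc + shift_matrix(is_c, off$dy[i], off$dx[i], fill = FALSE)
    counts[, j] <- acc[sel]
  }
  codes[max.col(counts, ties.method = "first")]
}

#' Render a phantom mask as a flat-shaded RGB image
#'
#' Paints each class with its display colour and adds Gaussian pixel
#' noise — the synthetic stand-in for a photograph that the smoke-scale
#' segmentation training consumes.
#'
#' @param mask Label matrix.
#' @param noise_sd Noise standard deviation on the 0-1 intensity scale.
#' @param seed Integer seed.
#' @return Numeric array `H x W x 3` with values in `[0, 1]`.
#' @export
render_phantom_rgb <- function(mask, noise_sd = 0.06, seed = 1L) {
  mask <- validate_mask(mask)
  pal <- ptery_palette() / 255
  img <- array(0, c(nrow(mask), ncol(mask), 3L))
  for (ch in 1:3)
    img[, , ch] <- matrix(pal[mask + 1L, ch], nrow(mask), ncol(mask))
  if (noise_sd > 0)
    img <- with_seed(seed, img + array(rnorm(length(img), sd = noise_sd),
                                       dim = dim(img)))
  pmin(pmax(img, 0), 1)
}

#' Draw a family of random phantom specs
#'
#' Randomises lesion direction, corneal size, pupil geometry and invasion
#' depth, for building seeded phantom cohorts in tests and benchmarks.
#'
#' @param n Number of specs.
#' @param size Image side length in pixels (square phantoms).
#' @param depth_frac_range Range of `invasion_distance_px / R` to sample
#'   uniformly; values above 1 produce lesion-free phantoms.
#' @param boundary_jitter_sd_px Passed to each spec.
#' @param seed Integer seed.
#' @return List of [phantom_spec()] objects.
#' @export
sample_phantom_specs <- function(n, size = 512L,
                                 depth_frac_range = c(0.05, 1.05),
                                 boundary_jitter_sd_px = 1.0, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      R <- runif(1, 0.30, 0.38) * size
      rp <- runif(1, 0.25, 0.35) * R
      off_r <- runif(1, 0, 0.25 * (R - rp))
      off_a <- runif(1, 0, 2 * pi)
      phantom_spec(
        height_px = size, width_px = size,
        cornea_center = c((size - 1) / 2, (size - 1) / 2) +
          runif(2, -0.03, 0.03) * size,
        cornea_radius_px = R, pupil_radius_px = rp,
        pupil_offset_px = off_r * c(cos(off_a), sin(off_a)),
        invasion_direction_deg = runif(1, 0, 360),
        invasion_distance_px = runif(1, depth_frac_range[1],
                                     depth_frac_range[2]) * R,
        boundary_jitter_sd_px = boundary_jitter_sd_px,
        seed = sample.int(.Machine$integer.max, 1L))
    })
  })
}
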