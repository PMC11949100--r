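# Severity quantification and clinical grading.
#
# From a label mask and the robustly restored corneal/pupillary circles:
#   alpha  = A_p / A_c, the fraction of the (restored) corneal disc
#            covered by pterygium, by per-pixel counting;
#   beta   = (L/2 - d_min) / L, the invasion depth ratio, where d_min is
#            the minimum distance from the fitted corneal center to the
#            visible corneal contour and L = 2 * fitted radius;
#   depth  = beta * reference corneal diameter (11.5-12.5 mm in adults).
# Clinical grades: 1 = invasion <= 3 mm; 2 = invasion > 3 mm, pupil
# spared; 3 = pupil covered.

#' Assessment configuration
#'
#' @param weight Weight-function kind for the IRLS fits.
#' @param gamma Tuning constant or `"auto"` (see [weight_spec()]).
#' @param max_iterations IRLS iteration cap (default 10).
#' @param tolerance IRLS early-stopping tolerance in pixels.
#' @param reference_diameter_mm Assumed corneal diameter used to convert
#'   the depth ratio to millimetres; adult range 11.5-12.5 mm, default
#'   11.5 mm.
#' @param pupil_epsilon Fraction of the pupil disc that pterygium must
#'   exceed before the pupil counts as covered (default 0.5%, so
#'   single-pixel segmentation noise cannot trigger grade 3).
#' @param pupil_fallback_ratio Pupil/cornea radius ratio used for the
#'   cornea-concentric pupil prior when the mask has no pupil pixels.
#' @return A `ptery_config` list.
#' @export
assess_config <- function(weight = c("tukey", "huber", "uniform"),
                          gamma = "auto", max_iterations = 10L,
                          tolerance = 1e-6,
                          reference_diameter_mm = 11.5,
                          pupil_epsilon = 0.005,
                          pupil_fallback_ratio = 0.3) {
  weight <- match.arg(weight)
  if (pupil_epsilon < 0 || pupil_epsilon >= 1)
    stop("pupil_epsilon must be in [0, 1)", call. = FALSE)
  structure(list(weight = weight, gamma = gamma,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 reference_diameter_mm = as.numeric(reference_diameter_mm),
                 pupil_epsilon = pupil_epsilon,
                 pupil_fallback_ratio = pupil_fallback_ratio),
            class = "ptery_config")
}

disc_membership <- function(mask, fit) {
  H <- nrow(mask); W <- ncol(mask)
  dx2 <- (seq_len(W) - 1 - fit$center[1])^2
  dy2 <- (seq_len(H) - 1 - fit$center[2])^2
  outer(dy2, dx2, "+") <= fit$radius^2
}

#' Invasion area ratio (per-pixel counting)
#'
#' `A_p` counts pterygium-class pixels whose centers lie inside the
#' fitted disc; `A_c` counts all in-frame pixel centers inside the disc
#' (the restored cornea, not just the visible cornea class).  Returns
#' `A_p / A_c`, with attribute `truncated` set when the fitted disc
#' extends past the image frame (A_c then counts in-frame pixels only).
#'
#' @param mask Label matrix.
#' @param fitted_circle A `circle_fit` (typically the corneal fit).
#' @return Ratio in `[0, 1]`.
#' @export
invasion_area_ratio <- function(mask, fitted_circle) {
  mask <- validate_mask(mask)
  stopifnot(inherits(fitted_circle, "circle_fit"))
  inside <- disc_membership(mask, fitted_circle)
  a_c <- sum(inside)
  if (a_c == 0L)
    stop("disc out of frame: fitted circle contains no in-frame pixels",
         call. = FALSE)
  a_p <- sum(inside & mask == ptery_classes()[["pterygium"]])
  cx <- fitted_circle$center[1]; cy <- fitted_circle$center[2]
  r <- fitted_circle$radius
  truncated <- (cx - r < 0) || (cy - r < 0) ||
    (cx + r > ncol(mask) - 1) || (cy + r > nrow(mask) - 1)
  structure(a_p / a_c, truncated = truncated)
}

#' Invasion depth ratio from the visible corneal contour
#'
#' @param contour `contour_points` (or an `n x 2` point matrix) of the
#'   visible cornea class.
#' @param fitted_circle Corneal `circle_fit`.
#' @return List with `d_min_px` (minimum contour-to-center distance),
#'   `L_px` (fitted corneal diameter `2 * radius`) and `beta`
#'   (`(L/2 - d_min)/L`, clipped to `[0, 0.5]`).
#' @export
invasion_depth <- function(contour, fitted_circle) {
  pts <- as_points_matrix(contour)
  stopifnot(inherits(fitted_circle, "circle_fit"))
  d <- sqrt((pts[, 1] - fitted_circle$center[1])^2 +
            (pts[, 2] - fitted_circle$center[2])^2)
  d_min <- min(d)
  L <- 2 * fitted_circle$radius
  beta <- min(max((L / 2 - d_min) / L, 0), 0.5)
  list(d_min_px = d_min, L_px = L, beta = beta)
}

#' Convert an invasion depth ratio to millimetres
#'
#' @param beta Invasion depth ratio in `[0, 0.5]`.
#' @param reference_diameter_mm Assumed corneal diameter; a warning is
#'   issued outside the adult range 11.5-12.5 mm.
#' @return Depth in mm (`beta * reference_diameter_mm`).
#' @export
physical_depth <- function(beta, reference_diameter_mm = 11.5) {
  if (any(beta < 0)) stop("beta must be non-negative", call. = FALSE)
  if (reference_diameter_mm < 11.5 || reference_diameter_mm > 12.5)
    warning("reference diameter ", reference_diameter_mm,
            " mm is outside the usual adult range 11.5-12.5 mm")
  beta * reference_diameter_mm
}

#' Does the pterygium cover the pupil?
#'
#' TRUE when pterygium-class pixels inside the fitted pupil disc exceed
#' `epsilon_fraction` of the disc's in-frame pixel count.
#'
#' @param mask Label matrix.
#' @param pupil_circle Pupil `circle_fit`.
#' @param epsilon_fraction Coverage tolerance (strict `>`).
#' @return Logical flag, with attribute `fraction` (the measured
#'   coverage fraction).
#' @export
pupil_coverage <- function(mask, pupil_circle, epsilon_fraction = 0.005) {
  mask <- validate_mask(mask)
  stopifnot(inherits(pupil_circle, "circle_fit"))
  inside <- disc_membership(mask, pupil_circle)
  n <- sum(inside)
  if (n == 0L)
    stop("disc out of frame: pupil circle contains no in-frame pixels",
         call. = FALSE)
  frac <- sum(inside & mask == ptery_classes()[["pterygium"]]) / n
  structure(frac > epsilon_fraction, fraction = frac)
}

#' Assign the clinical grade from invasion metrics
#'
#' Grade 3 when the pupil is covered (takes precedence regardless of
#' measured depth); otherwise grade 2 when the physical depth exceeds
#' 3 mm; otherwise grade 1.
#'
#' @param metrics List with at least `depth_mm` and `pupil_covered`.
#' @return A `grade_result`: `grade` in `{1, 2, 3}`, `rule_fired`,
#'   `metrics`.
#' @export
assign_grade <- function(metrics) {
  if (isTRUE(metrics$pupil_covered)) {
    g <- 3L; rule <- "pupil covered (coverage fraction above epsilon)"
  } else if (metrics$depth_mm > 3) {
    g <- 2L
    rule <- sprintf("invasion depth %.3f mm > 3 mm, pupil not covered",
                    metrics$depth_mm)
  } else {
    g <- 1L
    rule <- sprintf("invasion depth %.3f mm <= 3 mm", metrics$depth_mm)
  }
  structure(list(grade = g, rule_fired = rule, metrics = metrics),
            class = "grade_result")
}

#' Assess one anterior-segment label mask
#'
#' The full measurement pipeline: extract the cornea (and pupil)
#' contours, restore both circles by robust IRLS fitting, compute the
#' invasion area ratios, the depth ratio and physical depth, decide
#' pupil coverage, and assign the clinical grade.  Deterministic for a
#' fixed mask and configuration.
#'
#' When the mask has no pupil pixels, the pupil circle falls back to a
#' cornea-concentric prior (radius `pupil_fallback_ratio` times the
#' corneal radius) and the result is flagged `pupil_fallback`.
#'
#' @param mask Label matrix (must contain cornea-class pixels).
#' @param config An [assess_config()].
#' @return A `grade_result` whose `metrics` list carries
#'   `alpha_cornea`, `alpha_pupil`, `d_min_px`, `L_px`, `beta`,
#'   `depth_mm`, `reference_diameter_mm`, `pupil_covered`,
#'   `pupil_cover_fraction`, flags (`pupil_fallback`, `disc_truncated`),
#'   and the two fits (`cornea_fit`, `pupil_fit`).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(256, 256, invasion_distance_px = 60,
#'                                     boundary_jitter_sd_px = 0))
#' res <- assess_image(ph$mask)
#' res$grade
assess_image <- function(mask, config = assess_config()) {
  mask <- validate_mask(mask)
  stopifnot(inherits(config, "ptery_config"))
  codes <- ptery_classes()
  if (!any(mask == codes[["cornea"]]))
    stop("unassessable: mask contains no cornea-class pixels",
         call. = FALSE)
  wspec <- weight_spec(config$weight, config$gamma)
  cornea_ct <- extract_class_contour(mask, "cornea")
  cornea_fit <- fit_circle_irls(cornea_ct, wspec,
                                max_iterations = config$max_iterations,
                                tolerance = config$tolerance)
  pupil_fallback <- !any(mask == codes[["pupil"]])
  pupil_fit <- if (pupil_fallback) {
    f <- cornea_fit
    f$radius <- config$pupil_fallback_ratio * cornea_fit$radius
    f$weights <- f$residuals <- numeric(0)
    f$weight_kind <- "prior"
    f
  } else {
    fit_circle_irls(extract_class_contour(mask, "pupil"), wspec,
                    max_iterations = config$max_iterations,
                    tolerance = config$tolerance)
  }
  alpha_c <- invasion_area_ratio(mask, cornea_fit)
  covered <- pupil_coverage(mask, pupil_fit, config$pupil_epsilon)
  dep <- invasion_depth(cornea_ct, cornea_fit)
  depth_mm <- physical_depth(dep$beta, config$reference_diameter_mm)
  metrics <- list(
    alpha_cornea = as.numeric(alpha_c),
    alpha_pupil = attr(covered, "fraction"),
    d_min_px = dep$d_min_px, L_px = dep$L_px, beta = dep$beta,
    depth_mm = depth_mm,
    reference_diameter_mm = config$reference_diameter_mm,
    pupil_covered = as.logical(covered),
    pupil_cover_fraction = attr(covered, "fraction"),
    pupil_fallback = pupil_fallback,
    disc_truncated = isTRUE(attr(alpha_c, "truncated")),
    cornea_fit = cornea_fit, pupil_fit = pupil_fit)
  assign_grade(metrics)
}

#' @export
print.grade_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<grade_result> grade %d  (%s)\n", x$grade, x$rule_fired))
  cat(sprintf("  alpha_cornea=%.4f  beta=%.4f  depth=%.3f mm  pupil %s\n",
              m$alpha_cornea, m$beta, m$depth_mm,
              if (m$pupil_covered) "covered" else "spared"))
  invisible(x)
}
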