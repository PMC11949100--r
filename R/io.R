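# Mask and report I/O.
#
# Masks travel as lossless 8-bit PNG: grayscale PNGs carry the raw class
# codes 0..3; RGB PNGs in the default display palette are decoded by
# exact palette inversion.

#' Read a label mask from PNG
#'
#' @param path Path to a grayscale (codes 0..3) or RGB
#'   (default-palette colours) PNG.
#' @return Validated integer label matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: no file at ", path,
                               call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    mask <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  } else {
    rgb <- round(img[, , 1:3] * 255)
    pal <- ptery_palette()
    key <- rgb[, , 1] * 65536 + rgb[, , 2] * 256 + rgb[, , 3]
    palkey <- pal[, 1] * 65536 + pal[, 2] * 256 + pal[, 3]
    code <- match(key, palkey) - 1L
    if (anyNA(code)) {
      bad <- unique(key[is.na(code)])
      stop("mask contains ", length(bad),
           " RGB value(s) outside the class palette", call. = FALSE)
    }
    mask <- matrix(code, dim(img)[1], dim(img)[2])
  }
  validate_mask(mask, where = basename(path))
}

#' Write a label mask as grayscale PNG
#'
#' @param mask Label matrix.
#' @param path Output path.
#' @param rgb Write display-palette RGB instead of raw codes.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, rgb = FALSE) {
  mask <- validate_mask(mask)
  if (rgb) {
    pal <- ptery_palette() / 255
    img <- array(0, c(nrow(mask), ncol(mask), 3L))
    for (ch in 1:3)
      img[, , ch] <- matrix(pal[mask + 1L, ch], nrow(mask), ncol(mask))
    png::writePNG(img, path)
  } else {
    png::writePNG(mask / 255, path)
  }
  invisible(path)
}

report_fields <- function(result) {
  m <- result$metrics
  list(
    tool = "pterygrade", version = .ptery_version(),
    grade = result$grade, rule_fired = result$rule_fired,
    alpha_cornea = m$alpha_cornea, alpha_pupil = m$alpha_pupil,
    d_min_px = m$d_min_px, L_px = m$L_px, beta = m$beta,
    depth_mm = m$depth_mm,
    reference_diameter_mm = m$reference_diameter_mm,
    pupil_covered = m$pupil_covered,
    pupil_cover_fraction = m$pupil_cover_fraction,
    pupil_fallback = m$pupil_fallback,
    disc_truncated = m$disc_truncated,
    cornea_fit = list(center = m$cornea_fit$center,
                      radius = m$cornea_fit$radius,
                      n_iterations = m$cornea_fit$n_iterations,
                      converged = m$cornea_fit$converged,
                      weight_kind = m$cornea_fit$weight_kind,
                      n_points = length(m$cornea_fit$residuals),
                      rejected_fraction =
                        if (length(m$cornea_fit$weights))
                          mean(m$cornea_fit$weights < 1e-6) else 0),
    pupil_fit = list(center = m$pupil_fit$center,
                     radius = m$pupil_fit$radius,
                     weight_kind = m$pupil_fit$weight_kind))
}

#' Write an assessment report as JSON
#'
#' Schema-stable JSON carrying the grade, every invasion metric, fit
#' diagnostics, the configuration echo and the tool version.
#'
#' @param result A `grade_result` from [assess_image()].
#' @param path Output path.
#' @param config Optional [assess_config()] echoed into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, config = NULL) {
  stopifnot(inherits(result, "grade_result"))
  rep <- report_fields(result)
  if (!is.null(config)) rep$config <- unclass(config)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back an assessment report
#' @param path JSON report path.
#' @return Named list.
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Read a flat key/value run configuration file
#'
#' YAML (or JSON) document whose keys override [assess_config()]
#' defaults; unknown keys are rejected.
#'
#' @param path Config file path.
#' @return An [assess_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(assess_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(assess_config, raw)
}
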