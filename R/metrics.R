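# Segmentation-quality and grading-agreement metrics.

#' Per-class segmentation metrics
#'
#' One-vs-rest pixel counts and the derived overlap metrics:
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `IoU = TP/(TP+FP+FN)`, `Dice = 2TP/(2TP+FP+FN)`.
#' Convention for degenerate cases: when the class is absent from both
#' prediction and truth every metric is 1 (flagged `undefined`); a
#' zero-denominator metric is otherwise reported as 0 (also flagged).
#'
#' @param pred,truth Label matrices of identical shape.
#' @param class Class name or code.
#' @return A `class_metrics` list: `class_code`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `iou`, `dice`, `undefined`.
#' @export
per_class_metrics <- function(pred, truth, class) {
  pred <- validate_mask(pred, "pred")
  truth <- validate_mask(truth, "truth")
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth masks must have the same shape", call. = FALSE)
  code <- class_code(class)
  p <- pred == code; t <- truth == code
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  undefined <- FALSE
  if (tp + fp + fn == 0L) {
    undefined <- TRUE
    prec <- rec <- iou <- dice <- 1
  } else {
    rat <- function(num, den) {
      if (den == 0L) { undefined <<- TRUE; 0 } else num / den
    }
    prec <- rat(tp, tp + fp)
    rec <- rat(tp, tp + fn)
    iou <- tp / (tp + fp + fn)
    dice <- 2 * tp / (2 * tp + fp + fn)
  }
  structure(list(class_code = code, tp = tp, fp = fp, fn = fn,
                 precision = prec, recall = rec, iou = iou, dice = dice,
                 undefined = undefined),
            class = "class_metrics")
}

#' Grading agreement summary
#'
#' Confusion matrix (rows = expert grade, columns = predicted grade),
#' overall accuracy, weighted F1 (per-class F1 weighted by the expert
#' class prevalence), and Cohen's kappa with chance agreement
#' `P_e = sum_k row_k * col_k / N^2`.
#'
#' @param pred_grades,expert_grades Equal-length vectors of grades in
#'   `{1, 2, 3}`.
#' @param reference_diameter_mm Optional reference diameter recorded
#'   with the summary.
#' @return A `grading_summary`: `confusion` (3x3), `accuracy`,
#'   `weighted_f1`, `kappa`, `per_class_f1`, `n`,
#'   `reference_diameter_mm`.
#' @export
grading_summary <- function(pred_grades, expert_grades,
                            reference_diameter_mm = NA_real_) {
  pred <- as.integer(pred_grades); expert <- as.integer(expert_grades)
  if (length(pred) == 0L || length(pred) != length(expert))
    stop("pred and expert grade vectors must be non-empty and of equal length",
         call. = FALSE)
  if (!all(c(pred, expert) %in% 1:3))
    stop("grades must be in {1, 2, 3}", call. = FALSE)
  conf <- table(factor(expert, levels = 1:3),
                factor(pred, levels = 1:3))
  conf <- matrix(as.integer(conf), 3, 3,
                 dimnames = list(expert = 1:3, predicted = 1:3))
  n <- sum(conf)
  acc <- sum(diag(conf)) / n
  rs <- rowSums(conf); cs <- colSums(conf)
  f1 <- vapply(1:3, function(k) {
    den <- rs[k] + cs[k]                 # 2TP + FP + FN
    if (den == 0) 0 else 2 * conf[k, k] / den
  }, numeric(1))
  w <- rs / n
  wf1 <- sum(w * f1)
  pe <- sum(rs * cs) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) {
    if (abs(acc - 1) < 1e-15) 1 else NaN
  } else (acc - pe) / (1 - pe)
  structure(list(confusion = conf, accuracy = acc, weighted_f1 = wf1,
                 kappa = kappa, per_class_f1 = f1, n = n,
                 reference_diameter_mm = reference_diameter_mm),
            class = "grading_summary")
}

#' @export
print.grading_summary <- function(x, ...) {
  cat(sprintf(
    "<grading_summary> n=%d  accuracy=%.4f  weighted F1=%.4f  kappa=%.4f\n",
    x$n, x$accuracy, x$weighted_f1, x$kappa))
  print(x$confusion)
  invisible(x)
}

#' Reference-diameter sweep of grading agreement
#'
#' Each case's mask is assessed once (the fitted geometry, `beta` and
#' the pupil-coverage flag do not depend on the reference diameter); the
#' grade is then re-derived for every diameter in the sweep and compared
#' with the expert grade.  Because grade 3 is decided purely by pupil
#' coverage, grade-3 assignments are identical across diameters and the
#' diameter only moves the grade-1/grade-2 boundary.
#'
#' @param cases List of cases, each a list with `mask` (label matrix)
#'   and `expert_grade` (1, 2 or 3).
#' @param l_min,l_max,step Sweep over reference diameters in mm.
#' @param config Base [assess_config()] (its `reference_diameter_mm` is
#'   overridden by the sweep).
#' @return Data frame with columns `reference_diameter_mm`, `accuracy`,
#'   `weighted_f1`, `kappa`; attribute `summaries` holds the full
#'   `grading_summary` per diameter and attribute `pred_grades` the
#'   per-diameter predicted-grade matrix.
#' @export
diameter_sweep <- function(cases, l_min = 11.5, l_max = 12.5, step = 0.1,
                           config = assess_config()) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (length(cases) < 1L) stop("need at least one case", call. = FALSE)
  diam <- seq(l_min, l_max, by = step)
  assessed <- lapply(cases, function(cs) assess_image(cs$mask, config))
  expert <- vapply(cases, function(cs) as.integer(cs$expert_grade),
                   integer(1))
  grade_at <- function(res, L) {
    m <- res$metrics
    m$depth_mm <- physical_depth(m$beta, L)
    assign_grade(m)$grade
  }
  preds <- vapply(diam, function(L)
    vapply(assessed, grade_at, integer(1), L = L),
    integer(length(cases)))
  preds <- matrix(preds, nrow = length(cases),
                  dimnames = list(NULL, sprintf("%.1f", diam)))
  summaries <- lapply(seq_along(diam), function(j)
    grading_summary(preds[, j], expert, reference_diameter_mm = diam[j]))
  out <- data.frame(
    reference_diameter_mm = diam,
    accuracy = vapply(summaries, `[[`, numeric(1), "accuracy"),
    weighted_f1 = vapply(summaries, `[[`, numeric(1), "weighted_f1"),
    kappa = vapply(summaries, `[[`, numeric(1), "kappa"))
  attr(out, "summaries") <- summaries
  attr(out, "pred_grades") <- preds
  out
}
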