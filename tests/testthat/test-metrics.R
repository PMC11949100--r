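test_that("per-class metrics: identity and disjoint masks", {
  m <- matrix(sample(0:3, 256, TRUE), 16)
  for (cl in 0:3) {
    pm <- per_class_metrics(m, m, cl)
    expect_equal(c(pm$iou, pm$dice, pm$precision, pm$recall),
                 rep(1, 4))
  }
  a <- matrix(0L, 8, 8); a[1:4, ] <- 1L
  b <- matrix(0L, 8, 8); b[5:8, ] <- 1L
  pm <- per_class_metrics(a, b, 1L)
  expect_equal(c(pm$iou, pm$dice, pm$precision, pm$recall), rep(0, 4))
})

test_that("an 8x8 square shifted by 2 px gives the hand-counted overlap", {
  truth <- matrix(0L, 16, 16); truth[3:10, 3:10] <- 1L
  pred <- matrix(0L, 16, 16); pred[5:12, 3:10] <- 1L
  pm <- per_class_metrics(pred, truth, 1L)
  expect_equal(pm$tp, 48L)
  expect_equal(pm$fp, 16L)
  expect_equal(pm$fn, 16L)
  expect_equal(pm$iou, 0.6)
  expect_equal(pm$dice, 0.75)
})

test_that("degenerate classes follow the stated convention", {
  a <- matrix(0L, 4, 4)
  both_empty <- per_class_metrics(a, a, 2L)
  expect_true(both_empty$undefined)
  expect_equal(both_empty$dice, 1)
  b <- a; b[1, 1] <- 2L
  one_empty <- per_class_metrics(a, b, 2L)
  expect_true(one_empty$undefined)       # zero-denominator precision
  expect_equal(one_empty$dice, 0)
  expect_error(per_class_metrics(matrix(0L, 3, 3), a, 1L), "shape")
})

test_that("Dice equals 2 IoU / (1 + IoU) on random and phantom masks", {
  set.seed(5)
  for (i in 1:20) {
    a <- matrix(sample(0:3, 400, TRUE), 20)
    b <- matrix(sample(0:3, 400, TRUE), 20)
    for (cl in 0:3) {
      pm <- per_class_metrics(a, b, cl)
      expect_equal(pm$dice, 2 * pm$iou / (1 + pm$iou), tolerance = 1e-12)
    }
  }
  ph <- clean_phantom(128, d_frac = 0.5)
  pert <- perturb_mask(ph$mask, 0.03, 1L, seed = 4)
  for (cl in 0:3) {
    pm <- per_class_metrics(pert, ph$mask, cl)
    expect_equal(pm$dice, 2 * pm$iou / (1 + pm$iou), tolerance = 1e-12)
  }
})

test_that("perfect agreement scores 1/1/1; chance agreement has kappa 0", {
  g <- rep(1:3, times = c(10, 20, 5))
  s <- grading_summary(g, g)
  expect_equal(s$accuracy, 1)
  expect_equal(s$weighted_f1, 1)
  expect_equal(s$kappa, 1)
  # 2x2 chance case [[25,25],[25,25]] collapsed onto grades 1/2
  expert <- rep(1:2, each = 50)
  pred <- rep(rep(1:2, times = 2), times = c(25, 25, 25, 25))
  s2 <- grading_summary(pred, expert)
  expect_equal(s2$accuracy, 0.5)
  expect_equal(s2$kappa, 0)
})

test_that("summary statistics match caret on a fixed confusion matrix", {
  skip_if_not_installed("caret")
  conf <- matrix(c(40, 4, 0, 6, 58, 2, 0, 3, 12), 3, 3)  # rows = expert
  expert <- rep(1:3, times = rowSums(conf))
  pred <- unlist(lapply(1:3, function(i) rep(1:3, times = conf[i, ])))
  s <- grading_summary(pred, expert)
  expect_equal(unname(s$confusion), unname(conf))
  ref <- caret::confusionMatrix(as.table(t(conf)))  # caret: rows = pred
  expect_equal(s$accuracy, unname(ref$overall["Accuracy"]),
               tolerance = 1e-9)
  expect_equal(s$kappa, unname(ref$overall["Kappa"]), tolerance = 1e-9)
  w <- rowSums(conf) / sum(conf)
  expect_equal(s$weighted_f1, sum(w * ref$byClass[, "F1"]),
               tolerance = 1e-9)
})

test_that("case order does not change the summary", {
  set.seed(9)
  expert <- sample(1:3, 80, TRUE)
  pred <- ifelse(runif(80) < 0.7, expert, sample(1:3, 80, TRUE))
  s1 <- grading_summary(pred, expert)
  o <- sample(80)
  s2 <- grading_summary(pred[o], expert[o])
  expect_equal(s1$confusion, s2$confusion)
  expect_equal(s1$kappa, s2$kappa)
  expect_equal(s1$weighted_f1, s2$weighted_f1)
})

test_that("weighted F1 reduces to the single-class F1 at prevalence 1", {
  expert <- rep(2L, 40)
  pred <- c(rep(2L, 30), rep(1L, 10))
  s <- grading_summary(pred, expert)
  f1_class2 <- 2 * 30 / (2 * 30 + 10 + 0)
  expect_equal(s$weighted_f1, f1_class2)
})

test_that("inputs are validated", {
  expect_error(grading_summary(integer(0), integer(0)), "non-empty")
  expect_error(grading_summary(1:3, 1:2), "equal length")
  expect_error(grading_summary(c(1, 4), c(1, 2)), "grades")
})

test_that("diameter sweep produces 11 rows and only moves the 1/2 boundary", {
  cases <- lapply(c(0.9, 0.55, 0.45, 0.1), function(f) {
    ph <- clean_phantom(256, d_frac = f)
    list(mask = ph$mask, expert_grade = phantom_grade(ph$truth, 11.5))
  })
  tab <- diameter_sweep(cases)
  expect_equal(nrow(tab), 11L)
  expect_equal(tab$reference_diameter_mm, seq(11.5, 12.5, by = 0.1))
  preds <- attr(tab, "pred_grades")
  g3 <- preds == 3L
  expect_true(all(g3 == g3[, 1]))        # grade 3 immune to the diameter
  expect_error(diameter_sweep(cases, step = 0), "positive")
  expect_error(diameter_sweep(list()), "at least one")
})

test_that("a case near the 3 mm boundary flips grade at the predicted diameter", {
  # beta ~= 0.255: grade 1 at 11.5 mm (2.93 mm), grade 2 at 12.5 mm (3.19 mm)
  ph <- clean_phantom(512, d_frac = 1 - 2 * 0.255, R = 180)
  res <- assess_image(ph$mask)
  beta <- res$metrics$beta
  expect_lt(abs(beta - 0.255), 0.005)
  cases <- list(list(mask = ph$mask, expert_grade = 2L))
  tab <- diameter_sweep(cases)
  preds <- attr(tab, "pred_grades")[1, ]
  expect_equal(unname(preds[1]), 1L)
  expect_equal(unname(preds[11]), 2L)
  expect_true(all(diff(preds) >= 0))     # single monotone flip
  # the flip happens where L crosses 3 / beta
  flip_at <- tab$reference_diameter_mm[min(which(preds == 2L))]
  expect_lt(abs(flip_at - 3 / beta), 0.1 + 1e-9)
})
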