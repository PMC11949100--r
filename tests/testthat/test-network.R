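# numeric gradient helper
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
rel_err <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-8)

test_that("csam preserves shape and gates lie in (0, 1)", {
  set.seed(1)
  for (cfg in list(csam_config(deformable = FALSE),
                   csam_config(deformable = TRUE),
                   csam_config(dual_pooling = FALSE,
                               spatial_dw_kernel = 3L))) {
    x <- array(rnorm(12 * 10 * 6), c(12, 10, 6))
    y <- csam_forward(x, cfg, seed = 3)
    expect_equal(dim(y), dim(x))
    p <- pterygrade:::with_seed(3, pterygrade:::csam_p(6, cfg))
    fw <- pterygrade:::csam_fwd(p, x)
    expect_true(all(fw$cache$gate_c > 0 & fw$cache$gate_c < 1))
    expect_true(all(fw$cache$gate_s > 0 & fw$cache$gate_s < 1))
  }
  expect_error(csam_config(spatial_dw_kernel = 4L), "odd")
})

test_that("zero input maps to zero output through the multiplicative gate", {
  x <- array(0, c(8, 8, 4))
  y <- csam_forward(x, csam_config(), seed = 2)
  expect_equal(max(abs(y)), 0)
})

test_that("convolution layers agree with numeric gradients", {
  set.seed(42)
  for (s in 1:2) {
    p <- pterygrade:::conv_p(3L, 3L, 4L, stride = s)
    x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    fw <- pterygrade:::conv_fwd(p, x)
    dy <- array(rnorm(length(fw$y)), dim(fw$y))
    bw <- pterygrade:::conv_bwd(p, fw$cache, dy)
    f_x <- function(v) sum(pterygrade:::conv_fwd(p, array(v, dim(x)))$y * dy)
    f_w <- function(v) {
      p2 <- p; p2$w <- matrix(v, nrow(p$w))
      sum(pterygrade:::conv_fwd(p2, x)$y * dy)
    }
    expect_lt(rel_err(as.vector(bw$dx), num_grad(f_x, as.vector(x))), 1e-6)
    expect_lt(rel_err(as.vector(bw$g$w), num_grad(f_w, as.vector(p$w))), 1e-6)
  }
})

test_that("deformable depthwise convolution agrees with numeric gradients", {
  set.seed(7)
  p <- pterygrade:::deform_dw_p(3L, 2L)
  p$offset$w <- matrix(rnorm(length(p$offset$w), sd = 0.3),
                       nrow(p$offset$w))
  x <- array(rnorm(7 * 7 * 2), c(7, 7, 2))
  fw <- pterygrade:::deform_dw_fwd(p, x)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bw <- pterygrade:::deform_dw_bwd(p, fw$cache, dy)
  f_x <- function(v)
    sum(pterygrade:::deform_dw_fwd(p, array(v, dim(x)))$y * dy)
  f_ow <- function(v) {
    p2 <- p; p2$offset$w <- matrix(v, nrow(p$offset$w))
    sum(pterygrade:::deform_dw_fwd(p2, x)$y * dy)
  }
  expect_lt(rel_err(as.vector(bw$dx), num_grad(f_x, as.vector(x))), 1e-6)
  expect_lt(rel_err(as.vector(bw$g$offset$w),
                    num_grad(f_ow, as.vector(p$offset$w))), 1e-3)
})

test_that("csam backward agrees with numeric gradients", {
  set.seed(11)
  cfg <- csam_config(spatial_dw_kernel = 3L, spatial_dilated_kernel = 3L,
                     deformable = TRUE)
  p <- pterygrade:::with_seed(5, pterygrade:::csam_p(3L, cfg))
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  fw <- pterygrade:::csam_fwd(p, x)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bw <- pterygrade:::csam_bwd(p, fw$cache, dy)
  f_x <- function(v) sum(pterygrade:::csam_fwd(p, array(v, dim(x)))$y * dy)
  expect_lt(rel_err(as.vector(bw$dx), num_grad(f_x, as.vector(x))), 1e-4)
  f_caw <- function(v) {
    p2 <- p; p2$ca$w <- v
    sum(pterygrade:::csam_fwd(p2, x)$y * dy)
  }
  expect_lt(rel_err(bw$g$ca$w, num_grad(f_caw, p$ca$w)), 1e-6)
})

test_that("full-model loss gradient agrees with numeric gradients", {
  set.seed(13)
  cfg <- net_config(input_size_px = c(16L, 16L), base_channels = 2L,
                    embed_dim = 8L, n_transformer = 1L, n_heads = 2L,
                    csam = csam_config(spatial_dw_kernel = 3L,
                                       spatial_dilated_kernel = 3L,
                                       deformable = TRUE))
  m <- build_model(cfg, seed = 5)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  msk <- matrix(sample(0:3, 256, TRUE), 16, 16)
  fw <- pterygrade:::model_forward(m, img, train = TRUE)
  ls <- pterygrade:::combined_loss_grad(fw$scores, msk)
  g <- pterygrade:::model_backward(m, fw$cache, ls$dscores)
  loss_of <- function(mm) {
    f <- pterygrade:::model_forward(mm, img, train = TRUE)
    pterygrade:::combined_loss_grad(f$scores, msk)$loss
  }
  for (pth in c("stem", "down3", "head")) {
    ix <- sample(length(m$params[[pth]]$w), 4)
    gn <- vapply(ix, function(i) {
      m2 <- m; m2$params[[pth]]$w[i] <- m$params[[pth]]$w[i] + 1e-5
      l1 <- loss_of(m2)
      m2$params[[pth]]$w[i] <- m$params[[pth]]$w[i] - 1e-5
      (l1 - loss_of(m2)) / 2e-5
    }, numeric(1))
    expect_lt(rel_err(g[[pth]]$w[ix], gn), 1e-4)
  }
})

test_that("all csam parameters receive non-zero gradients", {
  set.seed(17)
  cfg <- net_config(input_size_px = c(16L, 16L), base_channels = 2L,
                    embed_dim = 8L, n_transformer = 1L, n_heads = 2L,
                    csam = csam_config(spatial_dw_kernel = 3L,
                                       spatial_dilated_kernel = 3L,
                                       deformable = TRUE))
  m <- build_model(cfg, seed = 3)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  msk <- matrix(sample(0:3, 256, TRUE), 16, 16)
  fw <- pterygrade:::model_forward(m, img, train = TRUE)
  ls <- pterygrade:::combined_loss_grad(fw$scores, msk)
  g <- pterygrade:::model_backward(m, fw$cache, ls$dscores)
  all_nonzero <- function(x) {
    if (is.list(x)) return(all(vapply(x, all_nonzero, logical(1))))
    any(x != 0)
  }
  for (cs in c("csam1", "csam2", "csam3"))
    expect_true(all_nonzero(g[[cs]]))
})

test_that("combined loss matches closed forms", {
  # uniform scores over 4 classes: cross-entropy = ln 4
  msk <- matrix(sample(0:3, 64, TRUE), 8, 8)
  sc <- array(0, c(8, 8, 4))
  l <- combined_loss(sc, msk, loss_weights = c(1, 0))
  expect_equal(as.numeric(l), log(4), tolerance = 1e-9)
  expect_equal(attr(l, "cross_entropy"), log(4), tolerance = 1e-9)
  # extreme one-hot-correct scores: loss -> 0
  onehot <- array(-50, c(8, 8, 4))
  for (k in 0:3) {
    pick <- msk == k
    tmp <- onehot[, , k + 1]; tmp[pick] <- 50
    onehot[, , k + 1] <- tmp
  }
  expect_lt(as.numeric(combined_loss(onehot, msk)), 1e-4)
  expect_error(combined_loss(sc, matrix(5L, 8, 8)), "class codes")
  expect_error(combined_loss(sc, matrix(0L, 4, 4)), "spatial size")
})

test_that("loss decreases monotonically from uniform to one-hot scores", {
  ph <- clean_phantom(64, d_frac = 0.5)
  msk <- ph$mask
  target <- array(-8, c(64, 64, 4))
  for (k in 0:3) {
    tmp <- target[, , k + 1]; tmp[msk == k] <- 8
    target[, , k + 1] <- tmp
  }
  lambdas <- seq(0, 1, length.out = 11)
  losses <- vapply(lambdas, function(l)
    as.numeric(combined_loss(l * target, msk)), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("setting loss weights to (1, 0) reproduces pure cross-entropy", {
  set.seed(19)
  sc <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  msk <- matrix(sample(0:3, 64, TRUE), 8, 8)
  l <- combined_loss(sc, msk, loss_weights = c(1, 0))
  expect_equal(as.numeric(l), attr(l, "cross_entropy"), tolerance = 1e-9)
})

test_that("model forward obeys the shape contract and size checks", {
  cfg <- net_config(input_size_px = c(32L, 32L), base_channels = 4L,
                    embed_dim = 16L, n_transformer = 1L,
                    csam = csam_config(spatial_dw_kernel = 3L,
                                       spatial_dilated_kernel = 3L,
                                       deformable = FALSE))
  m <- build_model(cfg, seed = 1)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fw <- pterygrade:::model_forward(m, img)
  expect_equal(dim(fw$scores), c(32L, 32L, 4L))
  expect_error(net_config(input_size_px = c(30L, 32L)), "8")
  expect_error(pterygrade:::model_forward(m, array(0, c(16, 16, 3))),
               "size mismatch")
})

test_that("CSAM adds parameters; disabling it keeps the shape contract", {
  base <- net_config(input_size_px = c(32L, 32L), base_channels = 4L,
                     embed_dim = 16L, n_transformer = 1L, csam = NULL)
  with_att <- net_config(input_size_px = c(32L, 32L), base_channels = 4L,
                         embed_dim = 16L, n_transformer = 1L,
                         csam = csam_config())
  m0 <- build_model(base, seed = 1)
  m1 <- build_model(with_att, seed = 1)
  expect_gt(n_parameters(m1), n_parameters(m0))
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_equal(dim(pterygrade:::model_forward(m0, img)$scores),
               c(32L, 32L, 4L))
})

test_that("prediction is deterministic and emits valid class codes", {
  cfg <- smoke_net_config(input_size_px = c(32L, 32L))
  m <- build_model(cfg, seed = 2)
  ph <- clean_phantom(32, d_frac = 0.5)
  img <- render_phantom_rgb(ph$mask, seed = 1)
  p1 <- predict(m, img)
  p2 <- predict(m, img)
  expect_identical(p1, p2)
  expect_true(all(p1 %in% 0:3))
  expect_equal(dim(p1), c(32L, 32L))
})

test_that("smoke training reduces the loss and checkpoints round-trip", {
  ts <- phantom_training_set(8, 32, seed = 50)
  m <- build_model(smoke_net_config(input_size_px = c(32L, 32L)), seed = 4)
  r <- train_smoke(m, ts, epochs = 4, seed = 5, learning_rate = 2e-3)
  expect_length(r$history, 4L)
  expect_lt(r$history[4], r$history[1])
  expect_error(train_smoke(m, ts[1:3], epochs = 1), "at least 8")
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(r$model, f)
  m2 <- load_checkpoint(f)
  img <- ts[[1]]$image
  expect_identical(predict(r$model, img), predict(m2, img))
  expect_identical(m2$config$input_size_px, c(32L, 32L))
})

test_that("training is seed-deterministic", {
  ts <- phantom_training_set(8, 32, seed = 60)
  m <- build_model(smoke_net_config(input_size_px = c(32L, 32L)), seed = 6)
  r1 <- train_smoke(m, ts, epochs = 2, seed = 7)
  r2 <- train_smoke(m, ts, epochs = 2, seed = 7)
  expect_identical(r1$history, r2$history)
  expect_identical(predict(r1$model, ts[[1]]$image),
                   predict(r2$model, ts[[1]]$image))
})
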