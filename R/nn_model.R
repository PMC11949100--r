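# Hybrid CNN-transformer encoder-decoder for anterior-segment
# segmentation.
#
# Encoder stage 1: a convolutional stem plus pre-activation residual
# blocks at three resolutions (full, 1/2, 1/4), each feeding a skip
# connection.  Encoder stage 2: the 1/8-resolution features are
# flattened into tokens, given a learned positional embedding, and
# passed through multi-head self-attention transformer blocks.  Decoder:
# successive 2x nearest upsampling, with each skip connection refined by
# a CSAM before concatenation.  The head is a 1x1 convolution to
# per-class scores.  Total encoder stride: 8.

#' Network configuration
#'
#' @param input_size_px `(H, W)` of the input images; both must be
#'   divisible by the encoder stride (8).
#' @param n_classes Number of output classes (4: background, pterygium,
#'   pupil, cornea).
#' @param base_channels Channels of the first encoder stage (doubled at
#'   each downsampling).
#' @param embed_dim Transformer token width (default `4 * base_channels`).
#' @param n_transformer Number of transformer blocks.
#' @param n_heads Attention heads (`embed_dim` must be divisible).
#' @param mlp_ratio Width multiplier of the transformer MLP.
#' @param csam A [csam_config()], or `NULL` to disable skip attention
#'   (plain baseline).
#' @param loss_weights `(cross-entropy weight, Dice weight)`; must sum
#'   to 1.
#' @return A `net_config` list.
#' @export
net_config <- function(input_size_px = c(512L, 512L), n_classes = 4L,
                       base_channels = 16L, embed_dim = 4L * base_channels,
                       n_transformer = 2L, n_heads = 4L, mlp_ratio = 2,
                       csam = csam_config(),
                       loss_weights = c(0.5, 0.5)) {
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  if (any(input_size_px %% 8L != 0L))
    stop("input H and W must be divisible by the encoder stride, 8",
         call. = FALSE)
  if (abs(sum(loss_weights) - 1) > 1e-9)
    stop("loss weights must sum to 1", call. = FALSE)
  if (embed_dim %% n_heads != 0L)
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  if (!is.null(csam)) stopifnot(inherits(csam, "csam_config"))
  structure(list(input_size_px = as.integer(input_size_px),
                 n_classes = as.integer(n_classes),
                 base_channels = as.integer(base_channels),
                 embed_dim = as.integer(embed_dim),
                 n_transformer = as.integer(n_transformer),
                 n_heads = as.integer(n_heads), mlp_ratio = mlp_ratio,
                 csam = csam, loss_weights = loss_weights),
            class = "net_config")
}

#' Smoke-scale network configuration
#'
#' The small named configuration exercised on 128 x 128 phantoms: 8 base
#' channels, a 32-wide single transformer block, and a proportionally
#' scaled CSAM (3x3 depthwise + 5x5 dilated depthwise, dilation 2,
#' plain sampling) whose receptive field covers the same fraction of the
#' image as the full-scale 5x5 + 7x7/dilation-3 deformable stages do at
#' 512 x 512 ([fullscale_net_config()]).
#'
#' @param input_size_px `(H, W)` of the input images.
#' @param ... Overrides passed to [net_config()].
#' @export
smoke_net_config <- function(input_size_px = c(128L, 128L), ...) {
  net_config(input_size_px = input_size_px, base_channels = 8L,
             embed_dim = 32L, n_transformer = 1L, n_heads = 4L,
             csam = csam_config(spatial_dw_kernel = 3L,
                                spatial_dilated_kernel = 5L,
                                spatial_dilation = 2L,
                                deformable = FALSE), ...)
}

#' Full-scale network configuration
#'
#' Records the full-resolution training protocol: 512 x 512 inputs,
#' Adam at learning rate 1e-4, 150 epochs over an 85:15 split.  The
#' architecture is buildable and runnable; the protocol fields document
#' the intended full-data regime.
#'
#' @param ... Overrides passed to [net_config()].
#' @export
fullscale_net_config <- function(...) {
  cfg <- net_config(input_size_px = c(512L, 512L), base_channels = 16L,
                    embed_dim = 64L, n_transformer = 2L, ...)
  cfg$protocol <- list(optimizer = "adam", learning_rate = 1e-4,
                       epochs = 150L, train_test_split = c(85L, 15L),
                       augmentation = c("random_horizontal_flip",
                                        "random_vertical_flip"))
  cfg
}

res_block_p <- function(c) list(a = conv_p(3L, c, c), b = conv_p(3L, c, c))

#' Build a segmentation model
#'
#' Initialises all parameters (He initialisation; offset predictors are
#' zero-initialised so deformable stages start as plain depthwise
#' convolutions).
#'
#' @param config A [net_config()].
#' @param seed Integer seed for parameter initialisation.
#' @return A `ptery_model` (list of `config` and `params`).
#' @export
build_model <- function(config = smoke_net_config(), seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  C <- config$base_channels; D <- config$embed_dim
  K <- config$n_classes
  n_tok <- prod(config$input_size_px %/% 8L)
  mk_csam <- function(ch)
    if (is.null(config$csam)) NULL else csam_p(ch, config$csam)
  params <- with_seed(seed, list(
    stem = conv_p(3L, 3L, C),
    enc1 = res_block_p(C),
    down1 = conv_p(3L, C, 2L * C, stride = 2L),
    enc2 = res_block_p(2L * C),
    down2 = conv_p(3L, 2L * C, 4L * C, stride = 2L),
    enc3 = res_block_p(4L * C),
    down3 = conv_p(3L, 4L * C, D, stride = 2L),
    pos = matrix(rnorm(n_tok * D, sd = 0.02), n_tok, D),
    tf = lapply(seq_len(config$n_transformer), function(i) list(
      ln1 = ln_p(D), attn = attn_p(D, config$n_heads),
      ln2 = ln_p(D),
      mlp1 = linear_p(D, round(config$mlp_ratio * D)),
      mlp2 = linear_p(round(config$mlp_ratio * D), D))),
    lnf = ln_p(D),
    dec3_pre = conv_p(3L, D, 4L * C), csam3 = mk_csam(4L * C),
    dec3_post = conv_p(3L, 8L * C, 4L * C),
    dec2_pre = conv_p(3L, 4L * C, 2L * C), csam2 = mk_csam(2L * C),
    dec2_post = conv_p(3L, 4L * C, 2L * C),
    dec1_pre = conv_p(3L, 2L * C, C), csam1 = mk_csam(C),
    dec1_post = conv_p(3L, 2L * C, C),
    head = conv_p(1L, C, K)))
  structure(list(config = config, params = params),
            class = "ptery_model")
}

#' Number of trainable parameters
#' @param model A `ptery_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  count <- function(x, nm = "") {
    if (is.list(x))
      return(sum(vapply(seq_along(x), function(i)
        count(x[[i]], if (is.null(names(x))) "" else names(x)[i]),
        numeric(1))))
    if (is.numeric(x) && nm %in% c("w", "b", "g", "pos")) length(x) else 0
  }
  as.integer(count(model$params))
}

res_block_fwd <- function(p, x, keep = TRUE) {
  r1 <- relu_fwd(x); c1 <- conv_fwd(p$a, r1$y, keep = keep)
  r2 <- relu_fwd(c1$y); c2 <- conv_fwd(p$b, r2$y, keep = keep)
  list(y = x + c2$y,
       cache = if (keep) list(r1 = r1$cache, c1 = c1$cache,
                              r2 = r2$cache, c2 = c2$cache))
}

res_block_bwd <- function(p, cache, dy) {
  b2 <- conv_bwd(p$b, cache$c2, dy)
  d2 <- relu_bwd(cache$r2, b2$dx)
  b1 <- conv_bwd(p$a, cache$c1, d2)
  d1 <- relu_bwd(cache$r1, b1$dx)
  list(dx = dy + d1, g = list(a = b1$g, b = b2$g))
}

tf_block_fwd <- function(p, x, keep = TRUE) {
  l1 <- ln_fwd(p$ln1, x)
  at <- attn_fwd(p$attn, l1$y, keep = keep)
  x2 <- x + at$y
  l2 <- ln_fwd(p$ln2, x2)
  m1 <- linear_fwd(p$mlp1, l2$y)
  mr <- relu_fwd(m1$y)
  m2 <- linear_fwd(p$mlp2, mr$y)
  list(y = x2 + m2$y,
       cache = if (keep) list(l1 = l1$cache, at = at$cache,
                              l2 = l2$cache, m1 = m1$cache,
                              mr = mr$cache, m2 = m2$cache))
}

tf_block_bwd <- function(p, cache, dy) {
  b_m2 <- linear_bwd(p$mlp2, cache$m2, dy)
  d_mr <- relu_bwd(cache$mr, b_m2$dx)
  b_m1 <- linear_bwd(p$mlp1, cache$m1, d_mr)
  b_l2 <- ln_bwd(p$ln2, cache$l2, b_m1$dx)
  dx2 <- dy + b_l2$dx
  b_at <- attn_bwd(p$attn, cache$at, dx2)
  b_l1 <- ln_bwd(p$ln1, cache$l1, b_at$dx)
  list(dx = dx2 + b_l1$dx,
       g = list(ln1 = b_l1$g, attn = b_at$g, ln2 = b_l2$g,
                mlp1 = b_m1$g, mlp2 = b_m2$g))
}

decoder_stage_fwd <- function(pre, csam, post, x, skip, keep = TRUE) {
  up <- upsample2_fwd(x)
  c1 <- conv_fwd(pre, up$y, keep = keep)
  r1 <- relu_fwd(c1$y)
  if (!is.null(csam)) {
    sk <- csam_fwd(csam, skip, keep = keep)
    skv <- sk$y
  } else { sk <- NULL; skv <- skip }
  cat_ <- abind3(r1$y, skv)
  c2 <- conv_fwd(post, cat_, keep = keep)
  r2 <- relu_fwd(c2$y)
  list(y = r2$y,
       cache = if (keep)
         list(up = up$cache, c1 = c1$cache, r1 = r1$cache,
              sk = if (is.null(sk)) NULL else sk$cache,
              c2 = c2$cache, r2 = r2$cache, nc_pre = dim(r1$y)[3]))
}

decoder_stage_bwd <- function(pre, csam, post, cache, dy) {
  d_r2 <- relu_bwd(cache$r2, dy)
  b_c2 <- conv_bwd(post, cache$c2, d_r2)
  nc <- cache$nc_pre
  d_main <- b_c2$dx[, , seq_len(nc), drop = FALSE]
  d_skipin <- b_c2$dx[, , -seq_len(nc), drop = FALSE]
  g_csam <- NULL
  if (!is.null(csam)) {
    b_sk <- csam_bwd(csam, cache$sk, d_skipin)
    d_skip <- b_sk$dx; g_csam <- b_sk$g
  } else d_skip <- d_skipin
  d_r1 <- relu_bwd(cache$r1, d_main)
  b_c1 <- conv_bwd(pre, cache$c1, d_r1)
  dx <- upsample2_bwd(cache$up, b_c1$dx)
  list(dx = dx, d_skip = d_skip,
       g = list(pre = b_c1$g, csam = g_csam, post = b_c2$g))
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

model_forward <- function(model, image, train = FALSE) {
  p <- model$params; cfg <- model$config
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("image must be an H x W x 3 array", call. = FALSE)
  if (any(d[1:2] %% 8L != 0L))
    stop("input H and W must be divisible by the encoder stride, 8",
         call. = FALSE)
  if (!all(d[1:2] == cfg$input_size_px))
    stop("size mismatch: model was built for ",
         paste(cfg$input_size_px, collapse = "x"), " inputs", call. = FALSE)
  keep <- isTRUE(train)
  cc <- list()
  st <- conv_fwd(p$stem, image, keep);  cc$st <- st$cache
  e1 <- res_block_fwd(p$enc1, st$y, keep);  cc$e1 <- e1$cache
  d1 <- conv_fwd(p$down1, e1$y, keep);  cc$d1 <- d1$cache
  d1r <- relu_fwd(d1$y);                cc$d1r <- d1r$cache
  e2 <- res_block_fwd(p$enc2, d1r$y, keep); cc$e2 <- e2$cache
  d2 <- conv_fwd(p$down2, e2$y, keep);  cc$d2 <- d2$cache
  d2r <- relu_fwd(d2$y);                cc$d2r <- d2r$cache
  e3 <- res_block_fwd(p$enc3, d2r$y, keep); cc$e3 <- e3$cache
  d3 <- conv_fwd(p$down3, e3$y, keep);  cc$d3 <- d3$cache
  hw8 <- dim(d3$y)[1:2]
  tok <- matrix(d3$y, prod(hw8), cfg$embed_dim) + p$pos
  tf_caches <- vector("list", cfg$n_transformer)
  for (i in seq_len(cfg$n_transformer)) {
    tb <- tf_block_fwd(p$tf[[i]], tok, keep)
    tok <- tb$y; tf_caches[[i]] <- tb$cache
  }
  cc$tf <- tf_caches
  lf <- ln_fwd(p$lnf, tok);             cc$lf <- lf$cache
  bott <- array(lf$y, c(hw8, cfg$embed_dim))
  s3 <- decoder_stage_fwd(p$dec3_pre, p$csam3, p$dec3_post, bott, e3$y,
                          keep)
  cc$s3 <- s3$cache
  s2 <- decoder_stage_fwd(p$dec2_pre, p$csam2, p$dec2_post, s3$y, e2$y,
                          keep)
  cc$s2 <- s2$cache
  s1 <- decoder_stage_fwd(p$dec1_pre, p$csam1, p$dec1_post, s2$y, e1$y,
                          keep)
  cc$s1 <- s1$cache
  hd <- conv_fwd(p$head, s1$y, keep);   cc$hd <- hd$cache
  cc$hw8 <- hw8
  list(scores = hd$y, cache = if (train) cc else NULL)
}

model_backward <- function(model, cache, dscores) {
  p <- model$params; cfg <- model$config
  g <- list()
  b_hd <- conv_bwd(p$head, cache$hd, dscores); g$head <- b_hd$g
  b_s1 <- decoder_stage_bwd(p$dec1_pre, p$csam1, p$dec1_post, cache$s1,
                            b_hd$dx)
  g$dec1_pre <- b_s1$g$pre; g$csam1 <- b_s1$g$csam
  g$dec1_post <- b_s1$g$post
  b_s2 <- decoder_stage_bwd(p$dec2_pre, p$csam2, p$dec2_post, cache$s2,
                            b_s1$dx)
  g$dec2_pre <- b_s2$g$pre; g$csam2 <- b_s2$g$csam
  g$dec2_post <- b_s2$g$post
  b_s3 <- decoder_stage_bwd(p$dec3_pre, p$csam3, p$dec3_post, cache$s3,
                            b_s2$dx)
  g$dec3_pre <- b_s3$g$pre; g$csam3 <- b_s3$g$csam
  g$dec3_post <- b_s3$g$post
  hw8 <- cache$hw8
  dtok <- matrix(b_s3$dx, prod(hw8), cfg$embed_dim)
  b_lf <- ln_bwd(p$lnf, cache$lf, dtok); g$lnf <- b_lf$g
  dtok <- b_lf$dx
  g$tf <- vector("list", cfg$n_transformer)
  for (i in rev(seq_len(cfg$n_transformer))) {
    tb <- tf_block_bwd(p$tf[[i]], cache$tf[[i]], dtok)
    dtok <- tb$dx; g$tf[[i]] <- tb$g
  }
  g$pos <- dtok
  d_bott <- array(dtok, c(hw8, cfg$embed_dim))
  b_d3 <- conv_bwd(p$down3, cache$d3, d_bott); g$down3 <- b_d3$g
  b_e3 <- res_block_bwd(p$enc3, cache$e3, b_d3$dx + b_s3$d_skip)
  g$enc3 <- b_e3$g
  d_d2r <- relu_bwd(cache$d2r, b_e3$dx)
  b_d2 <- conv_bwd(p$down2, cache$d2, d_d2r); g$down2 <- b_d2$g
  b_e2 <- res_block_bwd(p$enc2, cache$e2, b_d2$dx + b_s2$d_skip)
  g$enc2 <- b_e2$g
  d_d1r <- relu_bwd(cache$d1r, b_e2$dx)
  b_d1 <- conv_bwd(p$down1, cache$d1, d_d1r); g$down1 <- b_d1$g
  b_e1 <- res_block_bwd(p$enc1, cache$e1, b_d1$dx + b_s1$d_skip)
  g$enc1 <- b_e1$g
  b_st <- conv_bwd(p$stem, cache$st, b_e1$dx); g$stem <- b_st$g
  g
}

# ---- loss -----------------------------------------------------------------

softmax_scores <- function(scores) {
  d <- dim(scores)
  s <- matrix(scores, d[1] * d[2], d[3])
  softmax_rows(s)
}

#' Combined cross-entropy + soft-Dice segmentation loss
#'
#' `loss = w_ce * CE + w_dice * (1 - mean over classes of soft Dice)`,
#' with class probabilities from a pixelwise softmax over the score
#' channels.  With the default weights both terms contribute equally.
#'
#' @param predicted_class_scores Numeric array `H x W x K` of class
#'   scores (logits).
#' @param truth Label matrix `H x W` with codes `0..K-1`.
#' @param loss_weights `(ce_weight, dice_weight)`, summing to 1.
#' @return Non-negative scalar loss, with attributes `cross_entropy`
#'   and `dice_loss`.
#' @export
combined_loss <- function(predicted_class_scores, truth,
                          loss_weights = c(0.5, 0.5)) {
  l <- combined_loss_grad(predicted_class_scores, truth, loss_weights)
  structure(l$loss, cross_entropy = l$ce, dice_loss = l$dice_loss)
}

combined_loss_grad <- function(scores, truth, loss_weights = c(0.5, 0.5)) {
  d <- dim(scores); K <- d[3]
  if (!all(dim(truth) == d[1:2]))
    stop("score map and truth mask must have the same spatial size",
         call. = FALSE)
  if (abs(sum(loss_weights) - 1) > 1e-9)
    stop("loss weights must sum to 1", call. = FALSE)
  tv <- as.vector(truth)
  if (any(tv < 0L | tv >= K))
    stop("truth contains class codes outside 0..", K - 1L, call. = FALSE)
  n <- d[1] * d[2]
  p <- softmax_scores(scores)                    # n x K
  ip <- cbind(seq_len(n), tv + 1L)
  ce <- -mean(log(pmax(p[ip], 1e-12)))
  onehot <- matrix(0, n, K); onehot[ip] <- 1
  eps <- 1e-6
  s_pt <- colSums(p * onehot); s_p <- colSums(p); s_t <- colSums(onehot)
  den <- s_p + s_t + eps
  dice_k <- (2 * s_pt + eps) / den
  dice_loss <- 1 - mean(dice_k)
  loss <- loss_weights[1] * ce + loss_weights[2] * dice_loss
  # gradients wrt probabilities, then through the softmax
  dce_dp <- -onehot / pmax(p, 1e-12) / n
  # d(1 - mean_k dice_k)/dp = -(1/K) * (2 t * den - (2 s_pt + eps)) / den^2
  ddice_dp <- -(2 * onehot * rep(den, each = n) -
                rep(2 * s_pt + eps, each = n)) /
    rep(den^2, each = n) / K
  dl_dp <- loss_weights[1] * dce_dp + loss_weights[2] * ddice_dp
  dot <- rowSums(dl_dp * p)
  dlogits <- p * (dl_dp - dot)
  list(loss = loss, ce = ce, dice_loss = dice_loss,
       dscores = array(dlogits, d))
}
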