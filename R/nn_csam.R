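# Channel-and-shape attention module (CSAM).
#
# Applied on each skip connection.  Channel branch first: global average
# and max pooling produce per-channel descriptors, a shared 1D
# convolution over the channel axis (a lightweight replacement for fully
# connected layers) maps each to channel logits, and a logistic gate
# rescales the channels.  Shape (spatial) branch second: a depthwise
# convolution, a depthwise dilated convolution and a 1x1 convolution on
# the channel-refined features produce a single-channel attention map
# whose logistic gate rescales every spatial position.  Both depthwise
# stages can be deformable (learned bilinear sampling offsets), which
# lets the effective kernel adapt to the wing shape of the lesion.

#' CSAM configuration
#'
#' @param channel_kernel Odd length of the 1D convolution over channel
#'   descriptors.
#' @param spatial_dw_kernel Odd kernel of the first (depthwise) spatial
#'   stage.
#' @param spatial_dilated_kernel Odd kernel of the second (depthwise,
#'   dilated) spatial stage.
#' @param spatial_dilation Dilation factor of the second stage.
#' @param deformable Use deformable sampling in the spatial stages.
#' @param dual_pooling Use both average- and max-pooled channel
#'   descriptors (`TRUE`, as in CBAM) or average only.
#' @return A `csam_config` list.
#' @export
csam_config <- function(channel_kernel = 3L, spatial_dw_kernel = 5L,
                        spatial_dilated_kernel = 7L, spatial_dilation = 3L,
                        deformable = TRUE, dual_pooling = TRUE) {
  ks <- c(channel_kernel, spatial_dw_kernel, spatial_dilated_kernel)
  if (any(ks %% 2L == 0L)) stop("kernel sizes must be odd", call. = FALSE)
  if (spatial_dilation < 1L) stop("dilation must be >= 1", call. = FALSE)
  structure(list(channel_kernel = as.integer(channel_kernel),
                 spatial_dw_kernel = as.integer(spatial_dw_kernel),
                 spatial_dilated_kernel = as.integer(spatial_dilated_kernel),
                 spatial_dilation = as.integer(spatial_dilation),
                 deformable = isTRUE(deformable),
                 dual_pooling = isTRUE(dual_pooling)),
            class = "csam_config")
}

csam_p <- function(c, cfg) {
  mk_dw <- function(k, dil) if (cfg$deformable) deform_dw_p(k, c, dil)
                            else dw_p(k, c, dil)
  list(type = "csam", c = c, cfg = cfg,
       ca = list(w = rnorm(cfg$channel_kernel, sd = 0.1),
                 b = 0),
       dw1 = mk_dw(cfg$spatial_dw_kernel, 1L),
       dw2 = mk_dw(cfg$spatial_dilated_kernel, cfg$spatial_dilation),
       pw = conv_p(1L, c, 1L))
}

conv1d_same <- function(w, b, v) {
  k <- length(w); half <- (k - 1L) %/% 2L
  vp <- c(numeric(half), v, numeric(half))
  out <- numeric(length(v))
  for (j in seq_len(k)) out <- out + w[j] * vp[j:(j + length(v) - 1L)]
  out + b
}

conv1d_same_bwd <- function(w, v, dout) {
  k <- length(w); half <- (k - 1L) %/% 2L
  n <- length(v)
  vp <- c(numeric(half), v, numeric(half))
  dw <- vapply(seq_len(k), function(j)
    sum(dout * vp[j:(j + n - 1L)]), numeric(1))
  dvp <- numeric(n + 2L * half)
  for (j in seq_len(k))
    dvp[j:(j + n - 1L)] <- dvp[j:(j + n - 1L)] + w[j] * dout
  list(dw = dw, db = sum(dout), dv = dvp[(half + 1L):(half + n)])
}

csam_fwd <- function(p, x, keep = TRUE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(C == p$c)
  xm <- matrix(x, H * W, C)
  avg <- colMeans(xm)
  logits <- conv1d_same(p$ca$w, p$ca$b, avg)
  mx_arg <- NULL; mx <- NULL
  if (p$cfg$dual_pooling) {
    mx_arg <- max.col(t(xm), ties.method = "first")
    mx <- xm[cbind(mx_arg, seq_len(C))]
    logits <- logits + conv1d_same(p$ca$w, p$ca$b, mx)
  }
  gate_c <- sigmoid(logits)
  fc <- xm * rep(gate_c, each = H * W)
  fca <- array(fc, d)
  dwf <- if (p$cfg$deformable) deform_dw_fwd else dw_fwd
  s1 <- dwf(p$dw1, fca, keep = keep)
  s2 <- dwf(p$dw2, s1$y, keep = keep)
  s3 <- conv_fwd(p$pw, s2$y, keep = keep)
  gate_s <- sigmoid(s3$y[, , 1])
  y <- fca * as.vector(gate_s)
  list(y = y,
       cache = if (keep)
         list(xm = xm, gate_c = gate_c, fc = fc, fca = fca,
              avg = avg, mx = mx, mx_arg = mx_arg, logits = logits,
              s1 = s1, s2 = s2, s3 = s3, gate_s = gate_s, dims = d))
}

csam_bwd <- function(p, cache, dy) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]
  gs <- as.vector(cache$gate_s)
  dfca <- dy * gs
  dgate_s <- matrix(rowSums(matrix(dy * cache$fca, H * W, C)), H, W)
  ds3 <- array(dgate_s * cache$gate_s * (1 - cache$gate_s), c(H, W, 1L))
  pwb <- conv_bwd(p$pw, cache$s3$cache, ds3)
  dwb <- if (p$cfg$deformable) deform_dw_bwd else dw_bwd
  b2 <- dwb(p$dw2, cache$s2$cache, pwb$dx)
  b1 <- dwb(p$dw1, cache$s1$cache, b2$dx)
  dfca <- dfca + b1$dx
  dfc <- matrix(dfca, H * W, C)
  dx_m <- dfc * rep(cache$gate_c, each = H * W)
  dgate_c <- colSums(dfc * cache$xm)
  dlogits <- dgate_c * cache$gate_c * (1 - cache$gate_c)
  ca1 <- conv1d_same_bwd(p$ca$w, cache$avg, dlogits)
  dca_w <- ca1$dw; dca_b <- ca1$db
  davg <- ca1$dv
  dx_m <- dx_m + rep(davg / (H * W), each = H * W)
  if (p$cfg$dual_pooling) {
    ca2 <- conv1d_same_bwd(p$ca$w, cache$mx, dlogits)
    dca_w <- dca_w + ca2$dw; dca_b <- dca_b + ca2$db
    dx_m[cbind(cache$mx_arg, seq_len(C))] <-
      dx_m[cbind(cache$mx_arg, seq_len(C))] + ca2$dv
  }
  g <- list(ca = list(w = dca_w, b = dca_b),
            dw1 = b1$g, dw2 = b2$g, pw = pwb$g)
  list(dx = array(dx_m, d), g = g)
}

#' Apply a channel-and-shape attention module to a feature map
#'
#' Standalone forward pass through a freshly initialised CSAM with the
#' given configuration; output shape equals input shape, and the
#' attention gates lie in (0, 1).  Used inside the segmentation network
#' on every skip connection; exposed directly for inspection and
#' testing.
#'
#' @param feature_map Numeric array `H x W x C`.
#' @param config A [csam_config()].
#' @param seed Seed for the module's parameter initialisation.
#' @return Array of the same shape as `feature_map`.
#' @export
csam_forward <- function(feature_map, config = csam_config(), seed = 1L) {
  stopifnot(inherits(config, "csam_config"))
  d <- dim(feature_map)
  if (length(d) != 3L)
    stop("feature_map must be an H x W x C array", call. = FALSE)
  p <- with_seed(seed, csam_p(d[3], config))
  csam_fwd(p, feature_map)$y
}
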