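# Neural-network primitives on plain R arrays.
#
# Feature maps are numeric arrays [H, W, C]; token matrices are [N, D].
# Convolutions are im2col gathers followed by BLAS matrix products, with
# hand-written backward passes (scatter-add via rowsum).  Everything is
# deterministic given the RNG seed used at initialisation.

.im2col_cache <- new.env(parent = emptyenv())

# linear indices into the zero-padded plane for every (output pixel, tap)
im2col_index <- function(H, W, k, stride = 1L, dilation = 1L, pad) {
  key <- paste(H, W, k, stride, dilation, pad, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  span <- (k - 1L) * dilation + 1L
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  H_out <- (H + 2L * pad - span) %/% stride + 1L
  W_out <- (W + 2L * pad - span) %/% stride + 1L
  yo <- rep(seq_len(H_out), times = W_out)
  xo <- rep(seq_len(W_out), each = H_out)
  idx <- matrix(0L, H_out * W_out, k * k)
  t <- 0L
  for (kx in seq_len(k)) for (ky in seq_len(k)) {
    t <- t + 1L
    y <- (yo - 1L) * stride + (ky - 1L) * dilation + 1L
    x <- (xo - 1L) * stride + (kx - 1L) * dilation + 1L
    idx[, t] <- (x - 1L) * Hp + y
  }
  out <- list(idx = idx, Hp = Hp, Wp = Wp, H_out = H_out, W_out = W_out)
  .im2col_cache[[key]] <- out
  out
}

pad_plane <- function(x, pad) {
  # x: [H, W, C] -> padded matrix [Hp*Wp, C]
  d <- dim(x)
  if (pad == 0L) return(matrix(x, d[1] * d[2], d[3]))
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  dim(xp) <- c((d[1] + 2L * pad) * (d[2] + 2L * pad), d[3])
  xp
}

unpad_plane <- function(xp_mat, H, W, C, pad) {
  xp <- array(xp_mat, c(H + 2L * pad, W + 2L * pad, C))
  xp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
}

he_init <- function(n_in, n_out, fan_in, gain = sqrt(2)) {
  matrix(rnorm(n_in * n_out, sd = gain / sqrt(fan_in)), n_in, n_out)
}

# ---- dense conv2d ---------------------------------------------------------

conv_p <- function(k, cin, cout, stride = 1L, dilation = 1L,
                   zero_init = FALSE) {
  k2 <- k * k
  w <- if (zero_init) matrix(0, k2 * cin, cout)
       else he_init(k2 * cin, cout, fan_in = k2 * cin)
  list(type = "conv", k = as.integer(k), cin = cin, cout = cout,
       stride = as.integer(stride), dilation = as.integer(dilation),
       pad = as.integer((k - 1L) * dilation / 2L),
       w = w, b = numeric(cout))
}

conv_fwd <- function(p, x, keep = TRUE) {
  d <- dim(x)
  stopifnot(d[3] == p$cin)
  ii <- im2col_index(d[1], d[2], p$k, p$stride, p$dilation, p$pad)
  xp <- pad_plane(x, p$pad)
  P <- xp[as.vector(ii$idx), , drop = FALSE]      # (n*k2) x cin
  dim(P) <- c(nrow(ii$idx) * p$k^2, p$cin)
  dim(P) <- c(nrow(ii$idx), p$k^2 * p$cin)
  y <- P %*% p$w
  y <- sweep_add(y, p$b)
  dim(y) <- c(ii$H_out, ii$W_out, p$cout)
  list(y = y, cache = if (keep) list(P = P, dims = d, ii = ii))
}

conv_bwd <- function(p, cache, dy) {
  ii <- cache$ii; d <- cache$dims
  dy_m <- matrix(dy, ii$H_out * ii$W_out, p$cout)
  dW <- crossprod(cache$P, dy_m)
  db <- colSums(dy_m)
  k2 <- p$k^2
  if (p$stride == 1L) {
    # transpose convolution == convolution of dy with the spatially
    # flipped, channel-transposed kernel (same padding, stride 1)
    wb <- backflip_w(p$w, k2, p$cin, p$cout)
    dya <- array(dy_m, c(ii$H_out, ii$W_out, p$cout))
    iy <- im2col_index(ii$H_out, ii$W_out, p$k, 1L, p$dilation, p$pad)
    dyp <- pad_plane(dya, p$pad)
    Pd <- dyp[as.vector(iy$idx), , drop = FALSE]
    dim(Pd) <- c(nrow(iy$idx), k2 * p$cout)
    dx <- array(Pd %*% wb, c(d[1], d[2], p$cin))
  } else {
    dP <- dy_m %*% t(p$w)                          # n x (k2*cin)
    # scatter one tap at a time (a tap's indices are all distinct,
    # so plain indexed addition is exact)
    dxp <- matrix(0, ii$Hp * ii$Wp, p$cin)
    for (t in seq_len(k2)) {
      cols <- seq.int(t, k2 * p$cin, by = k2)
      rows <- ii$idx[, t]
      dxp[rows, ] <- dxp[rows, , drop = FALSE] + dP[, cols, drop = FALSE]
    }
    dx <- unpad_plane(dxp, d[1], d[2], p$cin, p$pad)
  }
  list(dx = dx, g = list(w = dW, b = db))
}

# weight for the transpose convolution: flip taps, swap channel roles
backflip_w <- function(w, k2, cin, cout) {
  wa <- array(w, c(k2, cin, cout))
  wa <- wa[k2:1, , , drop = FALSE]
  wb <- aperm(wa, c(1, 3, 2))          # k2 x cout x cin
  matrix(wb, k2 * cout, cin)
}

sweep_add <- function(m, b) m + rep(b, each = nrow(m))

# ---- depthwise conv2d -----------------------------------------------------

dw_p <- function(k, c, dilation = 1L) {
  list(type = "dw", k = as.integer(k), c = c,
       dilation = as.integer(dilation),
       pad = as.integer((k - 1L) * dilation / 2L),
       w = he_init(k * k, c, fan_in = k * k), b = numeric(c))
}

# depthwise conv expressed as a dense im2col matmul with a block-sparse
# weight matrix (only tap t of channel c maps to output channel c);
# trades extra BLAS flops for far less interpreter overhead
dw_dense_w <- function(w, k2, C) {
  wd <- matrix(0, k2 * C, C)
  wd[cbind(rep(seq_len(k2), C) + rep((seq_len(C) - 1L) * k2, each = k2),
           rep(seq_len(C), each = k2))] <- as.vector(w)
  wd
}

dw_fwd <- function(p, x, keep = TRUE) {
  d <- dim(x)
  stopifnot(d[3] == p$c)
  ii <- im2col_index(d[1], d[2], p$k, 1L, p$dilation, p$pad)
  xp <- pad_plane(x, p$pad)
  n <- nrow(ii$idx); k2 <- p$k^2
  P <- xp[as.vector(ii$idx), , drop = FALSE]
  dim(P) <- c(n, k2 * p$c)
  y <- P %*% dw_dense_w(p$w, k2, p$c)
  y <- sweep_add(y, p$b)
  dim(y) <- c(d[1], d[2], p$c)
  list(y = y, cache = if (keep) list(P = P, dims = d, ii = ii))
}

dw_bwd <- function(p, cache, dy) {
  ii <- cache$ii; d <- cache$dims
  n <- nrow(ii$idx); k2 <- p$k^2
  dy_m <- matrix(dy, n, p$c)
  dWd <- crossprod(cache$P, dy_m)                  # (k2*c) x c
  dW <- matrix(dWd[cbind(rep(seq_len(k2), p$c) +
                           rep((seq_len(p$c) - 1L) * k2, each = k2),
                         rep(seq_len(p$c), each = k2))], k2, p$c)
  db <- colSums(dy_m)
  # dx: depthwise convolution of dy with the flipped kernel
  dyp <- pad_plane(array(dy_m, c(d[1], d[2], p$c)), p$pad)
  Pd <- dyp[as.vector(ii$idx), , drop = FALSE]
  dim(Pd) <- c(n, k2 * p$c)
  dx <- array(Pd %*% dw_dense_w(p$w[k2:1, , drop = FALSE], k2, p$c),
              c(d[1], d[2], p$c))
  list(dx = dx, g = list(w = dW, b = db))
}

# ---- deformable depthwise conv2d ------------------------------------------
# Sampling positions are the regular taps plus learned per-pixel offsets
# (shared across channels, one (dy, dx) pair per tap), predicted by a
# zero-initialised 3x3 conv so training starts from the plain depthwise
# behaviour.  Samples are bilinear with zero padding outside the frame.

deform_dw_p <- function(k, c, dilation = 1L) {
  list(type = "deform_dw", k = as.integer(k), c = c,
       dilation = as.integer(dilation),
       w = he_init(k * k, c, fan_in = k * k), b = numeric(c),
       offset = conv_p(3L, c, 2L * k * k, zero_init = TRUE))
}

bilinear_gather <- function(xm, H, W, C, ys, xs) {
  # xm: matrix [H*W, C]; ys/xs 0-based fractional positions, length n
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  gat <- function(yy, xx) {
    ok <- yy >= 0 & yy < H & xx >= 0 & xx < W
    id <- ifelse(ok, xx * H + yy + 1, 1)
    v <- xm[id, , drop = FALSE]
    v[!ok, ] <- 0
    v
  }
  v00 <- gat(y0, x0); v01 <- gat(y0, x0 + 1)
  v10 <- gat(y0 + 1, x0); v11 <- gat(y0 + 1, x0 + 1)
  top <- v00 * (1 - fx) + v01 * fx
  bot <- v10 * (1 - fx) + v11 * fx
  list(val = top * (1 - fy) + bot * fy,
       dv_dy = bot - top,
       dv_dx = (v01 - v00) * (1 - fy) + (v11 - v10) * fy,
       y0 = y0, x0 = x0, fy = fy, fx = fx)
}

deform_dw_fwd <- function(p, x, keep = TRUE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(C == p$c)
  off <- conv_fwd(p$offset, x)
  offm <- matrix(off$y, H * W, 2L * p$k^2)
  xm <- matrix(x, H * W, C)
  k2 <- p$k^2; half <- (p$k - 1) / 2
  yo <- rep(seq_len(H) - 1, times = W)
  xo <- rep(seq_len(W) - 1, each = H)
  y <- matrix(0, H * W, C)
  taps <- vector("list", k2)
  t <- 0L
  for (kx in seq_len(p$k)) for (ky in seq_len(p$k)) {
    t <- t + 1L
    ys <- yo + (ky - 1 - half) * p$dilation + offm[, 2L * t - 1L]
    xs <- xo + (kx - 1 - half) * p$dilation + offm[, 2L * t]
    g <- bilinear_gather(xm, H, W, C, ys, xs)
    y <- y + g$val * rep(p$w[t, ], each = H * W)
    if (keep) taps[[t]] <- g
  }
  y <- sweep_add(y, p$b)
  dim(y) <- c(H, W, C)
  list(y = y, cache = if (keep) list(taps = taps, off_cache = off$cache,
                                     dims = d, xm = xm))
}

deform_dw_bwd <- function(p, cache, dy) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]
  n <- H * W; k2 <- p$k^2
  dy_m <- matrix(dy, n, C)
  dW <- matrix(0, k2, C)
  db <- colSums(dy_m)
  dxm <- matrix(0, n, C)
  doff <- matrix(0, n, 2L * k2)
  wch <- function(t) rep(p$w[t, ], each = n)
  for (t in seq_len(k2)) {
    g <- cache$taps[[t]]
    dW[t, ] <- colSums(g$val * dy_m)
    dval <- dy_m * wch(t)                        # n x C
    doff[, 2L * t - 1L] <- rowSums(dval * g$dv_dy)
    doff[, 2L * t] <- rowSums(dval * g$dv_dx)
    # scatter gradient to the four corners
    corner <- function(yy, xx, wgt) {
      ok <- yy >= 0 & yy < H & xx >= 0 & xx < W
      if (!any(ok)) return(invisible())
      id <- xx[ok] * H + yy[ok] + 1
      contrib <- dval[ok, , drop = FALSE] * wgt[ok]
      acc <- rowsum(contrib, id)
      ids <- as.integer(rownames(acc))
      dxm[ids, ] <<- dxm[ids, , drop = FALSE] + acc
      invisible()
    }
    corner(g$y0, g$x0, (1 - g$fy) * (1 - g$fx))
    corner(g$y0, g$x0 + 1, (1 - g$fy) * g$fx)
    corner(g$y0 + 1, g$x0, g$fy * (1 - g$fx))
    corner(g$y0 + 1, g$x0 + 1, g$fy * g$fx)
  }
  dofe <- array(doff, c(H, W, 2L * k2))
  ob <- conv_bwd(p$offset, cache$off_cache, dofe)
  dx <- array(dxm, c(H, W, C)) + ob$dx
  list(dx = dx, g = list(w = dW, b = db, offset = ob$g))
}

# ---- misc layers ----------------------------------------------------------

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dy) dy * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

upsample2_fwd <- function(x) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
         drop = FALSE]
  list(y = y, cache = d)
}

upsample2_bwd <- function(cache, dy) {
  d <- cache
  dya <- array(dy, c(2L, d[1], 2L, d[2], d[3]))
  array(colSums(aperm(dya, c(1, 3, 2, 4, 5)), dims = 2), d)
}

linear_p <- function(din, dout, zero_init = FALSE) {
  w <- if (zero_init) matrix(0, din, dout)
       else he_init(din, dout, fan_in = din, gain = 1)
  list(type = "linear", w = w, b = numeric(dout))
}

linear_fwd <- function(p, x) list(y = sweep_add(x %*% p$w, p$b), cache = x)
linear_bwd <- function(p, cache, dy)
  list(dx = dy %*% t(p$w),
       g = list(w = crossprod(cache, dy), b = colSums(dy)))

ln_p <- function(d) list(type = "ln", g = rep(1, d), b = numeric(d))

ln_fwd <- function(p, x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep_add(xhat * rep(p$g, each = nrow(x)), p$b)
  list(y = y, cache = list(xhat = xhat, inv = inv))
}

ln_bwd <- function(p, cache, dy) {
  xhat <- cache$xhat; inv <- cache$inv
  n <- ncol(dy)
  dg <- colSums(dy * xhat); db <- colSums(dy)
  dxhat <- dy * rep(p$g, each = nrow(dy))
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, g = list(g = dg, b = db))
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

attn_p <- function(d, heads) {
  list(type = "attn", d = d, heads = as.integer(heads),
       wq = linear_p(d, d), wk = linear_p(d, d), wv = linear_p(d, d),
       wo = linear_p(d, d))
}

attn_fwd <- function(p, x, keep = TRUE) {
  q <- linear_fwd(p$wq, x); k <- linear_fwd(p$wk, x)
  v <- linear_fwd(p$wv, x)
  dh <- p$d %/% p$heads
  N <- nrow(x)
  o <- matrix(0, N, p$d)
  heads_cache <- vector("list", p$heads)
  for (h in seq_len(p$heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    qh <- q$y[, cols, drop = FALSE]; kh <- k$y[, cols, drop = FALSE]
    vh <- v$y[, cols, drop = FALSE]
    A <- softmax_rows(tcrossprod(qh, kh) / sqrt(dh))
    o[, cols] <- A %*% vh
    if (keep) heads_cache[[h]] <- list(A = A, qh = qh, kh = kh, vh = vh)
  }
  out <- linear_fwd(p$wo, o)
  list(y = out$y,
       cache = if (keep) list(q = q, k = k, v = v, o_cache = out$cache,
                              heads = heads_cache, N = N))
}

attn_bwd <- function(p, cache, dy) {
  ob <- linear_bwd(p$wo, cache$o_cache, dy)
  do <- ob$dx
  dh <- p$d %/% p$heads
  dq <- matrix(0, cache$N, p$d); dk <- dq; dv <- dq
  for (h in seq_len(p$heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    hc <- cache$heads[[h]]
    doh <- do[, cols, drop = FALSE]
    dA <- tcrossprod(doh, hc$vh)
    dv[, cols] <- crossprod(hc$A, doh)
    # softmax backward (rowwise): dS = A * (dA - rowSums(dA * A))
    dS <- hc$A * (dA - rowSums(dA * hc$A)) / sqrt(dh)
    dq[, cols] <- dS %*% hc$kh
    dk[, cols] <- crossprod(dS, hc$qh)
  }
  qb <- linear_bwd(p$wq, cache$q$cache, dq)
  kb <- linear_bwd(p$wk, cache$k$cache, dk)
  vb <- linear_bwd(p$wv, cache$v$cache, dv)
  list(dx = qb$dx + kb$dx + vb$dx,
       g = list(wq = qb$g, wk = kb$g, wv = vb$g, wo = ob$g))
}
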