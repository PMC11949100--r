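# Training (Adam), prediction and checkpointing.

# recursive Adam over the parameter tree; only leaves named in
# `trainable` are parameters (other numeric entries are hyperparameters)
.trainable_names <- c("w", "b", "g", "pos")

adam_init <- function(params) {
  walk <- function(x, nm = "") {
    if (is.list(x)) return(lapply(seq_along(x), function(i)
      walk(x[[i]], if (is.null(names(x))) "" else names(x)[i])) |>
        stats::setNames(names(x)))
    if (is.numeric(x) && nm %in% .trainable_names)
      list(m = x * 0, v = x * 0) else NULL
  }
  walk(params)
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s, nm = "") {
    if (is.null(g)) return(list(p = p, s = s))
    if (is.list(p)) {
      for (k in names(g)) {
        if (is.null(p[[k]])) next
        r <- walk(p[[k]], g[[k]], s[[k]], k)
        p[[k]] <- r$p; s[[k]] <- r$s
      }
      return(list(p = p, s = s))
    }
    if (!(nm %in% .trainable_names)) return(list(p = p, s = s))
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk(params, grads, state)
}

flip_image <- function(img, h, v) {
  if (h) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  if (v) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  img
}
flip_mask <- function(m, h, v) {
  if (h) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (v) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m
}

#' Smoke-scale training loop
#'
#' Trains the model on rendered phantom image/mask pairs with Adam,
#' per-image updates and random horizontal/vertical flip augmentation.
#' Fully deterministic for a given seed on a fixed BLAS.
#'
#' @param model A `ptery_model` from [build_model()].
#' @param phantom_set List of training pairs, each a list with `image`
#'   (`H x W x 3` array) and `mask` (label matrix); at least 8 pairs.
#' @param epochs Number of passes over the set.
#' @param seed Integer seed driving augmentation and shuffling.
#' @param learning_rate Adam learning rate.
#' @param augment Apply random flips.
#' @param verbose Print the per-epoch mean loss.
#' @return List with `model` (trained) and `history` (mean training
#'   loss per epoch, length `epochs`).
#' @export
train_smoke <- function(model, phantom_set, epochs = 30L, seed = 1L,
                        learning_rate = 1e-3, augment = TRUE,
                        verbose = FALSE) {
  stopifnot(inherits(model, "ptery_model"))
  if (length(phantom_set) < 8L)
    stop("need at least 8 phantom image/mask pairs", call. = FALSE)
  lw <- model$config$loss_weights
  state <- adam_init(model$params)
  history <- numeric(epochs)
  t <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(phantom_set))
      ep_loss <- 0
      for (i in ord) {
        img <- phantom_set[[i]]$image
        msk <- phantom_set[[i]]$mask
        if (augment) {
          h <- runif(1) < 0.5; v <- runif(1) < 0.5
          img <- flip_image(img, h, v); msk <- flip_mask(msk, h, v)
        }
        fw <- model_forward(model, img, train = TRUE)
        ls <- combined_loss_grad(fw$scores, msk, lw)
        g <- model_backward(model, fw$cache, ls$dscores)
        t <- t + 1L
        r <- adam_step(model$params, g, state, learning_rate, t)
        model$params <- r$p; state <- r$s
        ep_loss <- ep_loss + ls$loss
      }
      history[ep] <- ep_loss / length(phantom_set)
      if (verbose)
        message(sprintf("epoch %d/%d  mean loss %.4f", ep, epochs,
                        history[ep]))
    }
  })
  list(model = model, history = history)
}

#' Predict a label mask for one image
#'
#' Pixelwise argmax over the class scores.
#'
#' @param object A `ptery_model`.
#' @param image `H x W x 3` array matching the model's configured size.
#' @param ... Unused.
#' @return Integer label matrix with codes `0..n_classes-1`.
#' @export
predict.ptery_model <- function(object, image, ...) {
  fw <- model_forward(object, image, train = FALSE)
  d <- dim(fw$scores)
  s <- matrix(fw$scores, d[1] * d[2], d[3])
  matrix(max.col(s, ties.method = "first") - 1L, d[1], d[2])
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries the full configuration echo and all
#' parameters; reloading reproduces forward outputs bitwise.
#'
#' @param model A `ptery_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `ptery_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ptery_model"))
  saveRDS(list(format = "pterygrade-checkpoint", version = .ptery_version(),
               config = model$config, params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "pterygrade-checkpoint"))
    stop("not a pterygrade checkpoint: ", path, call. = FALSE)
  structure(list(config = ck$config, params = ck$params),
            class = "ptery_model")
}

#' Build a rendered phantom training set
#'
#' Generates `n` random phantoms at the given size and renders each as a
#' flat-shaded noisy RGB image paired with its label mask.
#'
#' @param n Number of pairs.
#' @param size Image side length (must be divisible by 8).
#' @param seed Integer seed.
#' @param noise_sd Pixel noise of the rendering.
#' @return List of `list(image, mask, truth)` training pairs.
#' @export
phantom_training_set <- function(n, size = 128L, seed = 1L,
                                 noise_sd = 0.06) {
  specs <- sample_phantom_specs(n, size = size, seed = seed)
  lapply(seq_along(specs), function(i) {
    ph <- generate_phantom(specs[[i]])
    list(image = render_phantom_rgb(ph$mask, noise_sd = noise_sd,
                                    seed = seed + 7919L * i),
         mask = ph$mask, truth = ph$truth)
  })
}
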