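#' Encoder configuration
#'
#' Architecture and training hyperparameters for a single contrastive
#' encoder: a small convolutional stack (3x3 kernels, stride 2, zero padding
#' 1, ReLU) followed by a dense hidden layer and a linear projection head to
#' a low-dimensional embedding. The default projects to two dimensions --
#' Euclidean distance degrades in high dimensions, so the embedding is kept
#' as low as remains informative. Temperature, batch size and epochs follow
#' common SimCLR-scale practice and are all configurable.
#'
#' @param input_shape `(H, W, C)` of the simplified images; H must equal W.
#' @param conv_filters filter counts of the successive stride-2 conv blocks.
#' @param hidden width of the dense hidden layer.
#' @param embed_dim projection dimension (default 2).
#' @param temperature NT-Xent softmax temperature.
#' @param batch_size images per contrastive batch (each contributes a
#'   positive pair).
#' @param epochs passes over the training images.
#' @param lr Adam learning rate.
#' @param policy an [augmentation_policy()].
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(input_shape = c(32, 32, 4),
                           conv_filters = c(8, 16, 32),
                           hidden = 32, embed_dim = 2, temperature = 0.5,
                           batch_size = 64, epochs = 100, lr = 1e-3,
                           policy = augmentation_policy()) {
  if (input_shape[1] != input_shape[2])
    stop("encoder inputs must be square")
  if (embed_dim < 1 || embed_dim > 3)
    stop("'embed_dim' must be 1-3; distances are computed in this space")
  structure(list(input_shape = input_shape, conv_filters = conv_filters,
                 hidden = hidden, embed_dim = embed_dim,
                 temperature = temperature, batch_size = batch_size,
                 epochs = epochs, lr = lr, policy = policy),
            class = "encoder_config")
}

# He-initialized parameters + precomputed im2col geometry for each conv layer
init_encoder <- function(cfg, seed) {
  with_local_seed(seed, {
    H <- cfg$input_shape[1]
    C <- cfg$input_shape[3]
    k <- 3
    stride <- 2
    pad <- 1
    params <- list()
    geom <- list()
    cur_h <- H
    cur_c <- C
    for (i in seq_along(cfg$conv_filters)) {
      f <- cfg$conv_filters[i]
      geom[[i]] <- make_im2col_idx(cur_h, cur_h, cur_c, k, stride, pad)
      fan_in <- k * k * cur_c
      params[[paste0("Wc", i)]] <-
        matrix(rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f)
      params[[paste0("bc", i)]] <- numeric(f)
      cur_h <- geom[[i]]$Ho
      cur_c <- f
    }
    flat <- cur_h * cur_h * cur_c
    params$Wd1 <- matrix(rnorm(flat * cfg$hidden, sd = sqrt(2 / flat)),
                         flat, cfg$hidden)
    params$bd1 <- numeric(cfg$hidden)
    params$Wd2 <- matrix(rnorm(cfg$hidden * cfg$embed_dim,
                               sd = sqrt(1 / cfg$hidden)),
                         cfg$hidden, cfg$embed_dim)
    params$bd2 <- numeric(cfg$embed_dim)
    structure(list(cfg = cfg, params = params, geom = geom, seed = seed,
                   loss_curve = numeric(0), heldout_loss = c(NA, NA)),
              class = "abm_encoder")
  })
}

# x: array (H, W, C, B); returns embeddings B x embed_dim (+ caches)
encoder_forward <- function(enc, x, keep_cache = FALSE) {
  caches <- list()
  cur <- x
  nconv <- length(enc$cfg$conv_filters)
  for (i in seq_len(nconv)) {
    cf <- conv_forward(cur, enc$params[[paste0("Wc", i)]],
                       enc$params[[paste0("bc", i)]], enc$geom[[i]])
    rf <- relu_forward(cf$out)
    if (keep_cache) caches[[paste0("conv", i)]] <- cf
    if (keep_cache) caches[[paste0("relu", i)]] <- rf$mask
    cur <- rf$out
  }
  fl <- flatten_forward(cur)
  d1 <- dense_forward(fl$out, enc$params$Wd1, enc$params$bd1)
  r1 <- relu_forward(d1$out)
  d2 <- dense_forward(r1$out, enc$params$Wd2, enc$params$bd2)
  if (keep_cache) {
    caches$flat_d <- fl$d
    caches$d1 <- d1
    caches$relu_d1 <- r1$mask
    caches$d2 <- d2
  }
  list(z = d2$out, caches = caches)
}

encoder_backward <- function(enc, caches, dz) {
  grads <- list()
  bd2 <- dense_backward(dz, enc$params$Wd2, caches$d2)
  grads$Wd2 <- bd2$dW
  grads$bd2 <- bd2$db
  dr1 <- relu_backward(bd2$dx, caches$relu_d1)
  bd1 <- dense_backward(dr1, enc$params$Wd1, caches$d1)
  grads$Wd1 <- bd1$dW
  grads$bd1 <- bd1$db
  dcur <- flatten_backward(bd1$dx, caches$flat_d)
  for (i in rev(seq_along(enc$cfg$conv_filters))) {
    dcur <- relu_backward(dcur, caches[[paste0("relu", i)]])
    bc <- conv_backward(dcur, enc$params[[paste0("Wc", i)]],
                        caches[[paste0("conv", i)]])
    grads[[paste0("Wc", i)]] <- bc$dW
    grads[[paste0("bc", i)]] <- bc$db
    dcur <- bc$dx
  }
  grads
}

stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  x <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]
  x
}

#' Train a contrastive encoder
#'
#' SimCLR-style training: each batch image is augmented twice (random
#' mirror/rotation), both views are projected, and the NT-Xent loss pulls the
#' two views of the same image together relative to all other views in the
#' batch. Optimization is Adam. Training is fully reproducible: the same
#' `(images, cfg, seed)` produce identical weights, and R's global RNG state
#' is left untouched.
#'
#' @param images list of `simplified_image`s, all of the same shape; at least
#'   `2 * cfg$batch_size` images are required.
#' @param cfg an [encoder_config()].
#' @param seed integer training seed.
#' @return An `abm_encoder`: parameters, config, per-batch `loss_curve`, and
#'   `heldout_loss` (loss on a fixed held-out batch before and after
#'   training).
#' @export
train_encoder <- function(images, cfg, seed) {
  n <- length(images)
  if (n < 2 * cfg$batch_size)
    stop(sprintf("need at least 2*batch_size = %d images, got %d",
                 2 * cfg$batch_size, n))
  shp <- dim(images[[1]])
  same <- vapply(images, function(im) identical(dim(im), shp), logical(1))
  if (!all(same)) stop("all training images must share the same shape")
  if (!identical(as.integer(shp), as.integer(cfg$input_shape)))
    stop(sprintf("images are %s but encoder expects %s",
                 paste(shp, collapse = "x"),
                 paste(cfg$input_shape, collapse = "x")))
  enc <- init_encoder(cfg, seed)
  with_local_seed(seed + 1L, {
    opt <- adam_init(enc$params)
    held_idx <- sample.int(n, min(cfg$batch_size, n))
    make_batch <- function(idx) {
      va <- lapply(images[idx], augment_image, policy = cfg$policy)
      vb <- lapply(images[idx], augment_image, policy = cfg$policy)
      stack_images(c(va, vb))
    }
    held <- make_batch(held_idx)
    enc$heldout_loss[1] <- nt_xent_loss(
      encoder_forward(enc, held)$z, cfg$temperature)
    losses <- numeric(0)
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n - cfg$batch_size + 1, by = cfg$batch_size)
      for (s in starts) {
        idx <- perm[s:(s + cfg$batch_size - 1)]
        x <- make_batch(idx)
        fw <- encoder_forward(enc, x, keep_cache = TRUE)
        loss <- nt_xent_loss(fw$z, cfg$temperature)
        dz <- nt_xent_grad(fw$z, cfg$temperature)
        grads <- encoder_backward(enc, fw$caches, dz)
        st <- adam_step(enc$params, grads, opt, cfg$lr)
        enc$params <- st$params
        opt <- st$opt
        losses <- c(losses, loss)
      }
    }
    enc$loss_curve <- losses
    enc$heldout_loss[2] <- nt_xent_loss(
      encoder_forward(enc, held)$z, cfg$temperature)
    enc
  })
}

#' Project images to the embedding space
#'
#' Deterministic forward pass of a trained encoder; no stochastic layers are
#' used at projection time. `project_image()` maps one image to a point,
#' `project_images()` maps a list to a matrix (one row per image; batching is
#' transparent -- batched and single projections agree).
#'
#' @param enc a trained `abm_encoder`.
#' @param img a `simplified_image` matching the training schema.
#' @param imgs a list of such images.
#' @return `project_image()`: numeric vector of length `embed_dim`;
#'   `project_images()`: matrix (n x embed_dim).
#' @export
project_image <- function(enc, img) {
  check_img_shape(enc, img)
  as.vector(encoder_forward(enc, stack_images(list(img)))$z)
}

#' @rdname project_image
#' @export
project_images <- function(enc, imgs) {
  for (im in imgs) check_img_shape(enc, im)
  encoder_forward(enc, stack_images(imgs))$z
}

check_img_shape <- function(enc, img) {
  if (!identical(as.integer(dim(img)), as.integer(enc$cfg$input_shape)))
    stop(sprintf("image shape %s does not match encoder input %s",
                 paste(dim(img), collapse = "x"),
                 paste(enc$cfg$input_shape, collapse = "x")))
  invisible(TRUE)
}

# run expr under a fixed seed, restoring the caller's RNG state afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Serialize an encoder to JSON
#'
#' Checkpoints are plain text: config, seed, and flattened weights at full
#' precision. `read_encoder()` restores an encoder whose projections are
#' identical to the original's.
#'
#' @param enc an `abm_encoder`.
#' @param path output path.
#' @return `path` (write) or an `abm_encoder` (read).
#' @export
write_encoder <- function(enc, path) {
  cfg <- unclass(enc$cfg)
  cfg$policy <- enc$cfg$policy$elements
  obj <- list(cfg = cfg, seed = enc$seed,
              heldout_loss = enc$heldout_loss,
              params = lapply(enc$params, function(p)
                list(dim = dim(p) %||% length(p), values = as.vector(p))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_encoder
#' @export
read_encoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pol <- structure(list(elements = as.integer(obj$cfg$policy)),
                   class = "augmentation_policy")
  cfg <- encoder_config(
    input_shape = as.integer(obj$cfg$input_shape),
    conv_filters = as.integer(obj$cfg$conv_filters),
    hidden = obj$cfg$hidden, embed_dim = obj$cfg$embed_dim,
    temperature = obj$cfg$temperature, batch_size = obj$cfg$batch_size,
    epochs = obj$cfg$epochs, lr = obj$cfg$lr, policy = pol)
  enc <- init_encoder(cfg, obj$seed)
  for (nm in names(obj$params)) {
    p <- obj$params[[nm]]
    v <- as.numeric(p$values)
    if (length(p$dim) == 2) v <- matrix(v, p$dim[1], p$dim[2])
    enc$params[[nm]] <- v
  }
  enc$heldout_loss <- obj$heldout_loss
  enc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
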