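# Minimal neural-network primitives for the contrastive encoder.
#
# Convolutions are computed as matrix products through an im2col expansion:
# for each layer a patch-index table is precomputed once from the input
# geometry, batches are gathered into a (positions*batch) x (k*k*C) matrix,
# and the convolution is a single GEMM. The backward pass scatters patch
# gradients back with rowsum() over the same index table. This keeps the
# whole network in base R matrix algebra, which is ample for 32x32 inputs.

# patch-index table for an H x W x C input, k x k kernel, given stride/pad;
# indices address the zero-padded single-image array (Hp x Wp x C),
# positions ordered column-major over (Ho, Wo), patch entries ordered
# (ki, kj, c) to match the weight layout
make_im2col_idx <- function(H, W, C, k, stride, pad) {
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  Hp <- H + 2 * pad
  Wp <- W + 2 * pad
  ho <- rep(seq_len(Ho), times = Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  pos_off <- ((wo - 1) * stride) * Hp + (ho - 1) * stride
  ki <- rep(seq_len(k), times = k * C)
  kj <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  col_off <- (cc - 1) * Hp * Wp + (kj - 1) * Hp + ki
  list(idx = outer(pos_off, col_off, `+`), Ho = Ho, Wo = Wo, Hp = Hp,
       Wp = Wp, H = H, W = W, C = C, k = k, stride = stride, pad = pad)
}

# x: array (H, W, C, B); W_: (k*k*C) x F; returns out (Ho, Wo, F, B) + cache
conv_forward <- function(x, W_, b, ci) {
  d <- dim(x)
  B <- d[4]
  xp <- array(0, c(ci$Hp, ci$Wp, ci$C, B))
  xp[ci$pad + seq_len(ci$H), ci$pad + seq_len(ci$W), , ] <- x
  npos <- nrow(ci$idx)
  per <- ci$Hp * ci$Wp * ci$C
  idx_big <- ci$idx[rep(seq_len(npos), times = B), , drop = FALSE] +
    rep((seq_len(B) - 1) * per, each = npos)
  M <- matrix(xp[idx_big], nrow = npos * B)
  Y <- M %*% W_
  Y <- Y + rep(b, each = nrow(Y))
  Fd <- ncol(W_)
  out <- array(aperm(array(Y, c(npos, B, Fd)), c(1, 3, 2)),
               c(ci$Ho, ci$Wo, Fd, B))
  list(out = out, M = M, idx_big = idx_big, B = B, per = per, ci = ci)
}

conv_backward <- function(dout, W_, cache) {
  ci <- cache$ci
  npos <- nrow(ci$idx)
  Fd <- ncol(W_)
  B <- cache$B
  dY <- matrix(aperm(array(dout, c(npos, Fd, B)), c(1, 3, 2)),
               nrow = npos * B)
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- dY %*% t(W_)
  acc <- rowsum(as.vector(dM), as.vector(cache$idx_big))
  dxp <- numeric(cache$per * B)
  dxp[as.integer(rownames(acc))] <- acc[, 1]
  dxp <- array(dxp, c(ci$Hp, ci$Wp, ci$C, B))
  dx <- dxp[ci$pad + seq_len(ci$H), ci$pad + seq_len(ci$W), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

relu_backward <- function(dout, mask) dout * mask

# x: B x n_in
dense_forward <- function(x, W_, b) {
  list(out = x %*% W_ + rep(b, each = nrow(x)), x = x)
}

dense_backward <- function(dout, W_, cache) {
  list(dx = dout %*% t(W_), dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

# (Ho, Wo, F, B) -> B x (Ho*Wo*F)
flatten_forward <- function(x) {
  d <- dim(x)
  list(out = t(matrix(x, ncol = d[4])), d = d)
}

flatten_backward <- function(dout, d) array(t(dout), d)

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}
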