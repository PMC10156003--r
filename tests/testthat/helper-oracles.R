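# Independent oracle implementations used to cross-check the package's
# optimized code paths. These are deliberately naive (explicit loops,
# all-pairs scans) and share no code with the implementation.

# all-pairs neighbor scan
neighbors_oracle <- function(state, id, radius) {
  focal <- state[state$id == id, ]
  d <- sqrt((state$x - focal$x)^2 + (state$y - focal$y)^2)
  hits <- state[d <= radius & state$id != id, ]
  hits[order(hits$id), ]
}

# brute-force NT-Xent: explicit double loop over the published formula
nt_xent_oracle <- function(z, tau) {
  n2 <- nrow(z)
  N <- n2 / 2
  u <- z / sqrt(rowSums(z^2))
  sim <- function(i, j) sum(u[i, ] * u[j, ]) / tau
  total <- 0
  for (i in 1:n2) {
    pos <- if (i <= N) i + N else i - N
    denom <- 0
    for (k in 1:n2) if (k != i) denom <- denom + exp(sim(i, k))
    total <- total - log(exp(sim(i, pos)) / denom)
  }
  total / n2
}

# per-channel histogram-binning oracle for rasterization
rasterize_oracle <- function(cells, schema, d) {
  minx <- min(cells$x)
  miny <- min(cells$y)
  col <- floor((cells$x - minx) / d) + 1
  row <- floor((cells$y - miny) / d) + 1
  nr <- max(row)
  nc <- max(col)
  out <- array(0, c(nr, nc, length(schema$channels)))
  for (k in seq_along(schema$channels)) {
    ch <- schema$channels[[k]]
    for (i in seq_len(nrow(cells))) {
      match_kind <- is.null(ch$kind) || cells$kind[i] %in% ch$kind
      if (!match_kind) next
      if (ch$mode == "presence") {
        out[row[i], col[i], k] <- 1
      } else {
        out[row[i], col[i], k] <- out[row[i], col[i], k] +
          cells[[ch$property]][i]
      }
    }
    if (ch$mode == "continuous" && max(out[, , k]) > 0)
      out[, , k] <- out[, , k] / max(out[, , k])
  }
  out
}

# direct forward pass of the encoder by nested loops (no im2col)
naive_encoder_forward <- function(enc, img) {
  x <- img
  k <- 3; s <- 2; p <- 1
  for (li in seq_along(enc$cfg$conv_filters)) {
    W <- enc$params[[paste0("Wc", li)]]
    b <- enc$params[[paste0("bc", li)]]
    d <- dim(x)
    xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
    xp[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
    Ho <- (d[1] + 2 * p - k) %/% s + 1
    Wo <- (d[2] + 2 * p - k) %/% s + 1
    nf <- ncol(W)
    y <- array(0, c(Ho, Wo, nf))
    for (ho in 1:Ho) for (wo in 1:Wo) for (f in 1:nf) {
      acc <- b[f]
      ci <- 0
      for (cc in 1:d[3]) for (kj in 1:k) for (ki in 1:k) {
        ci <- ci + 1
        acc <- acc + xp[(ho - 1) * s + ki, (wo - 1) * s + kj, cc] * W[ci, f]
      }
      y[ho, wo, f] <- max(0, acc)  # ReLU
    }
    x <- y
  }
  v <- as.vector(x)
  h <- pmax(0, as.vector(v %*% enc$params$Wd1) + enc$params$bd1)
  as.vector(h %*% enc$params$Wd2) + enc$params$bd2
}
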