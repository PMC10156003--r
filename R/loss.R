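#' Normalized-temperature cross-entropy (NT-Xent) loss
#'
#' The SimCLR contrastive objective. Rows of `z` are 2N projected embeddings
#' laid out as N pairs: row `i` and row `i + N` are the two augmentations of
#' the same input (a positive pair). For each embedding the loss is the
#' negative log-softmax of the cosine similarity (divided by the temperature)
#' with its positive partner, against all 2N - 2 other embeddings; the result
#' is averaged over all 2N rows. Because similarities are cosine, the loss is
#' invariant to rescaling any individual embedding.
#'
#' When all 2N embeddings are identical, every similarity is equal and the
#' loss reduces to `log(2N - 1)` exactly.
#'
#' @param z numeric matrix (2N x d) of paired projections, N >= 2; no row may
#'   have zero norm.
#' @param temperature softmax temperature, > 0.
#' @return Scalar loss (finite, non-negative).
#' @examples
#' z <- matrix(rnorm(8 * 2), 8, 2)
#' nt_xent_loss(z, 0.5)
#' nt_xent_loss(matrix(1, 8, 2), 0.5)  # log(7)
#' @export
nt_xent_loss <- function(z, temperature = 0.5) {
  s <- nt_xent_parts(z, temperature)
  mean(s$lse - s$pos_sim)
}

#' @rdname nt_xent_loss
#' @description `nt_xent_grad()` returns the analytic gradient of the loss
#'   with respect to `z` (same shape as `z`); it is validated against finite
#'   differences in the package tests.
#' @export
nt_xent_grad <- function(z, temperature = 0.5) {
  s <- nt_xent_parts(z, temperature)
  n2 <- nrow(z)
  # dL/dS for the off-diagonal logits: softmax prob minus positive indicator
  P <- exp(s$S - s$lse)   # row-wise softmax over k != i (diag is -Inf)
  G <- P / n2
  G[cbind(seq_len(n2), s$pos)] <- G[cbind(seq_len(n2), s$pos)] - 1 / n2
  dU <- ((G + t(G)) %*% s$u) / temperature
  # back through the row normalization u = z / ||z||
  proj <- rowSums(dU * s$u)
  (dU - proj * s$u) / s$nrm
}

nt_xent_parts <- function(z, temperature) {
  if (!is.matrix(z) || nrow(z) %% 2 != 0)
    stop("'z' must be a 2N x d matrix of paired embeddings")
  n2 <- nrow(z)
  N <- n2 / 2
  if (N < 2) stop("NT-Xent needs at least 2 pairs (4 embeddings)")
  if (temperature <= 0) stop("'temperature' must be positive")
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm < 1e-12)) stop("zero-norm embedding in NT-Xent input")
  u <- z / nrm
  S <- (u %*% t(u)) / temperature
  diag(S) <- -Inf
  pos <- c((N + 1):n2, 1:N)
  m <- apply(S, 1, max)
  lse <- m + log(rowSums(exp(S - m)))
  list(u = u, nrm = nrm, S = S, pos = pos, lse = lse,
       pos_sim = S[cbind(seq_len(n2), pos)])
}
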