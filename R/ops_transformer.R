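# Transformer primitives over token matrices. A token sequence for one
# sample is an (N_tok x C) matrix; batches are (N_tok, C, B) arrays handled
# by looping over the third margin (batches here are small).

layernorm_fw <- function(x, gamma, beta, eps = 1e-5, keep = FALSE) {
  C <- ncol(x)
  mu <- rowMeans(x)
  v <- rowMeans(x * x) - mu^2
  invstd <- 1 / sqrt(pmax(v, 0) + eps)
  xhat <- (x - mu) * invstd
  out <- xhat * rep(gamma, each = nrow(x)) + rep(beta, each = nrow(x))
  list(out = out, cache = if (keep) list(xhat = xhat, invstd = invstd,
                                         gamma = gamma) else NULL)
}

layernorm_bw <- function(dout, cache) {
  N <- nrow(dout)
  dxhat <- dout * rep(cache$gamma, each = N)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dx <- cache$invstd *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

gelu_fw <- function(x) list(out = x * pnorm(x), cache = x)
gelu_bw <- function(dout, cache) dout * (pnorm(cache) + cache * dnorm(cache))

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

# Scaled dot-product multi-head self-attention on one sample (N x C).
# p: list(Wq, bq, Wk, bk, Wv, bv, Wo, bo); heads H with dk = C / H.
mhsa_fw <- function(x, p, heads, keep = FALSE) {
  N <- nrow(x); C <- ncol(x); dk <- C %/% heads
  if (C %% heads != 0L) stop_config("embed_dim not divisible by head count")
  Q <- x %*% p$Wq + rep(p$bq, each = N)
  K <- x %*% p$Wk + rep(p$bk, each = N)
  V <- x %*% p$Wv + rep(p$bv, each = N)
  O <- matrix(0, N, C)
  As <- if (keep) vector("list", heads) else NULL
  for (h in seq_len(heads)) {
    ix <- ((h - 1L) * dk + 1L):(h * dk)
    A <- softmax_rows(tcrossprod(Q[, ix, drop = FALSE],
                                 K[, ix, drop = FALSE]) / sqrt(dk))
    O[, ix] <- A %*% V[, ix, drop = FALSE]
    if (keep) As[[h]] <- A
  }
  out <- O %*% p$Wo + rep(p$bo, each = N)
  list(out = out,
       cache = if (keep) list(x = x, Q = Q, K = K, V = V, O = O, As = As,
                              p = p, heads = heads, dk = dk) else NULL,
       attn = As)
}

mhsa_bw <- function(dout, cache) {
  p <- cache$p; N <- nrow(dout); C <- ncol(dout)
  heads <- cache$heads; dk <- cache$dk
  dO <- tcrossprod(dout, p$Wo)
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dQ <- matrix(0, N, C); dK <- matrix(0, N, C); dV <- matrix(0, N, C)
  for (h in seq_len(heads)) {
    ix <- ((h - 1L) * dk + 1L):(h * dk)
    A <- cache$As[[h]]
    dOh <- dO[, ix, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, ix, drop = FALSE])
    dV[, ix] <- crossprod(A, dOh)
    dS <- (dA - rowSums(dA * A)) * A
    dQ[, ix] <- dS %*% cache$K[, ix, drop = FALSE] / sqrt(dk)
    dK[, ix] <- crossprod(dS, cache$Q[, ix, drop = FALSE]) / sqrt(dk)
  }
  dx <- tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  list(dx = dx,
       grads = list(Wq = crossprod(cache$x, dQ), bq = colSums(dQ),
                    Wk = crossprod(cache$x, dK), bk = colSums(dK),
                    Wv = crossprod(cache$x, dV), bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

# Pre-norm transformer block: z' = z + MHSA(LN(z)); z'' = z' + FFN(LN(z')).
# p adds ln1/ln2 gamma+beta and FFN W1, b1, W2, b2 (GELU nonlinearity).
tblock_fw <- function(x, p, heads, keep = FALSE) {
  N <- nrow(x)
  l1 <- layernorm_fw(x, p$ln1.gamma, p$ln1.beta, keep = keep)
  at <- mhsa_fw(l1$out, list(Wq = p$Wq, bq = p$bq, Wk = p$Wk, bk = p$bk,
                             Wv = p$Wv, bv = p$bv, Wo = p$Wo, bo = p$bo),
                heads, keep = keep)
  z1 <- x + at$out
  l2 <- layernorm_fw(z1, p$ln2.gamma, p$ln2.beta, keep = keep)
  h1 <- l2$out %*% p$W1 + rep(p$b1, each = N)
  g <- gelu_fw(h1)
  f <- g$out %*% p$W2 + rep(p$b2, each = N)
  out <- z1 + f
  list(out = out,
       cache = if (keep) list(l1 = l1$cache, at = at$cache, l2 = l2$cache,
                              ln_in2 = l2$out, gcache = g$cache,
                              gout = g$out, p = p) else NULL)
}

tblock_bw <- function(dout, cache) {
  p <- cache$p; N <- nrow(dout)
  # FFN branch
  dW2 <- crossprod(cache$gout, dout)
  db2 <- colSums(dout)
  dg <- tcrossprod(dout, p$W2)
  dh1 <- gelu_bw(dg, cache$gcache)
  dW1 <- crossprod(cache$ln_in2, dh1)
  db1 <- colSums(dh1)
  dl2 <- tcrossprod(dh1, p$W1)
  l2b <- layernorm_bw(dl2, cache$l2)
  dz1 <- dout + l2b$dx
  # attention branch
  ab <- mhsa_bw(dz1, cache$at)
  l1b <- layernorm_bw(ab$dx, cache$l1)
  dx <- dz1 + l1b$dx
  g <- ab$grads
  g$ln1.gamma <- l1b$dgamma; g$ln1.beta <- l1b$dbeta
  g$ln2.gamma <- l2b$dgamma; g$ln2.beta <- l2b$dbeta
  g$W1 <- dW1; g$b1 <- db1; g$W2 <- dW2; g$b2 <- db2
  list(dx = dx, grads = g)
}

# Row-major (height-major) tokenization: token t = (i-1)*W + j holds the
# feature vector of pixel (row i, col j). Inverse restores the grid exactly.
map_to_tokens <- function(xs) {
  d <- dim(xs)  # (H, W, C)
  matrix(aperm(xs, c(2, 1, 3)), d[1] * d[2], d[3])
}

tokens_to_map <- function(t, H, W) {
  aperm(array(t, c(W, H, ncol(t))), c(2, 1, 3))
}

#' Flatten a feature map into tokens and add positional embeddings
#'
#' Row-major tokenization of a (H, W, C, N) feature map into a
#' (H*W, C, N) token array, plus a learnable positional embedding shared
#' across the batch. The inverse reshape (\code{use tokens_to_feature_map})
#' restores the original grid bit-exactly.
#'
#' @param x feature map array of dim (H, W, C, N).
#' @param pos positional embedding matrix of dim (H*W, C).
#' @return token array of dim (H*W, C, N).
#' @export
flatten_add_positional <- function(x, pos) {
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (!is.matrix(pos) || nrow(pos) != d[1] * d[2] || ncol(pos) != d[3])
    stop_shape("positional embedding must be ", d[1] * d[2], " x ", d[3],
               ", got ", paste(dim(pos), collapse = " x "))
  out <- array(0, c(d[1] * d[2], d[3], d[4]))
  for (n in seq_len(d[4])) {
    out[, , n] <- map_to_tokens(array(x[, , , n], d[1:3])) + pos
  }
  out
}

#' @rdname flatten_add_positional
#' @param tokens token array of dim (H*W, C, N).
#' @param H,W spatial size of the target feature map.
#' @export
tokens_to_feature_map <- function(tokens, H, W) {
  d <- dim(tokens)
  if (length(d) == 2L) { dim(tokens) <- c(d, 1L); d <- dim(tokens) }
  if (d[1] != H * W) stop_shape("token count ", d[1], " != H*W = ", H * W)
  out <- array(0, c(H, W, d[2], d[3]))
  for (n in seq_len(d[3])) {
    out[, , , n] <- tokens_to_map(matrix(tokens[, , n], d[1], d[2]), H, W)
  }
  out
}

#' Multi-head scaled dot-product self-attention
#'
#' Computes \code{softmax(Q K' / sqrt(dk)) V} per head on a token sequence,
#' concatenates the head outputs and applies the output projection. The
#' projections are \code{Q = X Wq + bq} etc.; \code{dk = embed_dim / heads}.
#'
#' @param tokens (N_tok x C) matrix or (N_tok, C, B) array.
#' @param params list with Wq, bq, Wk, bk, Wv, bv, Wo, bo.
#' @param heads number of attention heads; must divide C.
#' @param return_attention also return the per-head attention matrices.
#' @return object like \code{tokens}; with attention as attribute if asked.
#' @export
multi_head_self_attention <- function(tokens, params, heads,
                                      return_attention = FALSE) {
  f <- function(m) mhsa_fw(m, params, heads, keep = return_attention)
  if (is.matrix(tokens)) {
    r <- f(tokens)
    out <- r$out
    if (return_attention) attr(out, "attention") <- r$cache$As
    return(out)
  }
  d <- dim(tokens)
  out <- array(0, d)
  attn <- if (return_attention) vector("list", d[3]) else NULL
  for (n in seq_len(d[3])) {
    r <- f(matrix(tokens[, , n], d[1], d[2]))
    out[, , n] <- r$out
    if (return_attention) attn[[n]] <- r$cache$As
  }
  if (return_attention) attr(out, "attention") <- attn
  out
}

#' Pre-norm transformer encoder block
#'
#' Applies \code{z' = z + MHSA(LN(z))} then \code{z'' = z' + FFN(LN(z'))}
#' with a GELU feed-forward network whose hidden width is
#' \code{mlp_ratio * embed_dim}.
#'
#' @param tokens (N_tok x C) matrix or (N_tok, C, B) array.
#' @param params flat list of block parameters (ln1/ln2 gamma+beta,
#'   attention projections, FFN W1/b1/W2/b2).
#' @param heads number of attention heads.
#' @return updated tokens, same shape as input.
#' @export
transformer_block <- function(tokens, params, heads) {
  if (is.matrix(tokens)) return(tblock_fw(tokens, params, heads)$out)
  d <- dim(tokens)
  out <- array(0, d)
  for (n in seq_len(d[3])) {
    out[, , n] <- tblock_fw(matrix(tokens[, , n], d[1], d[2]),
                            params, heads)$out
  }
  out
}
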