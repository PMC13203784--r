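# Low-level CNN primitives on (H, W, C, N) arrays with explicit forward and
# backward passes. Convolutions are computed as im2col + GEMM so all heavy
# arithmetic runs in BLAS; backward-data reuses the same routine with
# spatially flipped, channel-transposed kernels (stride-1 convolutions only;
# downsampling is done by max pooling and upsampling by 2x2/stride-2
# transposed convolution, which is non-overlapping and handled directly).

.geom_cache <- new.env(parent = emptyenv())

# Linear-index matrix mapping a padded (Hp, Wp, C) array to its im2col
# matrix of shape (k*k*C) x (Ho*Wo), stride 1. Cached per geometry.
im2col_idx <- function(H, W, C, k, pad) {
  key <- paste(H, W, C, k, pad, sep = "x")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- Hp - k + 1L; Wo <- Wp - k + 1L
  base <- as.vector(outer(seq_len(Ho), (seq_len(Wo) - 1L) * Hp, "+"))
  off <- as.vector(outer(as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+")),
                         (0:(C - 1L)) * Hp * Wp, "+"))
  idx <- outer(off, base, "+")
  out <- list(idx = idx, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
  .geom_cache[[key]] <- out
  out
}

pad_sample <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

# x: (H, W, Cin, N); W: (k, k, Cin, Cout); b: NULL or length-Cout.
# Returns list(out, cache) where cache holds the im2col matrices (training).
conv2d_fw <- function(x, W, b = NULL, pad = 1L, keep = FALSE) {
  d <- dim(x); k <- dim(W)[1]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  if (d[3] != Cin) stop_shape("conv2d: input has ", d[3],
                              " channels, kernel expects ", Cin)
  g <- im2col_idx(d[1], d[2], Cin, k, pad)
  Wmat <- matrix(W, k * k * Cin, Cout)
  out <- array(0, c(g$Ho, g$Wo, Cout, d[4]))
  cols <- if (keep) vector("list", d[4]) else NULL
  for (n in seq_len(d[4])) {
    xp <- pad_sample(array(x[, , , n], d[1:3]), pad)
    Xcol <- xp[g$idx]
    dim(Xcol) <- dim(g$idx)
    om <- crossprod(Wmat, Xcol)                      # Cout x (Ho*Wo)
    if (!is.null(b)) om <- om + as.numeric(b)
    out[, , , n] <- array(t(om), c(g$Ho, g$Wo, Cout))
    if (keep) cols[[n]] <- Xcol
  }
  list(out = out, cache = if (keep) list(cols = cols, W = W, b = b,
                                         pad = pad, xdim = d) else NULL)
}

conv2d_bw <- function(dout, cache) {
  W <- cache$W; k <- dim(W)[1]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  d <- dim(dout)
  dW <- matrix(0, k * k * Cin, Cout)
  db <- if (!is.null(cache$b)) numeric(Cout) else NULL
  for (n in seq_len(d[4])) {
    dm <- t(matrix(dout[, , , n], d[1] * d[2], Cout))   # Cout x S
    dW <- dW + tcrossprod(cache$cols[[n]], dm)
    if (!is.null(db)) db <- db + rowSums(dm)
  }
  # backward-data: convolve dout with flipped kernels, swapped in/out chans
  Wf <- aperm(W[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3))
  dx <- conv2d_fw(dout, Wf, b = NULL, pad = k - 1L - cache$pad)$out
  list(dx = dx, dW = array(dW, dim(W)), db = db)
}

# 2x2 stride-2 transposed convolution. W: (2, 2, Cout, Cin); b length Cout.
convtr2x2_fw <- function(x, W, b = NULL, keep = FALSE) {
  d <- dim(x); Cout <- dim(W)[3]; Cin <- dim(W)[4]
  if (d[3] != Cin) stop_shape("convtranspose: channel mismatch")
  H <- d[1]; Wd <- d[2]
  Wmat <- matrix(W, 4L * Cout, Cin)
  out <- array(0, c(2L * H, 2L * Wd, Cout, d[4]))
  xmats <- if (keep) vector("list", d[4]) else NULL
  for (n in seq_len(d[4])) {
    xmat <- t(matrix(x[, , , n], H * Wd, Cin))          # Cin x S
    oc <- Wmat %*% xmat                                  # (4*Cout) x S
    for (u in 1:2) for (v in 1:2) {
      sel <- seq(u + (v - 1L) * 2L, by = 4L, length.out = Cout)
      out[seq(u, 2L * H, 2L), seq(v, 2L * Wd, 2L), , n] <-
        array(t(oc[sel, , drop = FALSE]), c(H, Wd, Cout))
    }
    if (keep) xmats[[n]] <- xmat
  }
  if (!is.null(b)) out <- out + rep(b, each = 4L * H * Wd)
  list(out = out, cache = if (keep) list(xmats = xmats, W = W, b = b,
                                         xdim = d) else NULL)
}

convtr2x2_bw <- function(dout, cache) {
  W <- cache$W; Cout <- dim(W)[3]; Cin <- dim(W)[4]
  d <- cache$xdim; H <- d[1]; Wd <- d[2]
  Wmat <- matrix(W, 4L * Cout, Cin)
  dW <- matrix(0, 4L * Cout, Cin)
  db <- if (!is.null(cache$b)) numeric(Cout) else NULL
  dx <- array(0, d)
  for (n in seq_len(d[4])) {
    dc <- matrix(0, 4L * Cout, H * Wd)
    for (u in 1:2) for (v in 1:2) {
      sel <- seq(u + (v - 1L) * 2L, by = 4L, length.out = Cout)
      blk <- dout[seq(u, 2L * H, 2L), seq(v, 2L * Wd, 2L), , n, drop = FALSE]
      dc[sel, ] <- t(matrix(blk, H * Wd, Cout))
    }
    dx[, , , n] <- array(t(crossprod(Wmat, dc)), c(H, Wd, Cin))
    dW <- dW + tcrossprod(dc, cache$xmats[[n]])
    if (!is.null(db)) db <- db + colSums(matrix(rowSums(dc), 4L, Cout))
  }
  list(dx = dx, dW = array(dW, dim(W)), db = db)
}

relu_fw <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bw <- function(dout, cache) dout * cache

maxpool2x2_fw <- function(x) {
  d <- dim(x)
  ri <- seq(1L, d[1], 2L); ci <- seq(1L, d[2], 2L)
  a <- x[ri, ci, , , drop = FALSE]
  b <- x[ri + 1L, ci, , , drop = FALSE]
  cc <- x[ri, ci + 1L, , , drop = FALSE]
  dd <- x[ri + 1L, ci + 1L, , , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  s1 <- a == m
  s2 <- (b == m) & !s1
  s3 <- (cc == m) & !(s1 | s2)
  list(out = m, cache = list(s1 = s1, s2 = s2, s3 = s3, xdim = d))
}

maxpool2x2_bw <- function(dout, cache) {
  d <- cache$xdim
  ri <- seq(1L, d[1], 2L); ci <- seq(1L, d[2], 2L)
  dx <- array(0, d)
  s4 <- !(cache$s1 | cache$s2 | cache$s3)
  put <- function(sel, roff, coff) {
    tmp <- array(0, dim(dout)); tmp[sel] <- dout[sel]
    dx[ri + roff, ci + coff, , ] <<- tmp
  }
  put(cache$s1, 0L, 0L); put(cache$s2, 1L, 0L)
  put(cache$s3, 0L, 1L); put(s4, 1L, 1L)
  dx
}

# Batch normalization over (H, W, N) per channel. params: gamma, beta;
# buffers: running_mean, running_var (unbiased), updated in training mode.
batchnorm_fw <- function(x, gamma, beta, rmean, rvar, train,
                         momentum = 0.1, eps = 1e-5, keep = FALSE) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]; n <- HW * N
  if (train) {
    cs <- colMeans(matrix(x, HW, C * N))
    mu <- rowMeans(matrix(cs, C, N))
    cs2 <- colMeans(matrix(x * x, HW, C * N))
    vb <- rowMeans(matrix(cs2, C, N)) - mu^2
    vb <- pmax(vb, 0)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar +
      momentum * vb * (if (n > 1) n / (n - 1) else 1)
  } else {
    mu <- rmean; vb <- rvar
  }
  invstd <- 1 / sqrt(vb + eps)
  mu_v <- rep(rep(mu, each = HW), N)
  is_v <- rep(rep(invstd, each = HW), N)
  xhat <- (x - mu_v) * is_v
  out <- xhat * rep(rep(gamma, each = HW), N) + rep(rep(beta, each = HW), N)
  list(out = out, rmean = rmean, rvar = rvar,
       cache = if (keep) list(xhat = xhat, invstd = invstd, gamma = gamma,
                              d = d) else NULL)
}

batchnorm_bw <- function(dout, cache) {
  d <- cache$d; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]; n <- HW * N
  csum <- function(a) rowSums(matrix(colSums(matrix(a, HW, C * N)), C, N))
  dbeta <- csum(dout)
  dgamma <- csum(dout * cache$xhat)
  g_v <- rep(rep(cache$gamma * cache$invstd / n, each = HW), N)
  dx <- g_v * (n * dout - rep(rep(dbeta, each = HW), N) -
                 cache$xhat * rep(rep(dgamma, each = HW), N))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Dense bilinear resampling matrix (Ho x H), half-pixel-center convention.
bilinear_matrix <- function(H, Ho) {
  A <- matrix(0, Ho, H)
  for (i in seq_len(Ho)) {
    src <- (i - 0.5) * H / Ho + 0.5
    i0 <- floor(src); w <- src - i0
    i0c <- min(max(i0, 1L), H); i1c <- min(max(i0 + 1L, 1L), H)
    A[i, i0c] <- A[i, i0c] + (1 - w)
    A[i, i1c] <- A[i, i1c] + w
  }
  A
}

apply_rows <- function(A, x) {
  d <- dim(x)
  y <- A %*% matrix(x, d[1], prod(d[-1]))
  array(y, c(nrow(A), d[-1]))
}

# Bilinear resize of (H, W, C, N) to (Ho, Wo, C, N); exactly linear, so the
# backward pass is the transposed map.
bilinear_resize <- function(x, Ho, Wo) {
  d <- dim(x)
  if (d[1] == Ho && d[2] == Wo) return(x)
  Ah <- bilinear_matrix(d[1], Ho); Aw <- bilinear_matrix(d[2], Wo)
  y <- apply_rows(Ah, x)
  y <- aperm(apply_rows(Aw, aperm(y, c(2, 1, 3, 4))), c(2, 1, 3, 4))
  y
}

bilinear_resize_bw <- function(dout, H, W) {
  d <- dim(dout)
  if (d[1] == H && d[2] == W) return(dout)
  Ah <- t(bilinear_matrix(H, d[1])); Aw <- t(bilinear_matrix(W, d[2]))
  y <- apply_rows(Ah, dout)
  aperm(apply_rows(Aw, aperm(y, c(2, 1, 3, 4))), c(2, 1, 3, 4))
}
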