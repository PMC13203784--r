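# Hybrid residual-CNN / Transformer U-Net: parameter construction, forward
# pass (training and evaluation modes) and hand-wired backpropagation.
# Parameters live in a flat named list (hierarchical dotted names); those
# names are the stable matching key used by warm-start transfer.

he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

xavier_init <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

init_resblock <- function(P, Bf, prefix, Cin, Cout) {
  P[[paste0(prefix, ".conv1.W")]] <- he_init(c(3, 3, Cin, Cout), 9 * Cin)
  P[[paste0(prefix, ".bn1.gamma")]] <- rep(1, Cout)
  P[[paste0(prefix, ".bn1.beta")]] <- rep(0, Cout)
  P[[paste0(prefix, ".conv2.W")]] <- he_init(c(3, 3, Cout, Cout), 9 * Cout)
  P[[paste0(prefix, ".bn2.gamma")]] <- rep(1, Cout)
  P[[paste0(prefix, ".bn2.beta")]] <- rep(0, Cout)
  if (Cin != Cout) {
    P[[paste0(prefix, ".proj.W")]] <- he_init(c(1, 1, Cin, Cout), Cin)
    P[[paste0(prefix, ".projbn.gamma")]] <- rep(1, Cout)
    P[[paste0(prefix, ".projbn.beta")]] <- rep(0, Cout)
    Bf[[paste0(prefix, ".projbn.running_mean")]] <- rep(0, Cout)
    Bf[[paste0(prefix, ".projbn.running_var")]] <- rep(1, Cout)
  }
  for (bn in c("bn1", "bn2")) {
    Bf[[paste0(prefix, ".", bn, ".running_mean")]] <- rep(0, Cout)
    Bf[[paste0(prefix, ".", bn, ".running_var")]] <- rep(1, Cout)
  }
  list(P = P, Bf = Bf)
}

init_tblock <- function(P, prefix, C, hid) {
  P[[paste0(prefix, ".ln1.gamma")]] <- rep(1, C)
  P[[paste0(prefix, ".ln1.beta")]] <- rep(0, C)
  for (w in c("Wq", "Wk", "Wv", "Wo")) {
    P[[paste0(prefix, ".", w)]] <- xavier_init(C, C)
  }
  for (b in c("bq", "bk", "bv", "bo")) P[[paste0(prefix, ".", b)]] <- rep(0, C)
  P[[paste0(prefix, ".ln2.gamma")]] <- rep(1, C)
  P[[paste0(prefix, ".ln2.beta")]] <- rep(0, C)
  P[[paste0(prefix, ".W1")]] <- xavier_init(C, hid)
  P[[paste0(prefix, ".b1")]] <- rep(0, hid)
  P[[paste0(prefix, ".W2")]] <- xavier_init(hid, C)
  P[[paste0(prefix, ".b2")]] <- rep(0, C)
  P
}

#' Construct a hybrid U-Net model
#'
#' Builds the full parameter set of the hybrid residual-CNN / Transformer
#' U-Net described by an \code{\link{arch_config}}: a residual encoder whose
#' channel width doubles over \code{num_stages} stages, a bottleneck of two
#' residual blocks that double the channels again, an optional stack of
#' pre-norm Transformer blocks over the tokenized bottleneck map, a
#' skip-connected transposed-convolution decoder, and a 1x1 sigmoid output
#' head. All weights are drawn from a generator seeded by \code{seed}, so
#' construction is reproducible.
#'
#' @param cfg an \code{\link{arch_config}}.
#' @param seed integer seed for parameter initialization.
#' @return an object of class \code{hybrid_unet}: list with \code{cfg},
#'   flat named \code{params}, and normalization \code{buffers}.
#' @examples
#' m <- hybrid_unet(arch_config(base_channels = 8, input_size = 64,
#'                              transformer_layers = 2), seed = 1)
#' count_parameters(m)$total
#' @export
hybrid_unet <- function(cfg, seed = 0L) {
  validate_arch_config(cfg)
  with_seed(seed, {
    P <- list(); Bf <- list()
    S <- cfg$num_stages
    chans <- cfg$base_channels * 2^(seq_len(S) - 1L)
    # encoder
    for (s in seq_len(S)) {
      cin <- if (s == 1L) cfg$in_channels else chans[s - 1L]
      for (b in seq_len(cfg$residual_blocks_per_stage)) {
        r <- init_resblock(P, Bf, sprintf("enc%d.block%d", s, b),
                           if (b == 1L) cin else chans[s], chans[s])
        P <- r$P; Bf <- r$Bf
      }
    }
    # bottleneck CNN: two residual blocks, top -> 2*top channels
    top <- chans[S]; bc <- cfg$bottleneck_channels
    r <- init_resblock(P, Bf, "bot.block1", top, bc); P <- r$P; Bf <- r$Bf
    r <- init_resblock(P, Bf, "bot.block2", bc, bc); P <- r$P; Bf <- r$Bf
    # transformer
    if (cfg$use_transformer) {
      side <- cfg$input_size %/% 2^S
      ntok <- side * side
      P[["transformer.pos"]] <- matrix(rnorm(ntok * bc, 0, 0.02), ntok, bc)
      hid <- as.integer(round(cfg$mlp_ratio * bc))
      for (l in seq_len(cfg$transformer_layers)) {
        P <- init_tblock(P, sprintf("transformer.layer%d", l), bc, hid)
      }
    }
    # decoder
    for (s in rev(seq_len(S))) {
      cs <- chans[s]
      P[[sprintf("dec%d.up.W", s)]] <- he_init(c(2, 2, cs, 2L * cs), 2L * cs)
      P[[sprintf("dec%d.up.b", s)]] <- rep(0, cs)
      r <- init_resblock(P, Bf, sprintf("dec%d.block1", s), 2L * cs, cs)
      P <- r$P; Bf <- r$Bf
      r <- init_resblock(P, Bf, sprintf("dec%d.block2", s), cs, cs)
      P <- r$P; Bf <- r$Bf
    }
    # output head: 1x1 conv with bias
    P[["head.W"]] <- he_init(c(1, 1, cfg$base_channels, 1L), cfg$base_channels)
    P[["head.b"]] <- 0
    structure(list(cfg = cfg, params = P, buffers = Bf),
              class = "hybrid_unet")
  })
}

#' @export
print.hybrid_unet <- function(x, ...) {
  pc <- count_parameters(x)
  print(x$cfg)
  cat(sprintf("  parameters: %s total (%s transformer, %s CNN)\n",
              format(pc$total, big.mark = ","),
              format(pc$transformer_part, big.mark = ","),
              format(pc$cnn_part, big.mark = ",")))
  invisible(x)
}

# --- residual block forward/backward -----------------------------------

resblock_fw <- function(x, P, Bf, prefix, train, keep) {
  pn <- function(s) paste0(prefix, ".", s)
  has_proj <- !is.null(P[[pn("proj.W")]])
  cv1 <- conv2d_fw(x, P[[pn("conv1.W")]], pad = 1L, keep = keep)
  b1 <- batchnorm_fw(cv1$out, P[[pn("bn1.gamma")]], P[[pn("bn1.beta")]],
                     Bf[[pn("bn1.running_mean")]], Bf[[pn("bn1.running_var")]],
                     train, keep = keep)
  Bf[[pn("bn1.running_mean")]] <- b1$rmean
  Bf[[pn("bn1.running_var")]] <- b1$rvar
  r1 <- relu_fw(b1$out)
  cv2 <- conv2d_fw(r1$out, P[[pn("conv2.W")]], pad = 1L, keep = keep)
  b2 <- batchnorm_fw(cv2$out, P[[pn("bn2.gamma")]], P[[pn("bn2.beta")]],
                     Bf[[pn("bn2.running_mean")]], Bf[[pn("bn2.running_var")]],
                     train, keep = keep)
  Bf[[pn("bn2.running_mean")]] <- b2$rmean
  Bf[[pn("bn2.running_var")]] <- b2$rvar
  if (has_proj) {
    pj <- conv2d_fw(x, P[[pn("proj.W")]], pad = 0L, keep = keep)
    pb <- batchnorm_fw(pj$out, P[[pn("projbn.gamma")]], P[[pn("projbn.beta")]],
                       Bf[[pn("projbn.running_mean")]],
                       Bf[[pn("projbn.running_var")]], train, keep = keep)
    Bf[[pn("projbn.running_mean")]] <- pb$rmean
    Bf[[pn("projbn.running_var")]] <- pb$rvar
    s <- pb$out
  } else {
    pj <- NULL; pb <- NULL
    s <- x
  }
  z <- b2$out + s
  out <- relu_fw(z)
  list(out = out$out, Bf = Bf,
       cache = if (keep) list(cv1 = cv1$cache, b1 = b1$cache, r1 = r1$cache,
                              cv2 = cv2$cache, b2 = b2$cache,
                              pj = if (has_proj) pj$cache else NULL,
                              pb = if (has_proj) pb$cache else NULL,
                              relu_out = out$cache, has_proj = has_proj,
                              prefix = prefix) else NULL)
}

resblock_bw <- function(dout, cache, G) {
  pn <- function(s) paste0(cache$prefix, ".", s)
  dz <- relu_bw(dout, cache$relu_out)
  b2 <- batchnorm_bw(dz, cache$b2)
  G[[pn("bn2.gamma")]] <- b2$dgamma; G[[pn("bn2.beta")]] <- b2$dbeta
  c2 <- conv2d_bw(b2$dx, cache$cv2)
  G[[pn("conv2.W")]] <- c2$dW
  dr1 <- relu_bw(c2$dx, cache$r1)
  b1 <- batchnorm_bw(dr1, cache$b1)
  G[[pn("bn1.gamma")]] <- b1$dgamma; G[[pn("bn1.beta")]] <- b1$dbeta
  c1 <- conv2d_bw(b1$dx, cache$cv1)
  G[[pn("conv1.W")]] <- c1$dW
  dx <- c1$dx
  if (cache$has_proj) {
    pb <- batchnorm_bw(dz, cache$pb)
    G[[pn("projbn.gamma")]] <- pb$dgamma; G[[pn("projbn.beta")]] <- pb$dbeta
    pj <- conv2d_bw(pb$dx, cache$pj)
    G[[pn("proj.W")]] <- pj$dW
    dx <- dx + pj$dx
  } else {
    dx <- dx + dz
  }
  list(dx = dx, G = G)
}

#' Standalone residual block
#'
#' A residual block applies conv3x3 -> batch norm -> ReLU -> conv3x3 ->
#' batch norm, adds a skip path (identity when the channel counts match,
#' otherwise a 1x1 projection followed by batch norm) and applies a final
#' ReLU. \code{residual_block_params} builds a fresh parameter set;
#' \code{residual_block_forward} runs the block.
#'
#' @param Cin,Cout input and output channel counts.
#' @param seed seed for weight initialization.
#' @return \code{residual_block_params}: list with \code{params} and
#'   \code{buffers}; \code{residual_block_forward}: output feature map.
#' @export
residual_block_params <- function(Cin, Cout, seed = 0L) {
  with_seed(seed, {
    r <- init_resblock(list(), list(), "rb", Cin, Cout)
    list(params = r$P, buffers = r$Bf)
  })
}

#' @rdname residual_block_params
#' @param x feature map (H, W, Cin, N) (a 3-D array is taken as N = 1).
#' @param block a list as returned by \code{residual_block_params}.
#' @param train use batch statistics (TRUE) or running statistics (FALSE).
#' @export
residual_block_forward <- function(x, block, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  Cin <- dim(block$params[["rb.conv1.W"]])[3]
  if (d[3] != Cin) stop_shape("residual block expects ", Cin,
                              " channels, got ", d[3])
  resblock_fw(x, block$params, block$buffers, "rb", train, keep = FALSE)$out
}

# --- encoder / bottleneck / decoder ------------------------------------

#' Run the residual encoder
#'
#' Applies the encoder stages (residual blocks followed by 2x2 max pooling)
#' and returns the pre-pool skip maps plus the pooled bottom map. With the
#' default config a 256x256 input yields post-pool shapes
#' 32x128x128, 64x64x64, 128x32x32 and 256x16x16.
#'
#' @param model a \code{\link{hybrid_unet}}.
#' @param image array (H, W, C, N) or (H, W, C).
#' @param train training mode flag (batch-norm statistics).
#' @return list with \code{skips} (pre-pool feature maps, one per stage)
#'   and \code{bottom} (final pooled map).
#' @export
encoder_forward <- function(model, image, train = FALSE) {
  if (length(dim(image)) == 3L) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  S <- model$cfg$num_stages
  if (d[1] %% 2^S != 0 || d[2] %% 2^S != 0)
    stop_config("input size ", d[1], "x", d[2],
                " not divisible by 2^num_stages = ", 2^S)
  if (d[3] != model$cfg$in_channels)
    stop_shape("input has ", d[3], " channels, config expects ",
               model$cfg$in_channels)
  r <- encoder_fw(image, model$params, model$buffers, model$cfg,
                  train, keep = FALSE)
  list(skips = r$skips, bottom = r$x)
}

encoder_fw <- function(x, P, Bf, cfg, train, keep) {
  S <- cfg$num_stages
  skips <- vector("list", S)
  caches <- if (keep) vector("list", S) else NULL
  for (s in seq_len(S)) {
    bl <- vector("list", cfg$residual_blocks_per_stage)
    for (b in seq_len(cfg$residual_blocks_per_stage)) {
      r <- resblock_fw(x, P, Bf, sprintf("enc%d.block%d", s, b), train, keep)
      x <- r$out; Bf <- r$Bf
      if (keep) bl[[b]] <- r$cache
    }
    skips[[s]] <- x
    mp <- maxpool2x2_fw(x)
    x <- mp$out
    if (keep) caches[[s]] <- list(blocks = bl, pool = mp$cache)
  }
  list(x = x, skips = skips, Bf = Bf, caches = caches)
}

#' Run the bottleneck (CNN widening plus optional Transformer)
#'
#' Two residual blocks double the channel width of the encoder's pooled
#' bottom map at unchanged resolution; if the config enables the
#' Transformer, the map is tokenized row-major, augmented with learnable
#' positional embeddings, passed through the Transformer layers and
#' reshaped back. With \code{use_transformer = FALSE} the CNN map passes
#' through untouched (plain-U-Net ablation).
#'
#' @inheritParams encoder_forward
#' @param x the encoder's pooled bottom feature map.
#' @return feature map with \code{bottleneck_channels} channels.
#' @export
bottleneck_forward <- function(model, x, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  bottleneck_fw(x, model$params, model$buffers, model$cfg,
                train, keep = FALSE)$x
}

bottleneck_fw <- function(x, P, Bf, cfg, train, keep) {
  r1 <- resblock_fw(x, P, Bf, "bot.block1", train, keep); Bf <- r1$Bf
  r2 <- resblock_fw(r1$out, P, Bf, "bot.block2", train, keep); Bf <- r2$Bf
  x <- r2$out
  tcache <- NULL; tokens_in <- NULL
  if (cfg$use_transformer) {
    d <- dim(x)
    pos <- P[["transformer.pos"]]
    tok <- flatten_add_positional(x, pos)
    if (keep) tokens_in <- dim(tok)
    L <- cfg$transformer_layers
    tcache <- if (keep) vector("list", L) else NULL
    for (l in seq_len(L)) {
      p <- tblock_params(P, sprintf("transformer.layer%d", l))
      lc <- if (keep) vector("list", d[4]) else NULL
      for (n in seq_len(d[4])) {
        r <- tblock_fw(matrix(tok[, , n], dim(tok)[1], dim(tok)[2]),
                       p, cfg$attention_heads, keep = keep)
        tok[, , n] <- r$out
        if (keep) lc[[n]] <- r$cache
      }
      if (keep) tcache[[l]] <- lc
    }
    x <- tokens_to_feature_map(tok, d[1], d[2])
  }
  list(x = x, Bf = Bf,
       cache = if (keep) list(r1 = r1$cache, r2 = r2$cache,
                              tcache = tcache) else NULL)
}

tblock_params <- function(P, prefix) {
  keys <- c("ln1.gamma", "ln1.beta", "Wq", "bq", "Wk", "bk", "Wv", "bv",
            "Wo", "bo", "ln2.gamma", "ln2.beta", "W1", "b1", "W2", "b2")
  p <- lapply(keys, function(k) P[[paste0(prefix, ".", k)]])
  names(p) <- keys
  p
}

#' Run one decoder block
#'
#' Learned 2x upsampling via 2x2/stride-2 transposed convolution, bilinear
#' alignment to the skip map's spatial size if they differ, channel
#' concatenation with the skip, then two residual blocks that halve the
#' channel count.
#'
#' @inheritParams encoder_forward
#' @param x decoder input feature map.
#' @param skip the matching encoder skip map.
#' @param stage decoder stage index (num_stages .. 1).
#' @return feature map at the skip's resolution.
#' @export
decoder_block_forward <- function(model, x, skip, stage, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(skip)) == 3L) dim(skip) <- c(dim(skip), 1L)
  decblock_fw(x, skip, model$params, model$buffers, stage,
              train, keep = FALSE)$out
}

decblock_fw <- function(x, skip, P, Bf, s, train, keep) {
  up <- convtr2x2_fw(x, P[[sprintf("dec%d.up.W", s)]],
                     P[[sprintf("dec%d.up.b", s)]], keep = keep)
  u <- up$out
  ud <- dim(u); sd <- dim(skip)
  aligned_from <- NULL
  if (ud[1] != sd[1] || ud[2] != sd[2]) {
    aligned_from <- ud[1:2]
    u <- bilinear_resize(u, sd[1], sd[2])
  }
  cat_x <- array(0, c(sd[1], sd[2], dim(u)[3] + sd[3], sd[4]))
  cat_x[, , seq_len(dim(u)[3]), ] <- u
  cat_x[, , dim(u)[3] + seq_len(sd[3]), ] <- skip
  r1 <- resblock_fw(cat_x, P, Bf, sprintf("dec%d.block1", s), train, keep)
  Bf <- r1$Bf
  r2 <- resblock_fw(r1$out, P, Bf, sprintf("dec%d.block2", s), train, keep)
  Bf <- r2$Bf
  list(out = r2$out, Bf = Bf,
       cache = if (keep) list(up = up$cache, r1 = r1$cache, r2 = r2$cache,
                              nup = dim(u)[3], aligned_from = aligned_from,
                              s = s) else NULL)
}

# --- full model --------------------------------------------------------

#' Forward pass of the hybrid U-Net
#'
#' Maps a batch of images to per-pixel foreground probabilities via the
#' sigmoid output head. In training mode batch-norm uses batch statistics
#' and updates its running buffers (returned so the caller can store them);
#' in evaluation mode the stored statistics are used, making the pass
#' deterministic.
#'
#' @param model a \code{\link{hybrid_unet}}.
#' @param image array (H, W, C, N) or (H, W, C) with H = W = input_size.
#' @param train training mode flag.
#' @param keep keep intermediate activations for backpropagation.
#' @return list with \code{prob} (probabilities in [0,1], dim
#'   (H, W, 1, N)), \code{logits}, updated \code{buffers}, and (if
#'   \code{keep}) an opaque \code{cache} for \code{model_backward}.
#' @export
model_forward <- function(model, image, train = FALSE, keep = FALSE) {
  if (length(dim(image)) == 3L) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  cfg <- model$cfg
  if (d[1] != cfg$input_size || d[2] != cfg$input_size)
    stop_config("input is ", d[1], "x", d[2], ", config expects ",
                cfg$input_size, "x", cfg$input_size)
  P <- model$params
  enc <- encoder_fw(image, P, model$buffers, cfg, train, keep)
  Bf <- enc$Bf
  bot <- bottleneck_fw(enc$x, P, Bf, cfg, train, keep)
  Bf <- bot$Bf
  x <- bot$x
  dec_caches <- if (keep) vector("list", cfg$num_stages) else NULL
  for (s in rev(seq_len(cfg$num_stages))) {
    r <- decblock_fw(x, enc$skips[[s]], P, Bf, s, train, keep)
    x <- r$out; Bf <- r$Bf
    if (keep) dec_caches[[s]] <- r$cache
  }
  hd <- conv2d_fw(x, P[["head.W"]], P[["head.b"]], pad = 0L, keep = keep)
  logits <- hd$out
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, logits = logits, buffers = Bf,
       cache = if (keep) list(enc = enc$caches, bot = bot$cache,
                              dec = dec_caches, head = hd$cache,
                              xdim = d) else NULL)
}

# Backward pass: dlogits has the logits' shape; returns flat grads list
# aligned with model$params names.
model_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg
  G <- list()
  hb <- conv2d_bw(dlogits, cache$head)
  G[["head.W"]] <- hb$dW; G[["head.b"]] <- hb$db
  dx <- hb$dx
  dskips <- vector("list", cfg$num_stages)
  for (s in seq_len(cfg$num_stages)) {
    cc <- cache$dec[[s]]
    r2 <- resblock_bw(dx, cc$r2, G); G <- r2$G
    r1 <- resblock_bw(r2$dx, cc$r1, G); G <- r1$G
    dcat <- r1$dx
    nup <- cc$nup
    dup <- dcat[, , seq_len(nup), , drop = FALSE]
    dskips[[s]] <- dcat[, , nup + seq_len(dim(dcat)[3] - nup), , drop = FALSE]
    if (!is.null(cc$aligned_from))
      dup <- bilinear_resize_bw(dup, cc$aligned_from[1], cc$aligned_from[2])
    ub <- convtr2x2_bw(dup, cc$up)
    G[[sprintf("dec%d.up.W", cc$s)]] <- ub$dW
    G[[sprintf("dec%d.up.b", cc$s)]] <- ub$db
    dx <- ub$dx
  }
  # bottleneck
  if (cfg$use_transformer) {
    d <- dim(dx)
    dtok <- array(0, c(d[1] * d[2], d[3], d[4]))
    for (n in seq_len(d[4])) {
      dtok[, , n] <- map_to_tokens(array(dx[, , , n], d[1:3]))
    }
    for (l in rev(seq_len(cfg$transformer_layers))) {
      prefix <- sprintf("transformer.layer%d", l)
      for (n in seq_len(d[4])) {
        r <- tblock_bw(matrix(dtok[, , n], d[1] * d[2], d[3]),
                       cache$bot$tcache[[l]][[n]])
        dtok[, , n] <- r$dx
        for (k in names(r$grads)) {
          key <- paste0(prefix, ".", k)
          G[[key]] <- if (is.null(G[[key]])) r$grads[[k]] else
            G[[key]] + r$grads[[k]]
        }
      }
    }
    G[["transformer.pos"]] <- matrix(rowSums(matrix(dtok, d[1] * d[2] * d[3],
                                                    d[4])),
                                     d[1] * d[2], d[3])
    for (n in seq_len(d[4])) {
      dx[, , , n] <- tokens_to_map(matrix(dtok[, , n], d[1] * d[2], d[3]),
                                   d[1], d[2])
    }
  }
  r2 <- resblock_bw(dx, cache$bot$r2, G); G <- r2$G
  r1 <- resblock_bw(r2$dx, cache$bot$r1, G); G <- r1$G
  dx <- r1$dx
  # encoder (reverse)
  for (s in rev(seq_len(cfg$num_stages))) {
    cc <- cache$enc[[s]]
    dx <- maxpool2x2_bw(dx, cc$pool)
    dx <- dx + dskips[[s]]
    for (b in rev(seq_len(cfg$residual_blocks_per_stage))) {
      rb <- resblock_bw(dx, cc$blocks[[b]], G)
      dx <- rb$dx; G <- rb$G
    }
  }
  G
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground (1) iff its probability is greater than or equal
#' to the threshold; the tie at the threshold is assigned to foreground,
#' so the documented 0.5 cut is inclusive.
#'
#' @param p probability array with values in [0, 1].
#' @param threshold scalar in [0, 1] (default 0.5).
#' @return integer array of 0/1 with the same shape as \code{p}.
#' @export
binarize <- function(p, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]")
  out <- p
  out[] <- as.integer(p >= threshold)
  out
}

#' Count trainable parameters by component
#'
#' Sums the sizes of all trainable arrays (normalization running statistics
#' are buffers, not parameters) and splits the total into the Transformer
#' part (positional embedding plus all Transformer layer weights) and the
#' CNN part (everything else). The split is by parameter name, so
#' \code{total = transformer_part + cnn_part} by construction and the count
#' is independent of batch size or input contents.
#'
#' @param model a \code{\link{hybrid_unet}}.
#' @return list with \code{total}, \code{transformer_part}, \code{cnn_part}
#'   and a named per-parameter vector \code{by_name}.
#' @export
count_parameters <- function(model) {
  sizes <- vapply(model$params, length, integer(1))
  is_tr <- startsWith(names(sizes), "transformer.")
  list(total = sum(sizes),
       transformer_part = sum(sizes[is_tr]),
       cnn_part = sum(sizes[!is_tr]),
       by_name = sizes)
}

# --- checkpoints -------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the flat parameter map
#' (hierarchical names -> arrays), the normalization buffers, the
#' architecture config, the epoch index and the best validation Dice.
#' Parameter names are stable across versions; they are the matching key
#' used by \code{\link{warm_start}}.
#'
#' @param model a \code{\link{hybrid_unet}}.
#' @param path file path (.rds).
#' @param epoch epoch index at which the checkpoint was taken.
#' @param best_val_dice best validation Dice so far.
#' @param optimizer optional optimizer state to allow exact resumption.
#' @return \code{load_checkpoint} returns the checkpoint list.
#' @export
save_checkpoint <- function(model, path, epoch = 0L, best_val_dice = NA_real_,
                            optimizer = NULL) {
  obj <- list(format = "lesionseg-checkpoint-1",
              params = model$params, buffers = model$buffers,
              arch = unclass(model$cfg), epoch = as.integer(epoch),
              best_val_dice = best_val_dice, optimizer = optimizer)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_io("checkpoint file not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop_io("corrupt checkpoint file: ", path, " (", conditionMessage(e), ")"))
  if (!is.list(obj) || !identical(obj$format, "lesionseg-checkpoint-1"))
    stop_io("corrupt checkpoint file (unrecognized format): ", path)
  obj
}

#' @rdname save_checkpoint
#' @param checkpoint a checkpoint list from \code{load_checkpoint}.
#' @export
model_from_checkpoint <- function(checkpoint) {
  cfg <- do.call(arch_config, checkpoint$arch)
  structure(list(cfg = cfg, params = checkpoint$params,
                 buffers = checkpoint$buffers), class = "hybrid_unet")
}
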