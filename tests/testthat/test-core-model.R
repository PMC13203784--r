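# Core architecture: parameter formula, residual blocks, encoder shapes,
# tokenization, attention, bottleneck and the full forward contract.

test_that("conv_param_count follows Cout*Cin*k^2 (+Cout with bias)", {
  expect_identical(conv_param_count(32, 1, 1, bias = TRUE), 33L)
  expect_identical(conv_param_count(3, 32, 3, bias = FALSE), 864L)
  expect_identical(conv_param_count(1, 1, 1, bias = TRUE), 2L)
  expect_error(conv_param_count(0, 4, 3), "positive")
  expect_error(conv_param_count(4, -1, 3), "positive")
})

test_that("arch_config enforces its invariants", {
  cfg <- arch_config()
  expect_equal(cfg$bottleneck_channels, 512L)
  expect_error(arch_config(input_size = 250), "divisible")
  expect_error(arch_config(bottleneck_channels = 300), "2 x top")
  expect_error(arch_config(attention_heads = 7), "divisible")
  rt <- tempfile(fileext = ".yaml")
  write_arch_config(cfg, rt)
  expect_equal(read_arch_config(rt), cfg)
})

test_that("residual block: identity behaviour, shapes, oracle equivalence", {
  # zero conv weights + identity normalization pass non-negative input through
  blk <- residual_block_params(3, 3, seed = 1)
  for (k in c("rb.conv1.W", "rb.conv2.W")) blk$params[[k]][] <- 0
  x <- array(runif(6 * 6 * 3), c(6, 6, 3, 1))
  expect_equal(residual_block_forward(x, blk, train = FALSE), x,
               tolerance = 1e-5)  # eval BN with fresh stats is ~identity

  blk2 <- residual_block_params(32, 32, seed = 2)
  x2 <- array(rnorm(8 * 8 * 32), c(8, 8, 32, 1))
  expect_equal(dim(residual_block_forward(x2, blk2)), c(8, 8, 32, 1))
  expect_error(residual_block_forward(x, blk2), class = "lesionseg_shape_error")

  # brute-force composition oracle: ReLU(BN(Conv)) -> BN(Conv) -> +skip -> ReLU
  blk3 <- residual_block_params(4, 4, seed = 3)
  x3 <- array(rnorm(5 * 5 * 4), c(5, 5, 4, 1))
  got <- residual_block_forward(x3, blk3, train = TRUE)
  conv_naive <- function(x, W) {
    H <- dim(x)[1]; Wd <- dim(x)[2]; Cout <- dim(W)[4]; k <- dim(W)[1]
    xp <- array(0, c(H + 2, Wd + 2, dim(x)[3]))
    xp[2:(H + 1), 2:(Wd + 1), ] <- x[, , , 1]
    out <- array(0, c(H, Wd, Cout, 1))
    for (i in 1:H) for (j in 1:Wd) for (o in 1:Cout)
      out[i, j, o, 1] <- sum(xp[i:(i + k - 1), j:(j + k - 1), ] * W[, , , o])
    out
  }
  bn_naive <- function(x) {  # batch stats, gamma=1, beta=0
    for (c in seq_len(dim(x)[3])) {
      v <- x[, , c, 1]
      x[, , c, 1] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
    }
    x
  }
  y <- pmax(bn_naive(conv_naive(x3, blk3$params[["rb.conv1.W"]])), 0)
  z <- bn_naive(conv_naive(y, blk3$params[["rb.conv2.W"]]))
  want <- pmax(z + x3, 0)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("encoder halves resolution and doubles channels per stage", {
  m <- hybrid_unet(arch_config(base_channels = 8, input_size = 64,
                               transformer_layers = 1), seed = 1)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  enc <- encoder_forward(m, x)
  chans <- vapply(enc$skips, function(s) dim(s)[3], numeric(1))
  expect_equal(chans, 8 * 2^(0:3))
  sizes <- vapply(enc$skips, function(s) dim(s)[1], numeric(1))
  expect_equal(sizes, 64 / 2^(0:3))
  expect_equal(dim(enc$bottom), c(4, 4, 64, 1))
  bad <- array(0, c(60, 60, 3, 1))
  expect_error(encoder_forward(m, bad), class = "lesionseg_config_error")
})

test_that("tokenization is row-major, additive, and exactly invertible", {
  set.seed(9)
  x <- array(rnorm(4 * 4 * 5), c(4, 4, 5, 1))
  pos0 <- matrix(0, 16, 5)
  tok <- flatten_add_positional(x, pos0)
  expect_equal(dim(tok), c(16, 5, 1))
  # token t = (i-1)*W + j
  expect_equal(tok[(2 - 1) * 4 + 3, , 1], x[2, 3, , 1])
  expect_identical(tokens_to_feature_map(tok, 4, 4), x)
  pos <- matrix(rnorm(16 * 5), 16, 5)
  expect_equal(flatten_add_positional(x, pos)[, , 1], tok[, , 1] + pos)
  expect_error(flatten_add_positional(x, matrix(0, 15, 5)),
               class = "lesionseg_shape_error")
})

test_that("multi-head attention matches the dense oracle and is stochastic", {
  for (case in list(list(N = 3, C = 2, h = 1), list(N = 8, C = 8, h = 2),
                    list(N = 5, C = 6, h = 3))) {
    p <- random_attn_params(case$C, seed = case$N)
    X <- matrix(rnorm(case$N * case$C), case$N, case$C)
    got <- multi_head_self_attention(X, p, case$h)
    expect_equal(got, attention_oracle(X, p, case$h), tolerance = 1e-5)
  }
  # attention rows sum to 1
  p <- random_attn_params(4, seed = 2)
  X <- matrix(rnorm(6 * 4), 6, 4)
  at <- attr(multi_head_self_attention(X, p, 2, return_attention = TRUE),
             "attention")
  for (A in at) expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-6)
  expect_true(all(vapply(at, function(A) all(A >= 0), logical(1))))
  # single token: output = Wo'(V) + bo regardless of Q, K
  X1 <- matrix(rnorm(4), 1, 4)
  o1 <- multi_head_self_attention(X1, p, 2)
  V1 <- X1 %*% p$Wv + matrix(p$bv, 1, 4)
  expect_equal(o1, V1 %*% p$Wo + matrix(p$bo, 1, 4), tolerance = 1e-10)
  # identical tokens give identical outputs
  Xr <- matrix(rep(rnorm(4), each = 5), 5, 4)
  or <- multi_head_self_attention(Xr, p, 2)
  expect_equal(or, matrix(rep(or[1, ], each = 5), 5, 4), tolerance = 1e-10)
  expect_error(multi_head_self_attention(X, p, 3),
               class = "lesionseg_config_error")
})

test_that("transformer block is the quoted two-step pre-norm update", {
  C <- 6
  m <- tiny_model(seed = 4)
  p <- lesionseg:::tblock_params(m$params, "transformer.layer1")
  # independent step-by-step composition on a 4-token instance
  set.seed(11)
  X <- matrix(rnorm(4 * ncol(p$Wq)), 4, ncol(p$Wq))
  ln <- function(x, g, b) {
    t(apply(x, 1, function(r) (r - mean(r)) /
              sqrt(mean((r - mean(r))^2) + 1e-5))) *
      matrix(g, nrow(x), length(g), byrow = TRUE) +
      matrix(b, nrow(x), length(b), byrow = TRUE)
  }
  z1 <- X + attention_oracle(ln(X, p$ln1.gamma, p$ln1.beta), p, 2)
  u <- ln(z1, p$ln2.gamma, p$ln2.beta)
  h <- u %*% p$W1 + matrix(p$b1, 4, length(p$b1), byrow = TRUE)
  f <- (h * pnorm(h)) %*% p$W2 + matrix(p$b2, 4, length(p$b2), byrow = TRUE)
  want <- z1 + f
  expect_equal(transformer_block(X, p, 2), want, tolerance = 1e-6)
  # residual identity when output projections are zeroed
  p0 <- p; p0$Wo[] <- 0; p0$bo[] <- 0; p0$W2[] <- 0; p0$b2[] <- 0
  expect_equal(transformer_block(X, p0, 2), X)
})

test_that("bottleneck widens channels and the ablation switch bypasses it", {
  m <- tiny_model(seed = 5)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8, 1))
  out <- bottleneck_forward(m, x)
  expect_equal(dim(out), c(4, 4, 16, 1))
  # determinism in evaluation mode
  expect_identical(out, bottleneck_forward(m, x))
  # ablation: same weights, transformer off -> pure CNN path
  m2 <- m; m2$cfg$use_transformer <- FALSE
  cnn_only <- bottleneck_forward(m2, x)
  r1 <- lesionseg:::resblock_fw(x, m$params, m$buffers, "bot.block1",
                                train = FALSE, keep = FALSE)
  r2 <- lesionseg:::resblock_fw(r1$out, m$params, r1$Bf, "bot.block2",
                                train = FALSE, keep = FALSE)
  expect_identical(cnn_only, r2$out)
  expect_false(identical(out, cnn_only))
})

test_that("decoder block doubles resolution and aligns mismatched skips", {
  m <- tiny_model(seed = 6)
  x <- array(rnorm(4 * 4 * 16), c(4, 4, 16, 1))
  skip <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  out <- decoder_block_forward(m, x, skip, stage = 2)
  expect_equal(dim(out), c(8, 8, 8, 1))
  # odd-sized skip: aligned, not rejected
  skip_odd <- array(rnorm(9 * 9 * 8), c(9, 9, 8, 1))
  out_odd <- decoder_block_forward(m, x, skip_odd, stage = 2)
  expect_equal(dim(out_odd), c(9, 9, 8, 1))
})

test_that("model forward yields in-range probabilities of the input size", {
  m <- tiny_model(seed = 7)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  fw <- model_forward(m, x)
  expect_equal(dim(fw$prob), c(16, 16, 1, 2))
  expect_true(min(fw$prob) >= 0 && max(fw$prob) <= 1)
  # zero head -> every probability exactly 0.5
  m0 <- m; m0$params[["head.W"]][] <- 0; m0$params[["head.b"]][] <- 0
  expect_true(all(model_forward(m0, x)$prob == 0.5))
  expect_error(model_forward(m, array(0, c(8, 8, 3, 1))),
               class = "lesionseg_config_error")
})

test_that("binarize thresholds inclusively and is idempotent", {
  p <- array(c(0.6, 0.4, 0.5, 0, 1, 0.499), c(2, 3))
  b <- binarize(p)
  expect_equal(as.vector(b), c(1L, 0L, 1L, 0L, 1L, 0L))
  expect_equal(binarize(binarize(p)), b)
  expect_error(binarize(p, threshold = 1.5), "threshold")
})

test_that("parameter accounting splits cleanly and matches the conv formula", {
  m <- tiny_model(seed = 8)
  pc <- count_parameters(m)
  expect_identical(pc$total, pc$transformer_part + pc$cnn_part)
  # every convolution contributes conv_param_count of its spec
  conv_names <- grep("\\.(conv1|conv2|proj)\\.W$", names(m$params),
                     value = TRUE)
  for (nm in conv_names) {
    d <- dim(m$params[[nm]])
    expect_identical(length(m$params[[nm]]),
                     conv_param_count(d[3], d[4], d[1], bias = FALSE))
  }
  # output head contributes exactly Cin + 1 to the CNN part
  expect_identical(length(m$params[["head.W"]]) +
                     length(m$params[["head.b"]]),
                   conv_param_count(m$cfg$base_channels, 1, 1, bias = TRUE))
  # ablation: no transformer parameters at all
  m2 <- hybrid_unet(tiny_arch(use_transformer = FALSE), seed = 8)
  expect_identical(count_parameters(m2)$transformer_part, 0L)
  # invariant to input contents / batch size by construction: counts are
  # functions of the parameter list only
  expect_identical(count_parameters(m)$total, pc$total)
})

test_that("seeded construction and eval-mode forward are reproducible", {
  m1 <- tiny_model(seed = 42)
  m2 <- tiny_model(seed = 42)
  expect_identical(m1$params, m2$params)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  expect_identical(model_forward(m1, x)$prob, model_forward(m2, x)$prob)
})
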