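# Shared fixtures: tiny architectures and in-memory phantom sets so the
# suite never touches the network or large files.

tiny_arch <- function(...) {
  arch_config(in_channels = 3, base_channels = 4, num_stages = 2,
              transformer_layers = 1, attention_heads = 2, input_size = 16,
              ...)
}

tiny_model <- function(seed = 1L, ...) hybrid_unet(tiny_arch(...), seed = seed)

tiny_phantoms <- function(n = 4, size = 32, modality = "ultrasound",
                          seed = 5L) {
  cfg <- phantom_config(modality, image_size = size, patients = n,
                        images_per_patient = 1, seed = seed)
  lesionseg:::generate_memory_dataset(cfg)
}

# Dense brute-force attention oracle: literal softmax(QK'/sqrt(dk))V per
# head, concatenated, projected. Kept independent of the package internals.
attention_oracle <- function(X, p, heads) {
  N <- nrow(X); C <- ncol(X); dk <- C / heads
  Q <- X %*% p$Wq + matrix(p$bq, N, C, byrow = TRUE)
  K <- X %*% p$Wk + matrix(p$bk, N, C, byrow = TRUE)
  V <- X %*% p$Wv + matrix(p$bv, N, C, byrow = TRUE)
  O <- matrix(0, N, C)
  for (h in seq_len(heads)) {
    ix <- ((h - 1) * dk + 1):(h * dk)
    S <- Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE]) / sqrt(dk)
    A <- matrix(0, N, N)
    for (i in seq_len(N)) A[i, ] <- exp(S[i, ]) / sum(exp(S[i, ]))
    O[, ix] <- A %*% V[, ix, drop = FALSE]
  }
  O %*% p$Wo + matrix(p$bo, N, C, byrow = TRUE)
}

random_attn_params <- function(C, seed = 1) {
  set.seed(seed)
  list(Wq = matrix(rnorm(C * C, sd = 0.4), C, C), bq = rnorm(C, sd = 0.1),
       Wk = matrix(rnorm(C * C, sd = 0.4), C, C), bk = rnorm(C, sd = 0.1),
       Wv = matrix(rnorm(C * C, sd = 0.4), C, C), bv = rnorm(C, sd = 0.1),
       Wo = matrix(rnorm(C * C, sd = 0.4), C, C), bo = rnorm(C, sd = 0.1))
}
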