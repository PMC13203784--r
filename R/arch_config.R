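#' Architecture configuration for the hybrid U-Net
#'
#' Collects every structural hyperparameter of the hybrid residual-CNN /
#' Transformer segmentation network. The encoder has \code{num_stages}
#' stages whose channel widths start at \code{base_channels} and double per
#' stage; the bottleneck widens the top encoder channels by a factor of two
#' and (optionally) runs \code{transformer_layers} pre-norm Transformer
#' blocks over the tokenized 2-D feature map.
#'
#' Invariants enforced: \code{input_size} must be divisible by
#' \code{2^num_stages}; \code{bottleneck_channels} must equal twice the top
#' encoder width \code{base_channels * 2^(num_stages-1)} and be divisible by
#' \code{attention_heads}.
#'
#' @param in_channels number of input image channels (3 for RGB).
#' @param base_channels channel width of the first encoder stage; doubles
#'   each stage (default 32, giving 32-64-128-256).
#' @param num_stages number of encoder (and decoder) stages (default 4).
#' @param bottleneck_channels channel width of the bottleneck / token
#'   embedding dimension (default 512).
#' @param transformer_layers number of Transformer blocks in the bottleneck
#'   (default 4).
#' @param attention_heads number of self-attention heads (default 8).
#' @param mlp_ratio feed-forward hidden width as a multiple of the embedding
#'   dimension (default 4).
#' @param input_size input image side length in pixels (default 256).
#' @param use_transformer if \code{FALSE} the bottleneck is CNN-only and the
#'   model degrades to a plain residual U-Net (ablation switch).
#' @param residual_blocks_per_stage residual blocks per encoder stage
#'   (default 2).
#' @return an object of class \code{arch_config}.
#' @examples
#' cfg <- arch_config()
#' cfg$bottleneck_channels  # 512
#' @export
arch_config <- function(in_channels = 3L, base_channels = 32L, num_stages = 4L,
                        bottleneck_channels = NULL, transformer_layers = 4L,
                        attention_heads = 8L, mlp_ratio = 4.0,
                        input_size = 256L, use_transformer = TRUE,
                        residual_blocks_per_stage = 2L) {
  top <- base_channels * 2^(num_stages - 1L)
  if (is.null(bottleneck_channels)) bottleneck_channels <- 2L * top
  cfg <- list(
    in_channels = as.integer(in_channels),
    base_channels = as.integer(base_channels),
    num_stages = as.integer(num_stages),
    bottleneck_channels = as.integer(bottleneck_channels),
    transformer_layers = as.integer(transformer_layers),
    attention_heads = as.integer(attention_heads),
    mlp_ratio = as.numeric(mlp_ratio),
    input_size = as.integer(input_size),
    use_transformer = isTRUE(use_transformer),
    residual_blocks_per_stage = as.integer(residual_blocks_per_stage)
  )
  class(cfg) <- "arch_config"
  validate_arch_config(cfg)
  cfg
}

validate_arch_config <- function(cfg) {
  for (f in c("in_channels", "base_channels", "num_stages",
              "bottleneck_channels", "transformer_layers", "attention_heads",
              "input_size", "residual_blocks_per_stage")) {
    if (!is_count(cfg[[f]])) stop_config("arch_config field '", f,
                                         "' must be a positive integer")
  }
  if (cfg$mlp_ratio <= 0) stop_config("mlp_ratio must be positive")
  if (cfg$input_size %% 2^cfg$num_stages != 0)
    stop_config("input_size (", cfg$input_size,
                ") must be divisible by 2^num_stages (", 2^cfg$num_stages, ")")
  top <- cfg$base_channels * 2^(cfg$num_stages - 1L)
  if (cfg$bottleneck_channels != 2L * top)
    stop_config("bottleneck_channels (", cfg$bottleneck_channels,
                ") must equal 2 x top encoder channels (", 2L * top, ")")
  if (cfg$bottleneck_channels %% cfg$attention_heads != 0)
    stop_config("bottleneck_channels must be divisible by attention_heads")
  invisible(cfg)
}

#' @export
print.arch_config <- function(x, ...) {
  chans <- x$base_channels * 2^(seq_len(x$num_stages) - 1L)
  cat("Hybrid U-Net architecture config\n")
  cat("  input:", x$input_size, "x", x$input_size, "x", x$in_channels, "\n")
  cat("  encoder channels:", paste(chans, collapse = " -> "), "\n")
  cat("  bottleneck:", x$bottleneck_channels, "channels,",
      if (x$use_transformer)
        paste0(x$transformer_layers, " transformer layers x ",
               x$attention_heads, " heads, MLP x", x$mlp_ratio)
      else "CNN only", "\n")
  invisible(x)
}

#' Number of trainable parameters of a 2-D convolution
#'
#' \code{Cout * Cin * k^2}, plus \code{Cout} if the layer has a bias term.
#'
#' @param Cin,Cout input/output channel counts.
#' @param k square kernel size.
#' @param bias whether the layer has a per-output-channel bias.
#' @return integer parameter count.
#' @examples
#' conv_param_count(32, 1, 1, bias = TRUE)  # 33, the output head
#' @export
conv_param_count <- function(Cin, Cout, k, bias = TRUE) {
  if (!is_count(Cin) || !is_count(Cout) || !is_count(k))
    stop_config("conv spec dimensions must be positive integers")
  as.integer(Cout * Cin * k^2 + if (isTRUE(bias)) Cout else 0L)
}

#' Serialize / deserialize an architecture config
#'
#' Round-trips \code{arch_config} through a YAML file so experiment suites
#' are fully configuration-driven.
#' @param cfg an \code{arch_config}.
#' @param path file path.
#' @return \code{read_arch_config} returns an \code{arch_config}.
#' @export
write_arch_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_arch_config
#' @export
read_arch_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(arch_config, x)
}
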