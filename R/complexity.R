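# Deterministic complexity accounting: learnable parameter counts, forward
# FLOPs and checkpoint sizes for every architecture variant.
#
# FLOP convention (fixed package-wide):
#   * 2 FLOPs per multiply-accumulate;
#   * convolutions charged k^d taps per output element, plus 1 FLOP/element
#     bias;
#   * transpose convolutions charged like a mirrored convolution at output
#     resolution (k^d taps per output element), plus bias;
#   * instance normalization 4, LeakyReLU 1 and dropout 1 FLOP per element
#     of every block convolution output;
#   * max pooling 2^d - 1 comparisons per output element;
#   * upsampling 1 FLOP per output element, summation fusion 1 FLOP per
#     element and map;
#   * Fourier and data-consistency operations excluded.
# All counts are taken on the pooling-grid padded input (128x128x36 pads to
# 128x128x48 for five stages).

#' FLOPs of a single convolution under the package convention
#'
#' @param cin,cout channel counts.
#' @param shape output spatial shape (length 2 or 3).
#' @param kernel kernel side length.
#' @param pointwise additional FLOPs per output element beyond the 1-FLOP
#'   bias (0 for a bare convolution; 6 for a block convolution followed by
#'   instance normalization, LeakyReLU and dropout).
#' @return FLOP count (double).
#' @examples
#' count_conv_flops(1, 1, c(2, 2, 2), kernel = 1)  # 24
#' @export
count_conv_flops <- function(cin, cout, shape, kernel = 3, pointwise = 0) {
  v <- prod(shape)
  d <- length(shape)
  2 * kernel^d * cin * cout * v + (1 + pointwise) * cout * v
}

BLOCK_PW <- 6  # instance norm (4) + LeakyReLU (1) + dropout (1)

pad_shape <- function(shape, stages) {
  mult <- pool_multiple(stages)
  as.integer(ceiling(shape / mult) * mult)
}

level_voxels <- function(shape, stages) {
  d <- length(shape)
  prod(pad_shape(shape, stages)) / (2^d)^(seq_len(stages) - 1)
}

# forward FLOPs of one regularizer network
reg_flops <- function(config, shape, in_ch = config$in_channels,
                      interconnect = FALSE) {
  d <- length(shape)
  st <- config$stages
  ce <- enc_channels(config)
  V <- level_voxels(shape, st)
  kt <- 3^d           # convolution taps per output element
  ut <- 2^d           # transpose-convolution taps per output element
  cfl <- function(cin, cout, v, taps, pw) {
    2 * taps * cin * cout * v + (1 + pw) * cout * v
  }
  tot <- 0
  for (i in seq_len(st)) {
    cin1 <- if (i == 1L) in_ch else ce[i - 1L]
    tot <- tot + cfl(cin1, ce[i], V[i], kt, BLOCK_PW) +
                 cfl(ce[i], ce[i], V[i], kt, BLOCK_PW)
  }
  for (i in 2:st) tot <- tot + (2^d - 1) * ce[i - 1L] * V[i]   # max pooling
  if (!is_half_variant(config)) {
    for (j in seq_len(st - 1L)) {
      l <- st - j
      extra <- if (interconnect) ce[l] else 0
      tot <- tot + cfl(ce[l + 1L], ce[l], V[l], ut, 0) +       # tconv
        cfl(2 * ce[l] + extra, ce[l], V[l], kt, BLOCK_PW) +
        cfl(ce[l], ce[l], V[l], kt, BLOCK_PW)
    }
    tot <- tot + cfl(ce[1], config$in_channels, V[1], 1, 0)
  } else {
    ch <- config$base_channels
    if (config$upsampling == "trilinear") {
      tot <- tot + (st - 1) * ch * V[1]                  # upsampled maps
    } else {
      for (i in 2:st) tot <- tot + cfl(ch, ch, V[1], (2^(i - 1))^d, 0)
    }
    tot <- tot + (st - 1) * ch * V[1]                    # summation adds
    cin1 <- if (interconnect) 2 * ch else ch
    tot <- tot + cfl(cin1, ch, V[1], kt, BLOCK_PW) +
                 cfl(ch, ch, V[1], kt, BLOCK_PW) +
                 cfl(ch, config$in_channels, V[1], 1, 0)
  }
  tot
}

#' Forward-pass FLOPs of an unrolled network
#'
#' Sums the regularizer cost over all cascades under the package FLOP
#' convention (see [count_conv_flops()]); Fourier and data-consistency
#' operations are excluded. Dense variants account for the widened first
#' convolution (`2 * it` input channels at cascade `it`) and the
#' interconnection widening from cascade 2 on. A length-2 `input_shape`
#' counts the 2D analogue of the network (3x3 kernels, 2x2 pooling).
#'
#' @param config a [network_config()].
#' @param input_shape spatial shape before padding, length 3 (or 2 for the
#'   2D analogue).
#' @return total forward cost in GFLOPs (1 GFLOP = 1e9 FLOPs).
#' @examples
#' cfg <- network_config("varnet", cascades = 1)
#' count_forward_flops(cfg, c(128, 128, 36))  # one 3D U-Net: ~401 GFLOPs
#' @export
count_forward_flops <- function(config, input_shape = c(128, 128, 36)) {
  stopifnot(length(input_shape) %in% c(2L, 3L))
  dense <- is_dense_variant(config)
  tot <- 0
  for (it in seq_len(config$cascades)) {
    tot <- tot + reg_flops(config, input_shape,
                           in_ch = if (dense) 2L * it else config$in_channels,
                           interconnect = dense && it > 1L)
  }
  tot / 1e9
}

# parameters of one regularizer (3D model)
reg_params <- function(config, in_ch = config$in_channels,
                       interconnect = FALSE) {
  pconv <- function(cin, cout, k = 3) k^3 * cin * cout + cout
  st <- config$stages
  ce <- enc_channels(config)
  tot <- 0
  for (i in seq_len(st)) {
    cin1 <- if (i == 1L) in_ch else ce[i - 1L]
    tot <- tot + pconv(cin1, ce[i]) + pconv(ce[i], ce[i])
  }
  if (!is_half_variant(config)) {
    for (j in seq_len(st - 1L)) {
      l <- st - j
      extra <- if (interconnect) ce[l] else 0
      tot <- tot + (8 * ce[l + 1L] * ce[l] + ce[l]) +
        pconv(2 * ce[l] + extra, ce[l]) + pconv(ce[l], ce[l])
    }
    tot + pconv(ce[1], config$in_channels, 1)
  } else {
    ch <- config$base_channels
    if (config$upsampling == "transpose_conv")
      for (i in 2:st) tot <- tot + (2^(i - 1))^3 * ch * ch + ch
    cin1 <- if (interconnect) 2 * ch else ch
    tot + pconv(cin1, ch) + pconv(ch, ch) + pconv(ch, config$in_channels, 1)
  }
}

#' Learnable parameter count of an unrolled network
#'
#' Exact count of learnable scalars: all convolution / transpose-convolution
#' weights and biases of every cascade's regularizer plus one step-size
#' scalar `mu` per cascade. Equals the instantiated model's count from
#' [weights_parameter_count()].
#'
#' @param config a [network_config()].
#' @return parameter count (double).
#' @examples
#' count_parameters(network_config("varnet", cascades = 8))     # 180,609,816
#' count_parameters(network_config("halfvarnet", cascades = 8)) # 2,450,456
#' @export
count_parameters <- function(config) {
  dense <- is_dense_variant(config)
  tot <- config$cascades   # the mu scalars
  for (it in seq_len(config$cascades)) {
    tot <- tot + reg_params(config,
                            in_ch = if (dense) 2L * it else config$in_channels,
                            interconnect = dense && it > 1L)
  }
  tot
}

#' Checkpoint size in bytes
#'
#' 12 bytes per learnable parameter: 4-byte float32 weights plus the two
#' 4-byte Adam moment buffers stored with the optimizer state.
#'
#' @param param_count number of learnable scalars.
#' @return size in bytes.
#' @export
checkpoint_size_bytes <- function(param_count) {
  stopifnot(param_count >= 0)
  12 * param_count
}

#' Complexity audit table
#'
#' @param configs list of [network_config()] objects.
#' @param input_shape spatial shape, default `c(128, 128, 36)`.
#' @return data.frame with variant, cascades, parameters, GFLOPs and
#'   checkpoint size (MB, 1 MB = 1e6 bytes).
#' @export
complexity_audit <- function(configs, input_shape = c(128, 128, 36)) {
  if (inherits(configs, "network_config")) configs <- list(configs)
  rows <- lapply(configs, function(cfg) {
    p <- count_parameters(cfg)
    data.frame(variant = cfg$variant, cascades = cfg$cascades,
               parameters = p,
               gflops = count_forward_flops(cfg, input_shape),
               checkpoint_mb = checkpoint_size_bytes(p) / 1e6)
  })
  do.call(rbind, rows)
}
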