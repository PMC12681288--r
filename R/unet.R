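#' Unrolled network configuration
#'
#' Describes one of the four architecture variants. `varnet` / `dircn` use a
#' full 3D U-Net regularizer whose channel count doubles at every encoder
#' stage; `halfvarnet` / `halfdircn` use the Half U-Net simplification:
#' constant channel width in the encoder and a decoder reduced to upsampling
#' and summation, with learned operators only in the final stage. The `dircn`
#' variants add dense input connections (each cascade's regularizer consumes
#' the channel concatenation of all previous image iterates) and
#' interconnections between the decoders of consecutive cascades.
#'
#' Defaults follow the reference protocol: 32 base channels, five stages
#' (four max-pooling levels), dropout 0.25, trilinear upsampling.
#'
#' @param variant one of `"varnet"`, `"halfvarnet"`, `"dircn"`, `"halfdircn"`.
#' @param cascades number of unrolled iterations (>= 1).
#' @param base_channels channel width `ch` of the regularizer.
#' @param stages encoder depth (`stages - 1` poolings); >= 2.
#' @param dropout dropout rate in `[0, 1)`, active during training only.
#' @param upsampling `"trilinear"` (parameter-free) or `"transpose_conv"`
#'   (a single learned kernel-`2^(i-1)`, stride-`2^(i-1)` transpose
#'   convolution per Half U-Net stage; only meaningful for the Half variants).
#' @param in_channels input channels of the first cascade (2 = real/imag).
#' @return An object of class `network_config`.
#' @export
network_config <- function(variant = c("varnet", "halfvarnet", "dircn", "halfdircn"),
                           cascades = 8L, base_channels = 32L, stages = 5L,
                           dropout = 0.25,
                           upsampling = c("trilinear", "transpose_conv"),
                           in_channels = 2L) {
  variant <- match.arg(variant)
  upsampling <- match.arg(upsampling)
  cascades <- as.integer(cascades)
  stages <- as.integer(stages)
  base_channels <- as.integer(base_channels)
  if (cascades < 1L) stop("cascades must be >= 1", call. = FALSE)
  if (stages < 2L) stop("stages must be >= 2", call. = FALSE)
  if (base_channels < 1L) stop("base_channels must be >= 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  structure(list(variant = variant, cascades = cascades,
                 base_channels = base_channels, stages = stages,
                 dropout = dropout, upsampling = upsampling,
                 in_channels = as.integer(in_channels)),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("network_config: %s, %d cascades, ch=%d, %d stages, dropout=%g, upsampling=%s\n",
              x$variant, x$cascades, x$base_channels, x$stages, x$dropout,
              x$upsampling))
  invisible(x)
}

is_half_variant <- function(config) config$variant %in% c("halfvarnet", "halfdircn")
is_dense_variant <- function(config) config$variant %in% c("dircn", "halfdircn")

pool_multiple <- function(stages) 2L^(stages - 1L)

#' Pad a volume to the pooling grid
#'
#' Zero-pads each spatial dimension symmetrically up to the next multiple of
#' `2^(stages - 1)` so that `stages - 1` max-pooling halvings are exact
#' (e.g. 36 slices pad to 48 for five stages). The returned crop record
#' inverts the padding exactly.
#'
#' @param volume array `(C, X, Y, Z)`.
#' @param stages encoder depth.
#' @return list with `padded` (array) and `crop` (record for [crop_from_pool_grid()]).
#' @export
pad_to_pool_grid <- function(volume, stages) {
  stopifnot(length(dim(volume)) == 4L)
  sp <- dim(volume)[2:4]
  mult <- pool_multiple(stages)
  target <- as.integer(ceiling(sp / mult) * mult)
  pr <- ag_pad3(ag_const(volume), target)
  list(padded = pr$node$value, crop = pr$crop)
}

#' @rdname pad_to_pool_grid
#' @param padded padded array.
#' @param crop crop record returned by `pad_to_pool_grid`.
#' @export
crop_from_pool_grid <- function(padded, crop) {
  ag_crop3(ag_const(padded), crop)$value
}

#' Joint two-channel normalization
#'
#' Standardizes a two-channel (real/imaginary) image volume to mean 0 and
#' standard deviation 1 over both channels jointly, as applied before each
#' regularizer call. A constant volume returns unchanged with the sentinel
#' `sd = 1`.
#'
#' @param volume numeric array.
#' @return list `(normalized, mean, sd)`; `volume = normalized * sd + mean`.
#' @export
normalize_two_channel <- function(volume) {
  m <- mean(volume)
  s <- sqrt(mean((volume - m)^2))
  if (s == 0) return(list(normalized = volume, mean = 0, sd = 1))
  list(normalized = (volume - m) / s, mean = m, sd = s)
}

# ---- weight construction --------------------------------------------------

new_conv_w <- function(cin, cout, k, init = "he") {
  fan_in <- cin * k^3
  W <- if (init == "zero") matrix(0, cout, fan_in)
       else matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)
  list(W = ag_param(W), b = ag_param(numeric(cout)), k = k,
       cin = cin, cout = cout)
}

new_tconv_w <- function(cin, cout, s, init = "he") {
  # rows: cout + Cout*tap, tap-major blocks of size cout
  nr <- cout * s^3
  W <- if (init == "zero") matrix(0, nr, cin)
       else matrix(stats::rnorm(nr * cin, sd = sqrt(2 / (cin * s^3))), nr, cin)
  list(W = ag_param(W), b = ag_param(numeric(cout)), s = s,
       cin = cin, cout = cout)
}

enc_channels <- function(config) {
  ch <- config$base_channels
  if (is_half_variant(config)) rep(ch, config$stages)
  else ch * 2L^(seq_len(config$stages) - 1L)
}

#' Initialize the weights of a single regularizer network
#'
#' @param config a [network_config()].
#' @param in_channels input channel count (2, or `2 * it` for the dense
#'   variants at cascade `it`).
#' @param interconnect whether this regularizer receives decoder features
#'   from the previous cascade (DIRCN variants, cascades >= 2).
#' @param init `"he"` (Kaiming normal) or `"zero"`.
#' @return nested list of weight tensors.
#' @export
init_regularizer_weights <- function(config, in_channels = config$in_channels,
                                     interconnect = FALSE, init = "he") {
  ce <- enc_channels(config)
  st <- config$stages
  enc <- vector("list", st)
  for (i in seq_len(st)) {
    cin1 <- if (i == 1L) in_channels else ce[i - 1L]
    enc[[i]] <- list(conv1 = new_conv_w(cin1, ce[i], 3L, init),
                     conv2 = new_conv_w(ce[i], ce[i], 3L, init))
  }
  if (!is_half_variant(config)) {
    dec <- vector("list", st - 1L)
    for (j in seq_len(st - 1L)) {
      l <- st - j                      # level produced by this block
      extra <- if (interconnect) ce[l] else 0L
      dec[[j]] <- list(
        tconv = new_tconv_w(ce[l + 1L], ce[l], 2L, init),
        conv1 = new_conv_w(2L * ce[l] + extra, ce[l], 3L, init),
        conv2 = new_conv_w(ce[l], ce[l], 3L, init))
    }
    list(enc = enc, dec = dec,
         out = new_conv_w(ce[1], config$in_channels, 1L, init))
  } else {
    ch <- config$base_channels
    up <- NULL
    if (config$upsampling == "transpose_conv") {
      up <- vector("list", st)
      for (i in 2:st) up[[i]] <- new_tconv_w(ch, ch, 2L^(i - 1L), init)
    }
    cin1 <- if (interconnect) 2L * ch else ch
    list(enc = enc, up = up,
         final = list(conv1 = new_conv_w(cin1, ch, 3L, init),
                      conv2 = new_conv_w(ch, ch, 3L, init),
                      out = new_conv_w(ch, config$in_channels, 1L, init)))
  }
}

#' Initialize all weights of an unrolled network
#'
#' One regularizer per cascade plus one learned data-consistency step size
#' `mu` per cascade (initialized to 1). Dense variants widen the first
#' convolution of cascade `it` to `2 * it` input channels and add the
#' interconnection inputs from cascade 2 on.
#'
#' @param config a [network_config()].
#' @param seed optional integer seed for reproducible initialization.
#' @param init `"he"` or `"zero"`.
#' @return object of class `unrolled_weights`.
#' @export
init_unrolled_weights <- function(config, seed = NULL, init = "he") {
  build <- function() {
    cascades <- lapply(seq_len(config$cascades), function(it) {
      dense <- is_dense_variant(config)
      list(reg = init_regularizer_weights(
             config,
             in_channels = if (dense) 2L * it else config$in_channels,
             interconnect = dense && it > 1L,
             init = init),
           mu = ag_param(1.0))
    })
    structure(list(config = config, cascades = cascades),
              class = "unrolled_weights")
  }
  if (is.null(seed)) build() else with_local_seed(seed, build())
}

# flatten every parameter node in a weights structure (stable order)
collect_params <- function(x) {
  out <- list()
  walk <- function(v) {
    if (is.environment(v)) out[[length(out) + 1L]] <<- v
    else if (is.list(v)) for (e in v) if (!is.null(e)) walk(e)
  }
  walk(x)
  out
}

#' Number of learnable scalars in a weights structure
#' @param weights any nested weight structure from this package.
#' @export
weights_parameter_count <- function(weights) {
  sum(vapply(collect_params(weights), function(p) length(p$value), numeric(1)))
}

weights_values <- function(weights) {
  lapply(collect_params(weights), function(p) p$value)
}

weights_restore <- function(weights, values) {
  ps <- collect_params(weights)
  stopifnot(length(ps) == length(values))
  for (i in seq_along(ps)) ps[[i]]$value <- values[[i]]
  invisible(weights)
}

# ---- forward passes -------------------------------------------------------

conv_in_act <- function(x, cw, config, training) {
  x <- ag_conv3(x, cw$W, cw$b, cw$k)
  x <- ag_instnorm3(x)
  x <- ag_lrelu(x, 0.2)
  ag_dropout(x, config$dropout, training)
}

conv_block <- function(x, blk, config, training) {
  conv_in_act(conv_in_act(x, blk$conv1, config, training),
              blk$conv2, config, training)
}

# Full 3D U-Net. `prev_feats`: list of previous-cascade decoder outputs per
# level (DIRCN interconnections). Returns the output node and this cascade's
# decoder features.
unet_forward <- function(x, regw, config, training = FALSE, prev_feats = NULL) {
  st <- config$stages
  skips <- vector("list", st)
  for (i in seq_len(st)) {
    x <- conv_block(x, regw$enc[[i]], config, training)
    skips[[i]] <- x
    if (i < st) x <- ag_maxpool3(x)
  }
  feats <- vector("list", st - 1L)
  for (j in seq_len(st - 1L)) {
    l <- st - j
    tc <- regw$dec[[j]]$tconv
    x <- ag_tconv3(x, tc$W, tc$b, tc$cout, tc$s)
    ins <- list(skips[[l]], x)
    if (!is.null(prev_feats)) ins <- c(ins, list(prev_feats[[l]]))
    x <- ag_concat_c(ins)
    x <- conv_block(x, regw$dec[[j]], config, training)
    feats[[l]] <- x
  }
  out <- ag_conv3(x, regw$out$W, regw$out$b, 1L)
  list(out = out, feats = feats)
}

# Half U-Net: constant-width encoder; decoder = upsample every encoder output
# to full resolution, sum, then one learned block. `prev_sum`: previous
# cascade's post-sum map (HalfDIRCN interconnection).
half_unet_forward <- function(x, regw, config, training = FALSE, prev_sum = NULL) {
  st <- config$stages
  ups <- vector("list", st)
  for (i in seq_len(st)) {
    x <- conv_block(x, regw$enc[[i]], config, training)
    ups[[i]] <- if (i == 1L) x
                else if (config$upsampling == "trilinear")
                  ag_upsample3(x, rep(2L^(i - 1L), 3L))
                else {
                  tc <- regw$up[[i]]
                  ag_tconv3(x, tc$W, tc$b, tc$cout, tc$s)
                }
    if (i < st) x <- ag_maxpool3(x)
  }
  s <- ag_add_list(ups)
  fin_in <- if (!is.null(prev_sum)) ag_concat_c(list(s, prev_sum)) else s
  y <- conv_block(fin_in, regw$final, config, training)
  out <- ag_conv3(y, regw$final$out$W, regw$final$out$b, 1L)
  list(out = out, sum_map = s)
}

check_pool_grid <- function(image, stages) {
  if (length(dim(image)) != 4L)
    stop("expected a (channels, X, Y, Z) array", call. = FALSE)
  sp <- dim(image)[2:4]
  mult <- pool_multiple(stages)
  if (any(sp %% mult != 0L))
    stop("spatial dims ", paste(sp, collapse = "x"),
         " are not multiples of the pooling grid ", mult,
         "; use pad_to_pool_grid()", call. = FALSE)
  invisible(TRUE)
}

#' Apply a 3D U-Net regularizer
#'
#' Encoder of `stages` levels (two 3x3x3 convolutions with instance
#' normalization, LeakyReLU slope 0.2 and dropout after each; channels double
#' per level; 2x2x2 max pooling between levels) and a mirrored decoder with
#' kernel-2 stride-2 transpose convolutions, skip concatenations and a final
#' 1x1x1 convolution back to `in_channels`.
#'
#' @param image array `(C, X, Y, Z)` padded to the pooling grid.
#' @param config a [network_config()].
#' @param weights a regularizer weight set from [init_regularizer_weights()].
#' @param training enable dropout.
#' @return array of the same shape with `in_channels` channels.
#' @export
unet3d_apply <- function(image, config, weights, training = FALSE) {
  check_pool_grid(image, config$stages)
  unet_forward(ag_const(image), weights, config, training)$out$value
}

#' Apply a 3D Half U-Net regularizer
#'
#' Constant-width encoder; each encoder stage's output is upsampled to full
#' resolution (trilinearly by default), the maps are summed, and a single
#' learned block (two 3x3x3 convolutions plus a 1x1x1 output convolution)
#' produces the result. All other decoder operators are removed.
#'
#' @inheritParams unet3d_apply
#' @export
half_unet3d_apply <- function(image, config, weights, training = FALSE) {
  check_pool_grid(image, config$stages)
  half_unet_forward(ag_const(image), weights, config, training)$out$value
}
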