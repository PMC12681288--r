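# Unrolled cascade assembly. Each cascade it computes
#   k_{it+1} = k_it - mu_it * D (k_it - k_us) + F Reg(F^H k_it)
# with the regularizer wrapped in two-channel conversion, joint
# normalization (inverted on the output) and pooling-grid padding.
# Dense variants feed the concatenation of all previous image iterates to
# the regularizer, add an identity residual from the current image to the
# regularizer output, and interconnect consecutive decoders.

# Normalization + padding wrapper around one regularizer call. The input is
# standardized jointly over its channels; the output is rescaled by the same
# SD but the mean is NOT re-added: the regularizer predicts an update term,
# and re-injecting the input mean would place a spurious impulse on the
# (always sampled) DC bin, violating exact data consistency for a
# zero-weight regularizer.
reg_wrap <- function(img_node, regw, config, training, prev = NULL) {
  v <- img_node$value
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) { m <- 0; s <- 1 }
  xn <- ag_affine(img_node, 1 / s, -m / s)
  sp <- dim(v)[2:4]
  mult <- pool_multiple(config$stages)
  target <- as.integer(ceiling(sp / mult) * mult)
  pr <- ag_pad3(xn, target)
  res <- if (is_half_variant(config))
    half_unet_forward(pr$node, regw, config, training, prev_sum = prev)
  else
    unet_forward(pr$node, regw, config, training, prev_feats = prev)
  out <- ag_affine(ag_crop3(res$out, pr$crop), s, 0)
  feats <- if (is_half_variant(config)) res$sum_map else res$feats
  list(out = out, feats = feats)
}

# full unrolled forward pass on autograd nodes
unrolled_forward <- function(k_us, mask, config, weights, training = FALSE) {
  if (!inherits(weights, "unrolled_weights"))
    stop("weights must come from init_unrolled_weights()", call. = FALSE)
  k_us <- apply_mask_zero_fill(k_us, mask)    # zero-filled initial guess
  kus_node <- ag_const(k_us)
  k <- kus_node
  dense <- is_dense_variant(config)
  history <- vector("list", config$cascades)
  prev <- NULL
  for (it in seq_len(config$cascades)) {
    cas <- weights$cascades[[it]]
    img <- ag_c2ch(ag_ifft3c(k))
    history[[it]] <- img
    reg_in <- if (dense) ag_concat_c(history[seq_len(it)]) else img
    rr <- reg_wrap(reg_in, cas$reg, config, training,
                   prev = if (dense && it > 1L) prev else NULL)
    # The dense variants' identity residual (input image to regularizer
    # output) is realized by the additive pass-through of k_it:
    # k - mu D(k - k_us) + F net == F(F^H k + net) - mu D(k - k_us).
    dc <- ag_cscale_param(ag_mask3(ag_csub(k, kus_node), mask), cas$mu)
    model_k <- ag_fft3c(ag_ch2c(rr$out))
    k <- ag_cadd(ag_csub(k, dc), model_k)
    prev <- rr$feats
  }
  list(k = k, image = ag_c2ch(ag_ifft3c(k)), history = history)
}

finish_apply <- function(res, return_trace) {
  img <- res$image$value
  attr(img, "kspace") <- res$k$value
  if (return_trace)
    attr(img, "image_history") <- lapply(res$history, function(n) n$value)
  img
}

#' Reconstruct with a (Half)VarNet cascade
#'
#' Runs `cascades` unrolled iterations starting from the zero-filled
#' undersampled k-space. Each cascade subtracts the data-consistency residual
#' `mu_it * D (k_it - k_us)` and adds the Fourier transform of the
#' regularizer output (a 3D U-Net for `varnet`, a 3D Half U-Net for
#' `halfvarnet`). Returns the two-channel image `F^H k_final`; the final
#' k-space estimate is attached as attribute `"kspace"`.
#'
#' @param k_us complex 3D undersampled k-space `(kx, ky, kz)`.
#' @param mask sampling mask (plane `(ky, kz)`).
#' @param config a [network_config()] with variant `varnet` or `halfvarnet`.
#' @param weights from [init_unrolled_weights()].
#' @param training enable dropout.
#' @param return_trace attach the per-cascade image history.
#' @return array `(2, kx, ky, kz)`.
#' @export
varnet_apply <- function(k_us, mask, config, weights, training = FALSE,
                         return_trace = FALSE) {
  if (!config$variant %in% c("varnet", "halfvarnet"))
    stop("varnet_apply() handles variants varnet/halfvarnet; got ",
         config$variant, call. = FALSE)
  finish_apply(unrolled_forward(k_us, mask, config, weights, training),
               return_trace)
}

#' Reconstruct with a (Half)DIRCN cascade
#'
#' As [varnet_apply()], plus dense input connections (the regularizer of
#' cascade `it` consumes all previous image iterates, `2 * it` channels), an
#' identity residual from the current image to the regularizer output, and
#' decoder interconnections between consecutive cascades (same-resolution
#' decoder features for `dircn`; the pre-final-block summed map for
#' `halfdircn`).
#'
#' @inheritParams varnet_apply
#' @param config a [network_config()] with variant `dircn` or `halfdircn`.
#' @export
dircn_apply <- function(k_us, mask, config, weights, training = FALSE,
                        return_trace = FALSE) {
  if (!is_dense_variant(config))
    stop("dircn_apply() handles variants dircn/halfdircn; got ",
         config$variant, call. = FALSE)
  finish_apply(unrolled_forward(k_us, mask, config, weights, training),
               return_trace)
}

#' Reconstruct a volume with any variant
#'
#' Dispatches to [varnet_apply()] or [dircn_apply()]; `weights = NULL` gives
#' the zero-filled baseline `F^H k_us`.
#'
#' @inheritParams varnet_apply
#' @param weights unrolled weights, a checkpoint from [train_unrolled()]
#'   history, or `NULL` for the zero-filled baseline.
#' @export
reconstruct_volume <- function(k_us, mask, config = NULL, weights = NULL) {
  if (is.null(weights)) {
    img <- ifft3c(apply_mask_zero_fill(k_us, mask))
    out <- array(0, c(2L, dim(img)))
    out[1, , , ] <- Re(img)
    out[2, , , ] <- Im(img)
    return(out)
  }
  if (inherits(weights, "unrolled_checkpoint")) {
    config <- weights$config
    weights <- checkpoint_weights(weights)
  }
  if (is.null(config)) config <- weights$config
  if (is_dense_variant(config)) dircn_apply(k_us, mask, config, weights)
  else varnet_apply(k_us, mask, config, weights)
}
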