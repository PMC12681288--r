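#' Training configuration
#'
#' Defaults follow the reference recipe: Adam with learning rate 0.001,
#' batch size 4 (gradient accumulation over samples), at most 500 epochs,
#' model selection by lowest validation loss.
#'
#' @param lr Adam learning rate.
#' @param batch_size samples per optimizer step.
#' @param max_epochs maximum training epochs.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @param accel nominal acceleration factor of the dataset (metadata).
#' @param store_checkpoints `"all"` or `"improved"` (validation-loss
#'   improvements only; the selected best is always retained).
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, batch_size = 4L, max_epochs = 500L,
                         seed = 1L, accel = 4,
                         store_checkpoints = c("all", "improved")) {
  store_checkpoints <- match.arg(store_checkpoints)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 accel = accel, store_checkpoints = store_checkpoints),
            class = "train_config")
}

#' Image-domain MSE loss
#'
#' Mean squared difference between the two-channel (real/imaginary)
#' representation of `ifft3c(pred_k)` and of the fully sampled reference
#' image: the per-voxel mean over `2 N` real numbers.
#'
#' @param pred_k predicted complex k-space volume.
#' @param ref_image fully sampled complex reference image.
#' @return scalar loss.
#' @export
image_domain_mse_loss <- function(pred_k, ref_image) {
  if (!all(dim(pred_k) == dim(ref_image)))
    stop("shape mismatch between prediction and reference", call. = FALSE)
  delta <- ifft3c(pred_k) - ref_image
  sum(Re(delta)^2 + Im(delta)^2) / (2 * length(delta))
}

#' Split acquisitions between datasets without echo leakage
#'
#' All echoes of one acquisition belong to the same split, and the splits
#' partition the acquisitions.
#'
#' @param n_volumes number of acquisitions.
#' @param fractions length-3 vector (train, validation, test) summing to 1.
#' @param seed integer seed.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_by_acquisition <- function(n_volumes, fractions = c(0.7, 0.15, 0.15),
                                 seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  perm <- with_local_seed(seed, sample.int(n_volumes))
  n_train <- round(fractions[1] * n_volumes)
  n_val <- round(fractions[2] * n_volumes)
  rest <- setdiff(seq_len(n_volumes), perm[seq_len(n_train + n_val)])
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(rest))
}

#' Build a reconstruction dataset from phantom echo stacks
#'
#' Each selected echo of each acquisition becomes an independent training
#' sample (undersampled k-space plus fully sampled reference image); one
#' sampling mask is shared by all echoes of all acquisitions at a given
#' acceleration.
#'
#' @param stacks list of [echo_stack()] objects (one per acquisition).
#' @param mask a sampling mask.
#' @param echoes which echoes to include, default `1:3` (the ones used for
#'   fat-fraction mapping).
#' @return object of class `recon_dataset`: list with `samples` (each having
#'   `k_us`, `ref_image`, `vol_id`, `echo`) and `mask`.
#' @export
dataset_from_phantoms <- function(stacks, mask, echoes = 1:3) {
  samples <- list()
  for (v in seq_along(stacks)) {
    st <- stacks[[v]]
    for (e in echoes) {
      k <- fft3c(st$echoes[[e]])
      samples[[length(samples) + 1L]] <-
        list(k_us = apply_mask_zero_fill(k, mask),
             ref_image = st$echoes[[e]], vol_id = v, echo = e)
    }
  }
  structure(list(samples = samples, mask = mask), class = "recon_dataset")
}

# ---- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L)
}

adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, grad_scale = 1) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- if (is.null(p$grad)) p$value * 0 else p$grad * grad_scale
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    p$value <- p$value - lr * (state$m[[i]] / bc1) /
      (sqrt(state$v[[i]] / bc2) + eps)
  }
  state
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# forward + loss on one sample; returns the loss node (recording must be on
# for gradients)
sample_loss_node <- function(sample, mask, config, weights, training) {
  res <- unrolled_forward(sample$k_us, mask, config, weights, training)
  ag_mse_cplx(res$k, fft3c(sample$ref_image))
}

eval_dataset_loss <- function(dataset, config, weights) {
  mean(vapply(dataset$samples, function(s) {
    sample_loss_node(s, dataset$mask, config, weights, training = FALSE)$value
  }, numeric(1)))
}

make_checkpoint <- function(weights, opt_state, epoch, val_loss) {
  structure(list(config = weights$config, epoch = epoch, val_loss = val_loss,
                 values = weights_values(weights),
                 optimizer = list(m = opt_state$m, v = opt_state$v,
                                  t = opt_state$t)),
            class = "unrolled_checkpoint")
}

#' Rebuild a weights object from a checkpoint
#' @param ckpt an `unrolled_checkpoint`.
#' @export
checkpoint_weights <- function(ckpt) {
  w <- init_unrolled_weights(ckpt$config, init = "zero")
  weights_restore(w, ckpt$values)
  w
}

#' Save / load a checkpoint
#'
#' Single-file container with the per-cascade parameter values, the
#' configuration echo and the Adam optimizer state.
#'
#' @param ckpt an `unrolled_checkpoint`.
#' @param path file path.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "unrolled_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "unrolled_checkpoint"))
    stop("not a checkpoint file: ", path, call. = FALSE)
  ckpt
}

#' Train an unrolled network
#'
#' Adam updates of all cascade weights and step-size scalars against the
#' image-domain MSE loss, with per-epoch training and validation losses and
#' stored checkpoints. Deterministic for a fixed `train_config$seed`.
#'
#' @param net_config a [network_config()].
#' @param tr_config a [train_config()].
#' @param train_set,val_set [dataset_from_phantoms()] objects.
#' @param verbose print per-epoch losses.
#' @return object of class `train_history`: `epochs` data.frame
#'   (epoch, train_loss, val_loss), `checkpoints` (list indexed by epoch
#'   label), plus the config echoes.
#' @export
train_unrolled <- function(net_config, tr_config, train_set, val_set,
                           verbose = FALSE) {
  if (length(train_set$samples) == 0L) stop("empty training set", call. = FALSE)
  if (length(val_set$samples) == 0L) stop("empty validation set", call. = FALSE)
  with_local_seed(tr_config$seed, {
    weights <- init_unrolled_weights(net_config)
    params <- collect_params(weights)
    opt <- adam_init(params)
    ns <- length(train_set$samples)
    bs <- min(tr_config$batch_size, ns)
    epochs <- data.frame(epoch = integer(), train_loss = numeric(),
                         val_loss = numeric())
    checkpoints <- list()
    best_val <- Inf
    for (ep in seq_len(tr_config$max_epochs)) {
      ord <- sample.int(ns)
      ep_loss <- 0
      nb <- 0L
      i <- 1L
      while (i <= ns) {
        batch <- ord[i:min(i + bs - 1L, ns)]
        zero_grads(params)
        bl <- 0
        for (si in batch) {
          ag_tape_start()
          ln <- sample_loss_node(train_set$samples[[si]], train_set$mask,
                                 net_config, weights, training = TRUE)
          ag_backward(ln)
          ag_tape_stop()
          bl <- bl + ln$value
        }
        if (!is.finite(bl))
          stop("NaN/Inf training loss at epoch ", ep,
               "; try a lower learning rate", call. = FALSE)
        opt <- adam_step(params, opt, tr_config$lr,
                         grad_scale = 1 / length(batch))
        ep_loss <- ep_loss + bl / length(batch)
        nb <- nb + 1L
        i <- i + bs
      }
      val_loss <- eval_dataset_loss(val_set, net_config, weights)
      epochs <- rbind(epochs, data.frame(epoch = ep,
                                         train_loss = ep_loss / nb,
                                         val_loss = val_loss))
      keep <- tr_config$store_checkpoints == "all" || val_loss < best_val
      if (val_loss < best_val) best_val <- val_loss
      if (keep)
        checkpoints[[as.character(ep)]] <-
          make_checkpoint(weights, opt, ep, val_loss)
      if (verbose)
        message(sprintf("epoch %3d  train %.3e  val %.3e", ep,
                        ep_loss / nb, val_loss))
    }
    structure(list(epochs = epochs, checkpoints = checkpoints,
                   net_config = net_config, train_config = tr_config,
                   final_weights = weights),
              class = "train_history")
  })
}

#' Select the checkpoint with the lowest validation loss
#'
#' Ties resolve to the earliest epoch.
#'
#' @param history a `train_history` from [train_unrolled()], or anything with
#'   `epochs$val_loss` and a `checkpoints` list.
#' @return an `unrolled_checkpoint`.
#' @export
select_best_checkpoint <- function(history) {
  v <- history$epochs$val_loss
  if (length(v) == 0L) stop("empty history", call. = FALSE)
  best <- history$epochs$epoch[which.min(v)]
  ck <- history$checkpoints[[as.character(best)]]
  if (is.null(ck)) stop("checkpoint for epoch ", best, " was not stored",
                        call. = FALSE)
  ck
}

#' Evaluate reconstruction quality on a test set
#'
#' Reconstructs the first three echoes of every test acquisition, computes
#' reference and reconstructed fat-fraction maps (three-point Dixon),
#' removes the image background (Otsu mask from the fully sampled first
#' echo), and reports per-volume MSE / SSIM / PSNR on the FF maps plus
#' per-muscle FF errors and a Bland-Altman summary. Aggregates are
#' mean +/- standard error over test volumes.
#'
#' @param checkpoint an `unrolled_checkpoint`, an `unrolled_weights` object,
#'   or `NULL` for the zero-filled baseline.
#' @param test_stacks list of fully sampled [echo_stack()]s.
#' @param mask sampling mask used for retrospective undersampling.
#' @param rois optional list of [roi_label_map()]s (one per volume).
#' @return list with `per_volume` (data.frame), `per_muscle` (data.frame or
#'   `NULL`), `summary` (mean/se per metric), `bland_altman`.
#' @export
evaluate_reconstruction <- function(checkpoint, test_stacks, mask,
                                    rois = NULL) {
  weights <- NULL
  config <- NULL
  if (inherits(checkpoint, "unrolled_checkpoint")) {
    config <- checkpoint$config
    weights <- checkpoint_weights(checkpoint)
  } else if (inherits(checkpoint, "unrolled_weights")) {
    weights <- checkpoint
    config <- weights$config
  } else if (!is.null(checkpoint)) {
    stop("checkpoint must be a checkpoint, weights or NULL", call. = FALSE)
  }
  per_volume <- NULL
  per_muscle <- NULL
  for (v in seq_along(test_stacks)) {
    st <- test_stacks[[v]]
    if (length(st$echoes) < 3L) stop("test volume ", v, " has fewer than 3 echoes",
                                     call. = FALSE)
    te3 <- st$TE_list[1:3]
    fg <- background_mask(Mod(st$echoes[[1]]))
    rec <- lapply(1:3, function(e) {
      k_us <- apply_mask_zero_fill(fft3c(st$echoes[[e]]), mask)
      img2 <- reconstruct_volume(k_us, mask, config, weights)
      cx <- img2[1, , , ] + 1i * img2[2, , , ]
      dim(cx) <- dim(st$echoes[[e]])
      cx
    })
    ff_ref <- three_point_dixon(echo_stack(st$echoes[1:3], te3), foreground = fg)
    ff_rec <- three_point_dixon(echo_stack(rec, te3), foreground = fg)
    win <- min(7L, min(dim(fg)))
    if (win %% 2L == 0L) win <- win - 1L
    per_volume <- rbind(per_volume, data.frame(
      volume = v,
      mse = mse_metric(ff_ref, ff_rec),
      ssim = ssim_metric(ff_ref, ff_rec, window = win),
      psnr = psnr_metric(ff_ref, ff_rec)))
    if (!is.null(rois)) {
      lm <- rois[[v]]
      for (lab in seq_along(lm$label_names)) {
        if (!any(lm$labels == lab)) next
        m_ref <- roi_mean_ff(ff_ref, lm, lab)
        m_rec <- roi_mean_ff(ff_rec, lm, lab)
        per_muscle <- rbind(per_muscle, data.frame(
          volume = v, label = lab, muscle = lm$label_names[lab],
          ff_ref = m_ref, ff_rec = m_rec,
          ff_quadratic = ff_quadratic_error(m_ref, m_rec),
          ff_abs = ff_abs_difference(m_ref, m_rec)))
      }
    }
  }
  summary <- list(mse = aggregate_mean_se(per_volume$mse),
                  ssim = aggregate_mean_se(per_volume$ssim),
                  psnr = aggregate_mean_se(per_volume$psnr))
  ba <- NULL
  if (!is.null(per_muscle)) {
    summary$ff_quadratic <- aggregate_mean_se(per_muscle$ff_quadratic)
    summary$ff_abs <- aggregate_mean_se(per_muscle$ff_abs)
    if (nrow(per_muscle) >= 2)
      ba <- bland_altman(per_muscle$ff_ref, per_muscle$ff_rec)
  }
  list(per_volume = per_volume, per_muscle = per_muscle,
       summary = summary, bland_altman = ba)
}
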