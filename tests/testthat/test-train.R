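mini_world <- function(n_vol = 2, seed0 = 30, echoes = 1) {
  acq <- acquisition_spec(matrix = c(16, 16, 4))
  stacks <- lapply(seq_len(n_vol), function(s) {
    spec <- phantom_spec(matrix = c(16, 16, 4), n_muscles = 4,
                         ff_assignments = c(5, 10, 30, 60), seed = seed0 + s)
    ph <- make_thigh_phantom(spec)
    simulate_dixon_echoes(ph$water, ph$fat, spec = spec, acq = acq)
  })
  mask <- generate_vd_poisson_mask(16, 4, 2, center_fraction = 0.1, seed = 1)
  list(stacks = stacks, mask = mask,
       ds = dataset_from_phantoms(stacks, mask, echoes = echoes))
}

test_that("image_domain_mse_loss follows its closed forms", {
  ref <- rand_cvol(c(8, 8, 4), seed = 31)
  expect_equal(image_domain_mse_loss(fft3c(ref), ref), 0, tolerance = 1e-25)
  # constant offset delta on both channels -> delta^2
  delta <- 0.3
  shifted <- ref + complex(real = delta, imaginary = delta)
  expect_equal(image_domain_mse_loss(fft3c(shifted), ref), delta^2,
               tolerance = 1e-12)
  # brute-force elementwise oracle
  pk <- rand_cvol(c(8, 8, 4), seed = 32)
  img <- ifft3c(pk)
  acc <- 0
  for (i in seq_along(img))
    acc <- acc + (Re(img[i]) - Re(ref[i]))^2 + (Im(img[i]) - Im(ref[i]))^2
  expect_equal(image_domain_mse_loss(pk, ref), acc / (2 * length(img)),
               tolerance = 1e-12)
  expect_error(image_domain_mse_loss(pk, rand_cvol(c(4, 4, 4))), "mismatch")
})

test_that("echo splitting keeps acquisitions intact across datasets", {
  sp <- split_by_acquisition(20, c(0.7, 0.15, 0.15), seed = 2)
  all_idx <- c(sp$train, sp$val, sp$test)
  expect_setequal(all_idx, 1:20)
  expect_equal(length(all_idx), 20)          # no volume in two splits
  w <- mini_world(n_vol = 2, echoes = 1:3)
  vols <- vapply(w$ds$samples, `[[`, numeric(1), "vol_id")
  echos <- vapply(w$ds$samples, `[[`, numeric(1), "echo")
  expect_equal(sort(unique(vols)), 1:2)
  expect_equal(sum(vols == 1), 3)
  expect_equal(sort(echos[vols == 1]), 1:3)
})

test_that("training is deterministic, zero-lr is frozen, and NaN aborts", {
  w <- mini_world()
  cfg <- tiny_config("halfvarnet", cascades = 1, ch = 2, stages = 2)
  tc0 <- train_config(lr = 0, batch_size = 2, max_epochs = 3, seed = 7)
  h0 <- train_unrolled(cfg, tc0, w$ds, w$ds)
  expect_equal(diff(range(h0$epochs$train_loss)), 0, tolerance = 1e-14)
  expect_equal(diff(range(h0$epochs$val_loss)), 0, tolerance = 1e-14)
  tc <- train_config(lr = 1e-3, batch_size = 2, max_epochs = 2, seed = 7)
  h1 <- train_unrolled(cfg, tc, w$ds, w$ds)
  h2 <- train_unrolled(cfg, tc, w$ds, w$ds)
  expect_identical(h1$epochs$train_loss[1], h2$epochs$train_loss[1])
  expect_identical(h1$epochs$val_loss, h2$epochs$val_loss)
  expect_error(train_unrolled(cfg, tc, list(samples = list(), mask = w$mask),
                              w$ds), "empty")
  # non-finite data abort with a diagnostic (input validation or NaN loss)
  bad <- w$ds
  bad$samples[[1]]$ref_image[1] <- NaN
  expect_error(suppressWarnings(train_unrolled(cfg, tc, bad, w$ds)),
               "loss|non-finite")
})

test_that("select_best_checkpoint takes the earliest minimum", {
  fake <- list(epochs = data.frame(epoch = 1:3, val_loss = c(3, 1, 2)),
               checkpoints = list(`1` = structure(list(epoch = 1),
                                                  class = "unrolled_checkpoint"),
                                  `2` = structure(list(epoch = 2),
                                                  class = "unrolled_checkpoint"),
                                  `3` = structure(list(epoch = 3),
                                                  class = "unrolled_checkpoint")))
  expect_equal(select_best_checkpoint(fake)$epoch, 2)
  fake$epochs$val_loss <- c(2, 1, 1)
  expect_equal(select_best_checkpoint(fake)$epoch, 2)  # tie -> earliest
  fake$epochs$val_loss <- c(3, 2, 1)
  expect_equal(select_best_checkpoint(fake)$epoch, 3)  # monotone -> last
  expect_error(select_best_checkpoint(list(epochs = data.frame(
    epoch = integer(), val_loss = numeric()), checkpoints = list())), "empty")
})

test_that("checkpoints round-trip through files and rebuild the same model", {
  w <- mini_world()
  cfg <- tiny_config("halfvarnet", cascades = 1, ch = 2, stages = 2)
  tc <- train_config(lr = 1e-3, batch_size = 2, max_epochs = 2, seed = 7)
  h <- train_unrolled(cfg, tc, w$ds, w$ds)
  ck <- select_best_checkpoint(h)
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  save_checkpoint(ck, tmp)
  ck2 <- load_checkpoint(tmp)
  k_us <- w$ds$samples[[1]]$k_us
  a <- reconstruct_volume(k_us, w$mask, weights = ck)
  b <- reconstruct_volume(k_us, w$mask, weights = ck2)
  expect_identical(a, b)
})

test_that("evaluation with a zero-weight model at R=1 is an identity pipeline", {
  w <- mini_world(n_vol = 1, echoes = 1:3)
  full <- generate_vd_poisson_mask(16, 4, 1, seed = 0)
  cfg <- tiny_config("halfvarnet", cascades = 1, ch = 2, stages = 2)
  w0 <- init_unrolled_weights(cfg, init = "zero")
  ev <- evaluate_reconstruction(w0, w$stacks[1], full)
  # identity up to float round-off through the FFT/normalization round trips
  expect_lt(ev$per_volume$mse, 1e-20)
  expect_equal(ev$per_volume$ssim, 1, tolerance = 1e-12)
  expect_gt(ev$per_volume$psnr, 200)
})

test_that("report aggregation matches hand-computed mean and standard error", {
  vals <- c(1, 3, 5, 7, 9)
  agg <- aggregate_mean_se(vals)
  expect_equal(unname(agg["mean"]), 5)
  expect_equal(unname(agg["se"]), sd(vals) / sqrt(5))
})
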