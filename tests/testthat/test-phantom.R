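test_that("phantom truth matches the spec by construction", {
  spec <- phantom_spec(matrix = c(32, 32, 8), seed = 3)
  ph <- make_thigh_phantom(spec)
  labs <- ph$labels$labels
  for (m in seq_len(spec$n_muscles)) {
    sel <- labs == m
    expect_true(any(sel))
    expect_equal(unique(ph$ff_truth$values[sel]), spec$ff_assignments[m],
                 tolerance = 1e-12)
  }
  # labels partition the muscle region: muscle voxels have W+F = 1
  musc <- labs > 0
  expect_true(all(abs((ph$water + ph$fat)[musc] - 1) < 1e-12))
  # labeled voxels never overlap the fat ring or the background
  expect_true(all(ph$ff_truth$foreground[musc]))
  ring <- ph$support & labs == 0
  expect_true(any(ring))       # subcutaneous fat and bone-free border exist
  # default FF distribution emulates the clinical cohort
  expect_equal(stats::median(spec$ff_assignments), 8.9, tolerance = 0.2)
  expect_true(min(spec$ff_assignments) >= 4 && max(spec$ff_assignments) <= 83.5)
})

test_that("phantom geometry is seed-sensitive but structurally stable", {
  a <- make_thigh_phantom(phantom_spec(matrix = c(32, 32, 8), seed = 1))
  b <- make_thigh_phantom(phantom_spec(matrix = c(32, 32, 8), seed = 2))
  expect_false(identical(a$labels$labels, b$labels$labels))
  expect_equal(max(a$labels$labels), max(b$labels$labels))
  a2 <- make_thigh_phantom(phantom_spec(matrix = c(32, 32, 8), seed = 1))
  expect_identical(a$labels$labels, a2$labels$labels)
  expect_error(phantom_spec(n_muscles = 30), "capacity")
})

test_that("simulated echoes follow the phasor closed form", {
  spec <- phantom_spec(matrix = c(16, 16, 4), noise_sd = 0, b0_amplitude = 0,
                       seed = 5)
  ph <- make_thigh_phantom(spec)
  acq <- acquisition_spec(matrix = c(16, 16, 4))
  st <- simulate_dixon_echoes(ph$water, ph$fat, spec = spec, acq = acq)
  expect_length(st$echoes, 8)
  expect_equal(st$TE_list, seq(2.38, by = 2.38, length.out = 8))
  w <- ph$water
  f <- ph$fat
  # in-phase echoes (even): |S| = W + F ; out-of-phase (odd): |W - F|
  for (n in c(2, 4, 6, 8))
    expect_equal(Mod(st$echoes[[n]]), w + f, tolerance = 1e-9)
  for (n in c(1, 3, 5, 7))
    expect_equal(Mod(st$echoes[[n]]), abs(w - f), tolerance = 1e-9)
  # fat = 0: all magnitudes equal W
  st2 <- simulate_dixon_echoes(w, w * 0, spec = spec, acq = acq)
  for (n in 1:8) expect_equal(Mod(st2$echoes[[n]]), w, tolerance = 1e-9)
  # TE grid that breaks the in/out pattern is rejected
  bad <- acquisition_spec(TE_list = c(1.19, 3.57, 5.95), matrix = c(16, 16, 4))
  expect_error(simulate_dixon_echoes(w, f, spec = spec, acq = bad), "TE grid")
})

test_that("pipeline consistency: truth -> echoes -> fft -> dixon recovers truth", {
  d <- desk_phantom(noise_sd = 0, b0 = 50, seed = 1)
  # through k-space at R=1
  full <- generate_vd_poisson_mask(32, 8, 1, seed = 0)
  echoes_rt <- lapply(d$stack$echoes[1:3], function(e)
    ifft3c(apply_mask_zero_fill(fft3c(e), full)))
  ff <- three_point_dixon(echo_stack(echoes_rt, d$stack$TE_list[1:3]),
                          foreground = d$ph$support)
  expect_lt(max(abs(ff$values[d$ph$support] -
                      d$ph$ff_truth$values[d$ph$support])), 1e-6)
})

test_that("undersampling degrades zero-filled FF fidelity monotonically", {
  for (s in 1:5) {
    d <- desk_phantom(noise_sd = 0, b0 = 50, seed = s)
    fg <- d$ph$support
    truth <- ff_map(d$ph$ff_truth$values, fg)
    msev <- sapply(c(1, 4, 8), function(R) {
      m <- generate_vd_poisson_mask(32, 8, R, seed = s)
      echoes <- lapply(d$stack$echoes[1:3], function(e)
        ifft3c(apply_mask_zero_fill(fft3c(e), m)))
      ff <- three_point_dixon(echo_stack(echoes, d$stack$TE_list[1:3]),
                              foreground = fg)
      mse_metric(truth, ff)
    })
    expect_lt(msev[1], 1e-10)
    expect_gt(msev[2], msev[1])
    expect_gt(msev[3], msev[2])
  }
})

test_that("FF error grows monotonically with the noise level at R=1", {
  rmse <- sapply(c(0, 0.02, 0.08), function(sg) {
    spec <- phantom_spec(matrix = c(32, 32, 8), noise_sd = sg, seed = 11)
    ph <- make_thigh_phantom(spec)
    st <- simulate_dixon_echoes(ph$water, ph$fat, spec = spec,
                                acq = acquisition_spec(matrix = c(32, 32, 8)))
    ff <- three_point_dixon(echo_stack(st$echoes[1:3], st$TE_list[1:3]),
                            foreground = ph$support)
    sqrt(mean((ff$values[ph$support] - ph$ff_truth$values[ph$support])^2))
  })
  expect_true(all(diff(rmse) > 0))
})
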