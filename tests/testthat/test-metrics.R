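mk_ff <- function(vals, fg = NULL) ff_map(vals, fg)

test_that("mse/psnr follow the closed forms on the foreground", {
  v <- array(0, c(4, 4, 2))
  fg <- array(FALSE, c(4, 4, 2))
  fg[1:2, 1, 1] <- TRUE
  a <- v; a[1, 1, 1] <- 5; a[2, 1, 1] <- 5
  b <- v; b[1, 1, 1] <- 6; b[2, 1, 1] <- 8
  expect_equal(mse_metric(mk_ff(a, fg), mk_ff(b, fg)), 5)  # (1+9)/2
  expect_equal(mse_metric(mk_ff(a, fg), mk_ff(a, fg)), 0)
  expect_identical(psnr_metric(mk_ff(a, fg), mk_ff(a, fg)), Inf)
  # PSNR closed form at Table-1 scale: MSE 6.68e-2 on percent scale -> 51.75
  expect_equal(10 * log10(100^2 / 6.68e-2), 51.753, tolerance = 1e-3)
  # doubling MSE lowers PSNR by 3.01 dB
  c2 <- v; c2[1, 1, 1] <- a[1, 1, 1] + 1
  mseb <- mse_metric(mk_ff(a, fg), mk_ff(b, fg))
  expect_equal(10 * log10(100^2 / mseb) - 10 * log10(100^2 / (2 * mseb)),
               10 * log10(2), tolerance = 1e-12)
  # brute-force elementwise oracle on random maps
  set.seed(4)
  x <- mk_ff(array(runif(64, 0, 100), c(4, 4, 4)))
  y <- mk_ff(array(runif(64, 0, 100), c(4, 4, 4)))
  acc <- 0
  for (i in 1:64) acc <- acc + (x$values[i] - y$values[i])^2
  expect_equal(mse_metric(x, y), acc / 64, tolerance = 1e-12)
  # permutation invariance over foreground voxels
  perm <- sample(64)
  xp <- mk_ff(array(x$values[perm], c(4, 4, 4)))
  yp <- mk_ff(array(y$values[perm], c(4, 4, 4)))
  expect_equal(mse_metric(xp, yp), mse_metric(x, y), tolerance = 1e-12)
})

test_that("ssim equals the direct sliding-window oracle and behaves structurally", {
  set.seed(5)
  x <- array(runif(16^3, 0, 100), c(16, 16, 16))
  y <- x + array(rnorm(16^3, sd = 3), c(16, 16, 16))
  fx <- mk_ff(x)
  fy <- mk_ff(y)
  expect_equal(ssim_metric(fx, fx), 1, tolerance = 1e-12)
  # independent direct-loop reference on the same definition
  w <- 7
  c1 <- 1
  c2 <- 9
  vals <- c()
  for (i in 1:(16 - w + 1)) for (j in 1:(16 - w + 1)) for (k in 1:(16 - w + 1)) {
    wx <- x[i:(i + w - 1), j:(j + w - 1), k:(k + w - 1)]
    wy <- y[i:(i + w - 1), j:(j + w - 1), k:(k + w - 1)]
    mx <- mean(wx); my <- mean(wy)
    vx <- mean(wx^2) - mx^2; vy <- mean(wy^2) - my^2
    cxy <- mean(wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  expect_equal(ssim_metric(fx, fy), mean(vals), tolerance = 1e-6)
  # structure reversal scores worse than a small perturbation
  expect_lt(ssim_metric(fx, mk_ff(pmin(pmax(-x + 100, 0), 100))),
            ssim_metric(fx, mk_ff(pmin(pmax(x + 0.5, 0), 100))))
  expect_error(ssim_metric(mk_ff(array(1, c(4, 4, 4))),
                           mk_ff(array(1, c(4, 4, 4))), window = 7),
               "window")
})

test_that("FF error measures follow their formulas", {
  expect_equal(ff_quadratic_error(10, 10), 0)
  expect_equal(ff_quadratic_error(10, 9), 1)
  expect_equal(ff_quadratic_error(10, 9.9), 0.01, tolerance = 1e-12)
  expect_error(ff_quadratic_error(0, 1), "> 0")
  expect_equal(ff_abs_difference(10, 9), 1)
  expect_equal(ff_abs_difference(5, 5), 0)
  expect_equal(ff_abs_difference(3, 8), ff_abs_difference(8, 3))
})

test_that("dice and sensitivity/specificity match confusion-count enumeration", {
  a <- array(FALSE, c(4, 4, 1)); a[1:4, 1, 1] <- TRUE
  b <- array(FALSE, c(4, 4, 1)); b[3:4, 1, 1] <- TRUE; b[1:2, 2, 1] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, !a & FALSE), 0)
  expect_equal(dice_coefficient(a, b), 0.5)       # |a|=|b|=4, overlap 2
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  expect_equal(dice_coefficient(array(FALSE, c(2, 2, 1)),
                                array(FALSE, c(2, 2, 1))), 1)
  ss <- sens_spec(a, a)
  expect_equal(unname(ss), c(1, 1))
  allpos <- array(TRUE, c(4, 4, 1))
  ss2 <- sens_spec(allpos, a)
  expect_equal(unname(ss2), c(1, 0))
  # hand-computed confusion counts on a 2x2 toy
  p <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  t <- array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1))
  expect_equal(unname(sens_spec(p, t)), c(1 / 2, 1 / 2))
  expect_error(sens_spec(a, array(TRUE, c(2, 2, 1))), "differ")
})

test_that("bland_altman matches the closed form", {
  expect_equal(unname(bland_altman(c(1, 2, 3), c(1, 2, 3))), c(0, 0, 0))
  expect_equal(unname(bland_altman(c(0, 0, 0, 0), c(1, 1, 1, 1))), c(1, 1, 1))
  set.seed(6)
  r <- runif(50, 0, 30)
  m <- r + rnorm(50, 0.2, 0.5)
  ba <- bland_altman(r, m)
  d <- m - r
  expect_equal(unname(ba), c(mean(d), mean(d) - 1.96 * sd(d),
                             mean(d) + 1.96 * sd(d)), tolerance = 1e-12)
  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("aggregation reports mean and standard error", {
  x <- c(2, 4, 6, 8)
  expect_equal(unname(aggregate_mean_se(x)), c(5, sd(x) / 2), tolerance = 1e-12)
})
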