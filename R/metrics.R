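# Reconstruction, fat-fraction and segmentation-agreement metrics. All image
# metrics operate on fat-fraction maps in percent (peak 100) over the
# background-removed foreground.

ff_pair <- function(ref, rec) {
  if (!inherits(ref, "ff_map")) ref <- ff_map(ref)
  if (!inherits(rec, "ff_map")) rec <- ff_map(rec)
  if (!all(dim(ref$values) == dim(rec$values)))
    stop("FF map shapes differ", call. = FALSE)
  if (!identical(ref$foreground, rec$foreground))
    stop("FF maps carry different foreground masks", call. = FALSE)
  if (!any(ref$foreground)) stop("empty foreground", call. = FALSE)
  list(ref = ref, rec = rec, fg = ref$foreground)
}

#' Mean squared error over the foreground
#'
#' @param ref,rec [ff_map()] objects (percent units) with identical shapes
#'   and foreground masks.
#' @return MSE in percent^2.
#' @export
mse_metric <- function(ref, rec) {
  p <- ff_pair(ref, rec)
  mean((p$ref$values[p$fg] - p$rec$values[p$fg])^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` with peak 100 (percent scale). Identical maps
#' return `Inf`.
#'
#' @inheritParams mse_metric
#' @param peak dynamic range, default 100.
#' @return PSNR in dB.
#' @export
psnr_metric <- function(ref, rec, peak = 100) {
  m <- mse_metric(ref, rec)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

#' Structural similarity index over the foreground
#'
#' Mean local SSIM with a uniform cubic window and the standard stabilizers
#' `C1 = (0.01 * data_range)^2`, `C2 = (0.03 * data_range)^2`, averaged over
#' windows fully inside the volume whose center voxel is foreground.
#'
#' @inheritParams mse_metric
#' @param window odd window side length, default 7.
#' @param data_range dynamic range, default 100.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim_metric <- function(ref, rec, window = 7L, data_range = 100) {
  p <- ff_pair(ref, rec)
  d <- dim(p$ref$values)
  if (any(d < window)) stop("window larger than volume", call. = FALSE)
  x <- p$ref$values
  y <- p$rec$values
  n <- window^3
  sx <- box_sum3(x, window)
  sy <- box_sum3(y, window)
  sxx <- box_sum3(x * x, window)
  syy <- box_sum3(y * y, window)
  sxy <- box_sum3(x * y, window)
  mx <- sx / n
  my <- sy / n
  vx <- sxx / n - mx^2
  vy <- syy / n - my^2
  cxy <- sxy / n - mx * my
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  ssim <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  half <- (window - 1L) %/% 2L
  centers <- p$fg[half + seq_len(d[1] - window + 1L),
                  half + seq_len(d[2] - window + 1L),
                  half + seq_len(d[3] - window + 1L), drop = FALSE]
  if (!any(centers)) stop("no foreground-centered window fits", call. = FALSE)
  mean(ssim[centers])
}

# sliding-window sums over all fully-contained windows (valid mode), via
# cumulative sums along each axis
box_sum3 <- function(x, w) {
  for (axis in 1:3) {
    d <- dim(x)
    perm <- c(axis, seq_len(3)[-axis])
    xp <- aperm(x, perm)
    dp <- dim(xp)
    m <- matrix(xp, dp[1], dp[2] * dp[3])
    cs <- rbind(0, apply(m, 2, cumsum))
    s <- cs[(w + 1):(dp[1] + 1), , drop = FALSE] - cs[seq_len(dp[1] - w + 1), , drop = FALSE]
    dim(s) <- c(dp[1] - w + 1L, dp[2], dp[3])
    x <- aperm(s, order(perm))
  }
  x
}

#' Relative quadratic fat-fraction error
#'
#' `100 * ((ff_rec - ff_ref) / ff_ref)^2`, in percent.
#'
#' @param ff_ref reference mean FF (percent, > 0).
#' @param ff_rec reconstructed mean FF (percent).
#' @export
ff_quadratic_error <- function(ff_ref, ff_rec) {
  if (any(ff_ref <= 0)) stop("ff_ref must be > 0", call. = FALSE)
  100 * ((ff_rec - ff_ref) / ff_ref)^2
}

#' Absolute fat-fraction difference
#' @inheritParams ff_quadratic_error
#' @export
ff_abs_difference <- function(ff_ref, ff_rec) abs(ff_rec - ff_ref)

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks give 1 by convention.
#'
#' @param a,b logical arrays of identical shape.
#' @export
dice_coefficient <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Sensitivity and specificity of a binary segmentation
#'
#' @param pred,truth logical arrays of identical shape.
#' @return named numeric vector `(sensitivity, specificity)`; `NaN` where the
#'   denominator is empty.
#' @export
sens_spec <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ", call. = FALSE)
  tp <- sum(pred & truth)
  fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth)
  c(sensitivity = if (tp + fn == 0) NaN else tp / (tp + fn),
    specificity = if (tn + fp == 0) NaN else tn / (tn + fp))
}

#' Bland-Altman agreement analysis
#'
#' Bias `mean(rec - ref)` and 95% limits of agreement
#' `bias +/- 1.96 * SD(rec - ref)` (sample SD).
#'
#' @param ref_values,rec_values paired numeric vectors (length >= 2).
#' @return named numeric vector `(bias, loa_low, loa_high)`.
#' @export
bland_altman <- function(ref_values, rec_values) {
  if (length(ref_values) != length(rec_values))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(ref_values) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- rec_values - ref_values
  bias <- mean(d)
  s <- stats::sd(d)
  c(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Mean and standard error aggregation
#'
#' Test-set summaries are reported as mean over volumes plus the standard
#' error `sd / sqrt(n)`.
#'
#' @param x numeric vector.
#' @return named vector `(mean, se)`.
#' @export
aggregate_mean_se <- function(x) {
  c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
}
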